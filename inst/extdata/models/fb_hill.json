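{
  "name": "fb_hill",
  "species": ["W", "Y"],
  "parameters": {
    "mu_W": 1,
    "mu_Y": 1,
    "K": 1,
    "gamma": 0.1,
    "n": 1
  },
  "rates": {
    "W": "F - gamma*W",
    "Y": "mu_Y*W - gamma*Y"
  },
  "feedback": "mu_W/(1 + (Y/K)^n)",
  "output": "Y"
}
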