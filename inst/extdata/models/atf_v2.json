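{
  "name": "atf_v2",
  "species": ["W", "U", "C", "Y"],
  "parameters": {
    "mu_W": 0.1,
    "mu_U": 0.125,
    "mu_Y": 0.125,
    "eta_p": 0.05,
    "eta_m": 0.5,
    "gamma": 0.0001,
    "gamma_Y": 0.1
  },
  "rates": {
    "W": "mu_W - eta_p*U*W - gamma*W",
    "U": "F - eta_p*U*W - gamma*U",
    "C": "eta_p*U*W - (eta_m + gamma)*C",
    "Y": "mu_Y*(W + C) - gamma_Y*Y"
  },
  "feedback": "mu_U*Y",
  "output": "Y"
}
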