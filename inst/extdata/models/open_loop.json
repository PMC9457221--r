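{
  "name": "open_loop",
  "species": "Y",
  "parameters": {
    "mu": 1,
    "gamma": 0.1
  },
  "rates": {
    "Y": "F - gamma*Y"
  },
  "feedback": "mu",
  "output": "Y"
}
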