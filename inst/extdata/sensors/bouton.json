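{
  "params": {
    "gTotal": 20,
    "aCa": 20,
    "kappaB": 40,
    "pumpVmax": 1500,
    "pumpKm": 0.5,
    "storeInVmax": 0,
    "storeInKm": 0.5,
    "storeOutVmax": 0,
    "storeOutKm": 50,
    "storeCaBasal": 50,
    "slowFrac": 0.1,
    "slowK": 2,
    "caBasal": 0.05,
    "f0": 1,
    "sigma": 0
  },
  "meta": {
    "role": "standard granule-cell bouton model",
    "sharedAcrossVariants": true
  }
}
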