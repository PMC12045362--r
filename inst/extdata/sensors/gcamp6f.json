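{
  "name": "GCaMP6f",
  "units": {
    "rates": "1/s",
    "Ka": "uM"
  },
  "Rf": 7.60473761535661,
  "nCaPerLobe": 2,
  "lobeN": {
    "koffCa": 16.6452512917582,
    "Ka": 0.586005588697957,
    "hill": 4,
    "konPep": 43.188964599387,
    "koffPep": 60.4511582466641
  },
  "lobeC": {
    "koffCa": 45.0504383114878,
    "Ka": 4.09096568619536,
    "hill": 1.13898579724419,
    "konPep": 19.3478706180245,
    "koffPep": 151.924612907997
  },
  "meta": {
    "loss": 0.000914338793784374,
    "biphasicRatio": 8.00565366404014,
    "calibration": "joint slice-statistic fit, shared bouton CellParams",
    "script": "scripts/calibrate_defaults.R",
    "maxit": 1500,
    "targets": {
      "riseTime": 0.0181,
      "halfDecay1": 0.078,
      "halfDecay10": 0.13,
      "peak1": 0.29,
      "ratio10to1": 20,
      "ppr10ms": 3.1
    },
    "achieved": {
      "riseTime": 0.0175811415916817,
      "halfDecay1": 0.0775560654261103,
      "halfDecay10": 0.130678078578118,
      "peak1": 0.289982712813421,
      "ratio10to1": 19.9796504808388,
      "ppr10ms": 3.10862069328732
    }
  }
}
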