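{
  "name": "jGCaMP7f",
  "units": {
    "rates": "1/s",
    "Ka": "uM"
  },
  "Rf": 5.84972995932944,
  "nCaPerLobe": 2,
  "lobeN": {
    "koffCa": 132.525077978265,
    "Ka": 1.51728283759142,
    "hill": 2.24337003096322,
    "konPep": 659.887525626044,
    "koffPep": 73.3519889342564
  },
  "lobeC": {
    "koffCa": 1.10885549920612,
    "Ka": 2.12790347336879,
    "hill": 3.99340933679103,
    "konPep": 34.4548865578876,
    "koffPep": 5.20053334285948
  },
  "meta": {
    "loss": 2.27950090839368e-13,
    "biphasicRatio": 30.862818211343,
    "calibration": "joint slice-statistic fit, shared bouton CellParams",
    "script": "scripts/calibrate_defaults.R",
    "maxit": 1500,
    "targets": {
      "riseTime": 0.0137,
      "halfDecay1": 0.077,
      "halfDecay10": 0.126,
      "peak1": 0.34,
      "ppr10ms": 1.9
    },
    "achieved": {
      "riseTime": 0.0136999990933013,
      "halfDecay1": 0.0770000284311579,
      "halfDecay10": 0.125999988754656,
      "peak1": 0.34000007389555,
      "ratio10to1": 11.9832373109323,
      "ppr10ms": 1.89999965994249
    }
  }
}
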