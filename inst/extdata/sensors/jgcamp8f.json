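{
  "name": "jGCaMP8f",
  "units": {
    "rates": "1/s",
    "Ka": "uM"
  },
  "Rf": 6.33717046686275,
  "nCaPerLobe": 2,
  "lobeN": {
    "koffCa": 2623.43708350972,
    "Ka": 0.513879488164781,
    "hill": 1.2582556675368,
    "konPep": 299.677043712392,
    "koffPep": 400.545795344059
  },
  "lobeC": {
    "koffCa": 3.09250542384106,
    "Ka": 3.97643182547758,
    "hill": 0.324028705662133,
    "konPep": 8.79929697699903,
    "koffPep": 31.0533750799826
  },
  "meta": {
    "loss": 0.00118325687207619,
    "biphasicRatio": 9.09434224007206,
    "calibration": "joint slice-statistic fit, shared bouton CellParams",
    "script": "scripts/calibrate_defaults.R",
    "maxit": 1500,
    "targets": {
      "riseTime": 0.0031,
      "halfDecay1": 0.041,
      "halfDecay10": 0.123,
      "peak1": 0.59,
      "ratio10to1": 3
    },
    "achieved": {
      "riseTime": 0.00311168209699199,
      "halfDecay1": 0.041968816885445,
      "halfDecay10": 0.120677657020198,
      "peak1": 0.591013345826358,
      "ratio10to1": 3.04851747803677,
      "ppr10ms": 0.714272878593101
    }
  }
}
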