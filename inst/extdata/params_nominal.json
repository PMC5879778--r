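{
  "description": "Nominal parameter set of the hypoxia cell-cycle commitment model. Every value is calibrated, not transcribed: the set reproduces the published anchors (Hif1a peak 5 uM at 0.5% oxygen, negligible above 10%; Hif2a peak at 5% oxygen, detectable at 20%; E2F threshold 1 uM; commitment time 13.5 h at 2% oxygen; quiescence below ~1.2% oxygen; optimal oxygen 8-10%; convexity factor k near 27.9).",
  "units": {
    "concentration": "uM",
    "time": "h",
    "oxygen": "fraction (0.02 = 2%)"
  },
  "parameters": {
    "m1": 0.105765374364037,
    "b1": 3.85597,
    "p1": 0.005,
    "t1": 0.0596381,
    "m2": 0.579059525075472,
    "b2": 0.54635,
    "p2": 0.05,
    "t2": 0.418079,
    "kf3A": 2.86493,
    "kr3A": 0.134133,
    "kf3B": 0.803436,
    "kr3B": 0.134133,
    "kf6B": 1.34133,
    "kr6B": 0.268267,
    "kf12": 1.34133,
    "kr12": 0.268267,
    "k8": 8.04802,
    "m9": 0.134133,
    "k9": 0.5,
    "m13": 0.733202,
    "k13": 0.679711,
    "k'13": 0.106182,
    "m_E2F": 0.00487115,
    "k_E2F": 0.65504,
    "m_E2F-RbP": 0.607164,
    "k_E2F-RbP": 0.5,
    "m_5cycD": 0.0953813,
    "k_5cycD": 202.51,
    "m_cycD-Rb": 0.168081,
    "k_cycD-Rb": 0.5,
    "m_RbP": 0.0900064,
    "k_RbP": 0.3,
    "m_cycE-RbP": 20.785,
    "k_cycE-RbP": 0.3,
    "m_Rb-nP": 0.268267,
    "k_Rb-nP": 0.3,
    "k3a": 0.028298,
    "k4": 0.357444,
    "epsilon": 1.50254,
    "g_Myc": 0.270887,
    "g_cycD": 0.107306,
    "g_p/p": 0.0536532,
    "g_Rb": 0.0552318,
    "d_Myc": 2.82088,
    "d_Hif1a-Myc": 0.0804802,
    "d_Hif2a-Myc": 0.0119797,
    "d_cycE": 0.0938933,
    "d_E2F": 0.00790796,
    "d_cycD": 0.134133,
    "d_p/p": 0.134158,
    "d_cycD-p/p": 0.134133,
    "d_cycE-p/p": 0.134133,
    "d_Rb": 0.0266541,
    "d_E2F-Rb": 0.00411887,
    "d_RbP": 0.116721,
    "n": 4,
    "n_deg": 1,
    "[O2]_TH": 0.1,
    "E2F_TH": 1
  },
  "initial_conditions": {
    "Hif1a-Myc": 0,
    "Hif2a-Myc": 0,
    "Myc": 0.1,
    "cycE": 0.05,
    "E2F": 0.05,
    "cycD": 0.05,
    "p/p": 0.1,
    "cycD-p/p": 0,
    "cycE-p/p": 0,
    "Rb": 0.1,
    "E2F-Rb": 0.6,
    "RbP": 0,
    "Rb-nP": 0
  },
  "unify_k_e2f_rbp": false
}
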