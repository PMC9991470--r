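{
  "panel": [
    {
      "element": "Zn",
      "wavelength_nm": 213.85,
      "dl_ug_g": 0.05
    },
    {
      "element": "Pb",
      "wavelength_nm": 220.35,
      "dl_ug_g": 0.09
    },
    {
      "element": "Cd",
      "wavelength_nm": 226.5,
      "dl_ug_g": 0.03
    },
    {
      "element": "Co",
      "wavelength_nm": 228.61,
      "dl_ug_g": 0.03
    },
    {
      "element": "Ni",
      "wavelength_nm": 231.6,
      "dl_ug_g": 0.05
    },
    {
      "element": "Fe",
      "wavelength_nm": 238.2,
      "dl_ug_g": 0.04
    },
    {
      "element": "Mn",
      "wavelength_nm": 257.61,
      "dl_ug_g": 0.07
    },
    {
      "element": "Cr",
      "wavelength_nm": 267.71,
      "dl_ug_g": 0.02
    },
    {
      "element": "Mg",
      "wavelength_nm": 280.26,
      "dl_ug_g": 0.08
    },
    {
      "element": "Cu",
      "wavelength_nm": 324.75,
      "dl_ug_g": 0.07
    },
    {
      "element": "Se",
      "wavelength_nm": 361.38,
      "dl_ug_g": 0.04
    },
    {
      "element": "Ca",
      "wavelength_nm": 393.36,
      "dl_ug_g": 0.08
    },
    {
      "element": "Al",
      "wavelength_nm": 396.15,
      "dl_ug_g": 0.1
    },
    {
      "element": "Sr",
      "wavelength_nm": 407.77,
      "dl_ug_g": 0.02
    },
    {
      "element": "Na",
      "wavelength_nm": 589.6,
      "dl_ug_g": 0.33
    },
    {
      "element": "K",
      "wavelength_nm": 766.49,
      "dl_ug_g": 0.76
    }
  ],
  "distributions": {
    "free-range": [
      {
        "element": "Zn",
        "mean": 1.72,
        "sd": 0.39,
        "nondetect": false
      },
      {
        "element": "Pb",
        "mean": 1.04,
        "sd": 0.27,
        "nondetect": false
      },
      {
        "element": "Cd",
        "mean": 0,
        "sd": 0,
        "nondetect": true
      },
      {
        "element": "Co",
        "mean": 0.22,
        "sd": 0.04,
        "nondetect": false
      },
      {
        "element": "Ni",
        "mean": 0.44,
        "sd": 0.12,
        "nondetect": false
      },
      {
        "element": "Fe",
        "mean": 2.1,
        "sd": 0.6,
        "nondetect": false
      },
      {
        "element": "Mn",
        "mean": 0.67,
        "sd": 0.13,
        "nondetect": false
      },
      {
        "element": "Cr",
        "mean": 0.71,
        "sd": 0.28,
        "nondetect": false
      },
      {
        "element": "Mg",
        "mean": 6042,
        "sd": 2106,
        "nondetect": false
      },
      {
        "element": "Cu",
        "mean": 1.56,
        "sd": 0.31,
        "nondetect": false
      },
      {
        "element": "Se",
        "mean": 4.22,
        "sd": 1.68,
        "nondetect": false
      },
      {
        "element": "Ca",
        "mean": 366310,
        "sd": 46778,
        "nondetect": false
      },
      {
        "element": "Al",
        "mean": 71.9,
        "sd": 6.5,
        "nondetect": false
      },
      {
        "element": "Sr",
        "mean": 120.4,
        "sd": 24.8,
        "nondetect": false
      },
      {
        "element": "Na",
        "mean": 2156,
        "sd": 388,
        "nondetect": false
      },
      {
        "element": "K",
        "mean": 1850,
        "sd": 302,
        "nondetect": false
      }
    ],
    "caged": [
      {
        "element": "Zn",
        "mean": 2.33,
        "sd": 0.51,
        "nondetect": false
      },
      {
        "element": "Pb",
        "mean": 2.16,
        "sd": 0.19,
        "nondetect": false
      },
      {
        "element": "Cd",
        "mean": 0.34,
        "sd": 0.08,
        "nondetect": false
      },
      {
        "element": "Co",
        "mean": 0.32,
        "sd": 0.09,
        "nondetect": false
      },
      {
        "element": "Ni",
        "mean": 0.59,
        "sd": 0.1,
        "nondetect": false
      },
      {
        "element": "Fe",
        "mean": 3.2,
        "sd": 1,
        "nondetect": false
      },
      {
        "element": "Mn",
        "mean": 1.01,
        "sd": 0.31,
        "nondetect": false
      },
      {
        "element": "Cr",
        "mean": 2.32,
        "sd": 1.03,
        "nondetect": false
      },
      {
        "element": "Mg",
        "mean": 5363,
        "sd": 1849,
        "nondetect": false
      },
      {
        "element": "Cu",
        "mean": 2.13,
        "sd": 0.55,
        "nondetect": false
      },
      {
        "element": "Se",
        "mean": 2.18,
        "sd": 1.01,
        "nondetect": false
      },
      {
        "element": "Ca",
        "mean": 342560,
        "sd": 35458,
        "nondetect": false
      },
      {
        "element": "Al",
        "mean": 88.5,
        "sd": 11.7,
        "nondetect": false
      },
      {
        "element": "Sr",
        "mean": 171.3,
        "sd": 44.6,
        "nondetect": false
      },
      {
        "element": "Na",
        "mean": 3016,
        "sd": 612,
        "nondetect": false
      },
      {
        "element": "K",
        "mean": 2305,
        "sd": 226,
        "nondetect": false
      }
    ]
  }
}
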