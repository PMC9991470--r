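{
  "input": {},
  "n_per_class": [127, 122],
  "plant_k": [0, 0],
  "plant_displacement": 10,
  "n_projections": 1000,
  "cutoff": 3,
  "n_train": [80, 80],
  "representation": "autoscaled",
  "models": ["plsda", "lssvm"],
  "lv_grid": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10],
  "lssvm_grid": [
    {
      "sigma2": 10,
      "gamma": 0.5
    },
    {
      "sigma2": 50,
      "gamma": 0.5
    },
    {
      "sigma2": 100,
      "gamma": 0.5
    },
    {
      "sigma2": 300,
      "gamma": 0.5
    },
    {
      "sigma2": 500,
      "gamma": 0.5
    },
    {
      "sigma2": 700,
      "gamma": 0.5
    },
    {
      "sigma2": 1000,
      "gamma": 0.5
    },
    {
      "sigma2": 3000,
      "gamma": 0.5
    },
    {
      "sigma2": 10,
      "gamma": 1
    },
    {
      "sigma2": 50,
      "gamma": 1
    },
    {
      "sigma2": 100,
      "gamma": 1
    },
    {
      "sigma2": 300,
      "gamma": 1
    },
    {
      "sigma2": 500,
      "gamma": 1
    },
    {
      "sigma2": 700,
      "gamma": 1
    },
    {
      "sigma2": 1000,
      "gamma": 1
    },
    {
      "sigma2": 3000,
      "gamma": 1
    },
    {
      "sigma2": 10,
      "gamma": 5
    },
    {
      "sigma2": 50,
      "gamma": 5
    },
    {
      "sigma2": 100,
      "gamma": 5
    },
    {
      "sigma2": 300,
      "gamma": 5
    },
    {
      "sigma2": 500,
      "gamma": 5
    },
    {
      "sigma2": 700,
      "gamma": 5
    },
    {
      "sigma2": 1000,
      "gamma": 5
    },
    {
      "sigma2": 3000,
      "gamma": 5
    },
    {
      "sigma2": 10,
      "gamma": 10
    },
    {
      "sigma2": 50,
      "gamma": 10
    },
    {
      "sigma2": 100,
      "gamma": 10
    },
    {
      "sigma2": 300,
      "gamma": 10
    },
    {
      "sigma2": 500,
      "gamma": 10
    },
    {
      "sigma2": 700,
      "gamma": 10
    },
    {
      "sigma2": 1000,
      "gamma": 10
    },
    {
      "sigma2": 3000,
      "gamma": 10
    },
    {
      "sigma2": 10,
      "gamma": 50
    },
    {
      "sigma2": 50,
      "gamma": 50
    },
    {
      "sigma2": 100,
      "gamma": 50
    },
    {
      "sigma2": 300,
      "gamma": 50
    },
    {
      "sigma2": 500,
      "gamma": 50
    },
    {
      "sigma2": 700,
      "gamma": 50
    },
    {
      "sigma2": 1000,
      "gamma": 50
    },
    {
      "sigma2": 3000,
      "gamma": 50
    },
    {
      "sigma2": 10,
      "gamma": 100
    },
    {
      "sigma2": 50,
      "gamma": 100
    },
    {
      "sigma2": 100,
      "gamma": 100
    },
    {
      "sigma2": 300,
      "gamma": 100
    },
    {
      "sigma2": 500,
      "gamma": 100
    },
    {
      "sigma2": 700,
      "gamma": 100
    },
    {
      "sigma2": 1000,
      "gamma": 100
    },
    {
      "sigma2": 3000,
      "gamma": 100
    }
  ],
  "n_splits": 100,
  "train_frac": 0.7,
  "seed": 20190101,
  "out_dir": {},
  "verbose": false
}
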