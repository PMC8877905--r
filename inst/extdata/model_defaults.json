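{
  "ann": {
    "hidden": [64, 32],
    "dropout": 0.2,
    "learning_rate": 0.001,
    "batch_size": 32,
    "max_epochs": 200,
    "patience": 20,
    "val_fraction": 0.1
  },
  "random_forest": {
    "ntree": 500
  },
  "svm": {
    "kernel": "radial",
    "cost": 1
  },
  "gradient_boosting": {
    "nrounds": 200,
    "eta": 0.1,
    "max_depth": 4
  }
}
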