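[
  {
    "pair": "A:1->B:12",
    "blocks": 5,
    "paths": [
      {
        "path": "1-2-11-10-13-14-23-24",
        "n_blocks": 4,
        "occupancy": 0.8,
        "mean_length": 5.88042973
      },
      {
        "path": "1-2-11-10-13-14-15-24",
        "n_blocks": 1,
        "occupancy": 0.2,
        "mean_length": 5.63538223
      }
    ]
  }
]
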