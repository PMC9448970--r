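{
  "n_occasions": 8,
  "start_year": 2013,
  "colonies": ["RobbenIsland", "StonyPoint"],
  "marking_schedule": [
    [
      [6, 0, 0],
      [2, 0, 0],
      [2, 0, 2],
      [2, 0, 2],
      [2, 0, 2],
      [2, 0, 2],
      [2, 0, 2],
      [2, 0, 2]
    ],
    [
      [8, 0, 0],
      [2, 0, 2],
      [2, 0, 2],
      [2, 0, 2],
      [2, 0, 2],
      [2, 0, 2],
      [2, 0, 2],
      [2, 0, 2]
    ]
  ],
  "true_phi": [
    [
      [0.8, 0.8],
      [0.8, 0.8],
      [0.8, 0.8],
      [0.8, 0.8],
      [0.8, 0.8],
      [0.8, 0.8],
      [0.8, 0.8]
    ],
    [
      [0.78, 0.78],
      [0.78, 0.78],
      [0.78, 0.78],
      [0.78, 0.78],
      [0.78, 0.78],
      [0.78, 0.78],
      [0.78, 0.78]
    ],
    [
      [0.75, 0.75],
      [0.75, 0.75],
      [0.75, 0.75],
      [0.75, 0.75],
      [0.75, 0.75],
      [0.75, 0.75],
      [0.75, 0.75]
    ]
  ],
  "true_p": [
    [
      [0.9, 0.9],
      [0.9, 0.9],
      [0.9, 0.9],
      [0.9, 0.9],
      [0.9, 0.9],
      [0.9, 0.9],
      [0.9, 0.9],
      [0.9, 0.9]
    ],
    [
      [0.55, 0.55],
      [0.55, 0.55],
      [0.55, 0.55],
      [0.55, 0.55],
      [0.55, 0.55],
      [0.55, 0.55],
      [0.55, 0.55],
      [0.55, 0.55]
    ],
    [
      [0.5, 0.5],
      [0.5, 0.5],
      [0.5, 0.5],
      [0.5, 0.5],
      [0.5, 0.5],
      [0.5, 0.5],
      [0.5, 0.5],
      [0.5, 0.5]
    ]
  ],
  "true_psi": [
    [
      [
          [0.78, 0.9],
          [0.78, 0.9],
          [0.78, 0.9],
          [0.78, 0.9],
          [0.78, 0.9],
          [0.78, 0.9],
          [0.78, 0.9]
        ],
      [
          [0.22, 0.1],
          [0.22, 0.1],
          [0.22, 0.1],
          [0.22, 0.1],
          [0.22, 0.1],
          [0.22, 0.1],
          [0.22, 0.1]
        ],
      [
          [0, 0],
          [0, 0],
          [0, 0],
          [0, 0],
          [0, 0],
          [0, 0],
          [0, 0]
        ]
    ],
    [
      [
          [0.66, 0.69],
          [0.66, 0.69],
          [0.66, 0.69],
          [0.66, 0.69],
          [0.66, 0.69],
          [0.66, 0.69],
          [0.66, 0.69]
        ],
      [
          [0.34, 0.31],
          [0.34, 0.31],
          [0.34, 0.31],
          [0.34, 0.31],
          [0.34, 0.31],
          [0.34, 0.31],
          [0.34, 0.31]
        ],
      [
          [0, 0],
          [0, 0],
          [0, 0],
          [0, 0],
          [0, 0],
          [0, 0],
          [0, 0]
        ]
    ],
    [
      [
          [0.5, 0.5],
          [0.5, 0.5],
          [0.5, 0.5],
          [0.5, 0.5],
          [0.5, 0.5],
          [0.5, 0.5],
          [0.5, 0.5]
        ],
      [
          [0, 0],
          [0, 0],
          [0, 0],
          [0, 0],
          [0, 0],
          [0, 0],
          [0, 0]
        ],
      [
          [0.5, 0.5],
          [0.5, 0.5],
          [0.5, 0.5],
          [0.5, 0.5],
          [0.5, 0.5],
          [0.5, 0.5],
          [0.5, 0.5]
        ]
    ]
  ],
  "ground_reader_rate": [6, 1.5, 1.5],
  "nest_check_rate": 0.8,
  "seed": 20130301
}
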