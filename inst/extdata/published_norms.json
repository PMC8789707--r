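{
  "provenance": "Published Italian adult FAB norms (regression-based Equivalent Scores), N = 475",
  "equations": [
    {
      "scale": "fab",
      "age": {
        "family": "cube",
        "coef": 4e-06,
        "center": 269630.547368
      },
      "education": {
        "family": "log",
        "coef": -1.565729,
        "center": 2.366383
      }
    },
    {
      "scale": "fab1",
      "age": {
        "family": "cube",
        "coef": 1e-06,
        "center": 269630.547368
      },
      "education": {
        "family": "log",
        "coef": -0.607345,
        "center": 2.366383
      }
    },
    {
      "scale": "fab2",
      "age": {
        "family": "cube",
        "coef": 2e-06,
        "center": 269630.547368
      },
      "education": {
        "family": "reciprocal",
        "coef": 2.527494,
        "center": 0.105356
      }
    },
    {
      "scale": "fab3",
      "age": {
        "family": "square",
        "coef": 0.000103,
        "center": 3958.627368
      },
      "education": {
        "family": "log",
        "coef": -0.640471,
        "center": 2.366383
      }
    }
  ],
  "tables": [
    {
      "scale": "fab",
      "oTL": 12.02,
      "iTL": 13.16,
      "t1": 13.71,
      "t2": 15.1,
      "median": 16.24,
      "precision": 2,
      "n": 475
    },
    {
      "scale": "fab1",
      "oTL": 3.49,
      "iTL": 3.81,
      "t1": 4.35,
      "t2": 4.76,
      "median": 5.49,
      "precision": 2,
      "n": 475
    },
    {
      "scale": "fab2",
      "oTL": 2.74,
      "iTL": 3.76,
      "t1": 4.45,
      "t2": 5.41,
      "median": 5.69,
      "precision": 2,
      "n": 475
    },
    {
      "scale": "fab3",
      "oTL": 2.8,
      "iTL": 3.12,
      "t1": 3.57,
      "t2": 5.09,
      "median": 5.65,
      "precision": 2,
      "n": 475
    }
  ]
}
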