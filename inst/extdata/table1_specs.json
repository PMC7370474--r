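{
  "version": "1.0",
  "description": "Class-conditional population parameters of the 283-patient pheochromocytoma cohort (class 0 = no IHD, n = 209; class 1 = IHD, n = 74). Categorical features stored as per-class counts, normally distributed features as mean/sd, the skewed urine-metabolite ratio as median and quartiles. precrystal and precolloid share the published merged crystal/colloid row.",
  "n_total": 283,
  "n_class": { "0": 209, "1": 74 },
  "specs": [
    {
      "name": "age",
      "kind": "continuous-normal",
      "encoding": "numerical",
      "params_by_class": {
        "0": { "mean": 51.9, "sd": 12.3 },
        "1": { "mean": 54.0, "sd": 13.8 }
      }
    },
    {
      "name": "sex",
      "kind": "bernoulli",
      "encoding": "categorical",
      "level1_meaning": "male",
      "params_by_class": {
        "0": { "count": 110, "n": 209 },
        "1": { "count": 31, "n": 74 }
      }
    },
    {
      "name": "bmi",
      "kind": "continuous-normal",
      "encoding": "numerical",
      "support": { "lower": 0 },
      "params_by_class": {
        "0": { "mean": 24.1, "sd": 3.5 },
        "1": { "mean": 21.9, "sd": 2.7 }
      }
    },
    {
      "name": "asa",
      "kind": "multinomial",
      "encoding": "numerical",
      "dual": true,
      "levels": [1, 2, 3],
      "params_by_class": {
        "0": { "counts": [52, 136, 21], "n": 209 },
        "1": { "counts": [14, 53, 7], "n": 74 }
      }
    },
    {
      "name": "dm",
      "kind": "bernoulli",
      "encoding": "categorical",
      "level1_meaning": "diabetes mellitus present",
      "params_by_class": {
        "0": { "count": 61, "n": 209 },
        "1": { "count": 23, "n": 74 }
      }
    },
    {
      "name": "chd",
      "kind": "bernoulli",
      "encoding": "categorical",
      "level1_meaning": "coronary heart disease present",
      "params_by_class": {
        "0": { "count": 66, "n": 209 },
        "1": { "count": 37, "n": 74 }
      }
    },
    {
      "name": "hypertension",
      "kind": "multinomial",
      "encoding": "numerical",
      "dual": true,
      "levels": [0, 1, 2],
      "level_meanings": ["normal", "intermittent", "continuous"],
      "params_by_class": {
        "0": { "counts": [82, 47, 80], "n": 209 },
        "1": { "counts": [30, 18, 26], "n": 74 }
      }
    },
    {
      "name": "arrhythmia",
      "kind": "bernoulli",
      "encoding": "categorical",
      "level1_meaning": "arrhythmia present",
      "params_by_class": {
        "0": { "count": 12, "n": 209 },
        "1": { "count": 4, "n": 74 }
      }
    },
    {
      "name": "side",
      "kind": "bernoulli",
      "encoding": "categorical",
      "level1_meaning": "left-sided tumor",
      "params_by_class": {
        "0": { "count": 103, "n": 209 },
        "1": { "count": 39, "n": 74 }
      }
    },
    {
      "name": "size",
      "kind": "continuous-normal",
      "encoding": "numerical",
      "support": { "lower": 0 },
      "params_by_class": {
        "0": { "mean": 5.2, "sd": 2.5 },
        "1": { "mean": 6.5, "sd": 3.1 }
      }
    },
    {
      "name": "necrosis",
      "kind": "bernoulli",
      "encoding": "categorical",
      "level1_meaning": "tumor necrosis present",
      "params_by_class": {
        "0": { "count": 69, "n": 209 },
        "1": { "count": 33, "n": 74 }
      }
    },
    {
      "name": "ctvalue",
      "kind": "continuous-normal",
      "encoding": "numerical",
      "params_by_class": {
        "0": { "mean": 43.2, "sd": 20.6 },
        "1": { "mean": 45.6, "sd": 20.2 }
      }
    },
    {
      "name": "preablock",
      "kind": "bernoulli",
      "encoding": "categorical",
      "level1_meaning": "alpha adrenoreceptor antagonist used",
      "params_by_class": {
        "0": { "count": 115, "n": 209 },
        "1": { "count": 42, "n": 74 }
      }
    },
    {
      "name": "precrystal",
      "kind": "bernoulli",
      "encoding": "categorical",
      "level1_meaning": "crystal fluid used (shares the merged crystal/colloid row)",
      "params_by_class": {
        "0": { "count": 118, "n": 209 },
        "1": { "count": 29, "n": 74 }
      }
    },
    {
      "name": "precolloid",
      "kind": "bernoulli",
      "encoding": "categorical",
      "level1_meaning": "colloid fluid used (shares the merged crystal/colloid row)",
      "params_by_class": {
        "0": { "count": 118, "n": 209 },
        "1": { "count": 29, "n": 74 }
      }
    },
    {
      "name": "preblood",
      "kind": "bernoulli",
      "encoding": "categorical",
      "level1_meaning": "preoperative blood transfusion",
      "params_by_class": {
        "0": { "count": 54, "n": 209 },
        "1": { "count": 15, "n": 74 }
      }
    },
    {
      "name": "prevma",
      "kind": "continuous-lognormal",
      "encoding": "numerical",
      "support": { "lower": 0 },
      "params_by_class": {
        "0": { "median": 1.4, "q1": 0.9, "q3": 2.2 },
        "1": { "median": 1.47, "q1": 0.9, "q3": 2.7 }
      }
    },
    {
      "name": "surgeryapproach",
      "kind": "bernoulli",
      "encoding": "categorical",
      "level1_meaning": "laparoscopic (vs open)",
      "params_by_class": {
        "0": { "count": 109, "n": 209 },
        "1": { "count": 42, "n": 74 }
      }
    }
  ]
}
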