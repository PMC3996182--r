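[
  {
    "disease": "COPD",
    "cohort_size": 30,
    "findings": [
      {
        "name": "core_body_temperature",
        "count": 8
      },
      {
        "name": "pulse",
        "count": 5
      },
      {
        "name": "arterial_systolic_pressure",
        "count": 19
      },
      {
        "name": "diastolic_blood_pressure",
        "count": 11
      },
      {
        "name": "fio2",
        "count": 28
      },
      {
        "name": "frequency",
        "count": 17
      },
      {
        "name": "tidal_volume",
        "count": 21
      },
      {
        "name": "peep",
        "count": 18
      },
      {
        "name": "pso2",
        "count": 21
      },
      {
        "name": "ph",
        "count": 23
      },
      {
        "name": "po2",
        "count": 22
      },
      {
        "name": "pco2",
        "count": 17
      },
      {
        "name": "bicarbonate",
        "count": 20
      },
      {
        "name": "pressure_support",
        "count": 22
      },
      {
        "name": "volume_support",
        "count": 8
      }
    ]
  },
  {
    "disease": "ARDS",
    "cohort_size": 65,
    "findings": [
      {
        "name": "core_body_temperature",
        "count": 48
      },
      {
        "name": "pulse",
        "count": 41
      },
      {
        "name": "arterial_systolic_pressure",
        "count": 13
      },
      {
        "name": "diastolic_blood_pressure",
        "count": 23
      },
      {
        "name": "fio2",
        "count": 50
      },
      {
        "name": "frequency",
        "count": 39
      },
      {
        "name": "tidal_volume",
        "count": 49
      },
      {
        "name": "peep",
        "count": 43
      },
      {
        "name": "pso2",
        "count": 48
      },
      {
        "name": "ph",
        "count": 40
      },
      {
        "name": "po2",
        "count": 39
      },
      {
        "name": "pco2",
        "count": 38
      },
      {
        "name": "bicarbonate",
        "count": 34
      },
      {
        "name": "pressure_support",
        "count": 57
      },
      {
        "name": "volume_support",
        "count": 8
      }
    ]
  },
  {
    "disease": "CVD",
    "cohort_size": 63,
    "findings": [
      {
        "name": "core_body_temperature",
        "count": 52
      },
      {
        "name": "pulse",
        "count": 55
      },
      {
        "name": "arterial_systolic_pressure",
        "count": 26
      },
      {
        "name": "diastolic_blood_pressure",
        "count": 13
      },
      {
        "name": "fio2",
        "count": 49
      },
      {
        "name": "frequency",
        "count": 57
      },
      {
        "name": "tidal_volume",
        "count": 43
      },
      {
        "name": "peep",
        "count": 43
      },
      {
        "name": "pso2",
        "count": 54
      },
      {
        "name": "ph",
        "count": 38
      },
      {
        "name": "po2",
        "count": 28
      },
      {
        "name": "pco2",
        "count": 43
      },
      {
        "name": "bicarbonate",
        "count": 46
      },
      {
        "name": "pressure_support",
        "count": 53
      },
      {
        "name": "volume_support",
        "count": 10
      }
    ]
  }
]
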