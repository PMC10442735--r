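{
  "settings": {
    "horizon_years": 5,
    "cost_year": 2021,
    "currency": "ZAR",
    "usd_per_zar": 0.053
  },
  "risk_rules": [
    {
      "complication_class": "macrovascular",
      "threshold_percent": 7,
      "increment_per_point_fraction": 0.38
    },
    {
      "complication_class": "microvascular",
      "threshold_percent": 6.5,
      "increment_per_point_fraction": 0.4
    }
  ],
  "complications": [
    {
      "name": "myocardial_infarction",
      "complication_class": "macrovascular",
      "baseline_incidence_fraction": 0.06,
      "source_cost_zar": 43415,
      "source_cost_year": 2014,
      "cost_2021_zar": 65025
    },
    {
      "name": "stroke",
      "complication_class": "macrovascular",
      "baseline_incidence_fraction": 0.04,
      "source_cost_zar": 34722,
      "source_cost_year": 2019,
      "cost_2021_zar": 38245
    },
    {
      "name": "cardiovascular_disease",
      "complication_class": "macrovascular",
      "baseline_incidence_fraction": 0.17,
      "source_cost_zar": 21598,
      "source_cost_year": 2019,
      "cost_2021_zar": 23789
    },
    {
      "name": "nephropathy",
      "complication_class": "microvascular",
      "baseline_incidence_fraction": 0.25,
      "source_cost_zar": 503399,
      "source_cost_year": 2019,
      "cost_2021_zar": 554469
    },
    {
      "name": "retinopathy",
      "complication_class": "microvascular",
      "baseline_incidence_fraction": 0.15,
      "source_cost_zar": 3973,
      "source_cost_year": 2019,
      "cost_2021_zar": 4376
    },
    {
      "name": "foot_ulcers_diabetic_foot",
      "complication_class": "microvascular",
      "baseline_incidence_fraction": 0.13,
      "source_cost_zar": 83333,
      "source_cost_year": 2021,
      "cost_2021_zar": 83333
    },
    {
      "name": "amputations",
      "complication_class": "microvascular",
      "baseline_incidence_fraction": 0.03,
      "source_cost_zar": 323418,
      "source_cost_year": 2020,
      "cost_2021_zar": 339589
    }
  ],
  "inflation": [
    {
      "year": 2015,
      "rate_fraction": 0.0633938017630706
    },
    {
      "year": 2016,
      "rate_fraction": 0.0633938017630706
    },
    {
      "year": 2017,
      "rate_fraction": 0.0633938017630706
    },
    {
      "year": 2018,
      "rate_fraction": 0.0633938017630706
    },
    {
      "year": 2019,
      "rate_fraction": 0.0633938017630706
    },
    {
      "year": 2020,
      "rate_fraction": 0.0490121190587729
    },
    {
      "year": 2021,
      "rate_fraction": 0.0500003091973855
    }
  ],
  "cohorts": [
    {
      "label": "standard_of_care",
      "hba1c_baseline_percent": 9,
      "hba1c_6mo_percent": 8.2
    },
    {
      "label": "mydiacare",
      "hba1c_baseline_percent": 7.8,
      "hba1c_6mo_percent": 7.2
    }
  ],
  "population": [
    {
      "year": 1,
      "prevalence": 328118,
      "incidence": 43410
    },
    {
      "year": 2,
      "prevalence": 368295,
      "incidence": 43744
    },
    {
      "year": 3,
      "prevalence": 408454,
      "incidence": 44087
    },
    {
      "year": 4,
      "prevalence": 448603,
      "incidence": 44439
    },
    {
      "year": 5,
      "prevalence": 488752,
      "incidence": 44800
    }
  ],
  "monitoring": [
    {
      "scenario": "standard_of_care",
      "annual_cost_per_patient_zar": 6728.96793781357
    },
    {
      "scenario": "mydiacare",
      "annual_cost_per_patient_zar": 9689.71383045154
    }
  ],
  "market_shares": [0.02, 0.03, 0.04, 0.05, 0.06]
}
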