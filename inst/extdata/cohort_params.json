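{
  "version": "1.0",
  "comment": "Default per (sex x BMI-category) distribution parameters for the synthetic cohort generator: [mean, sd] on the measurement scale. Transcribed group summaries of the reference clamp study cohort (87 non-diabetic sub-Saharan African adults). Units: age years; bmi kg/m2; percent_fat %; waist/hip cm; sbp/dbp mmHg; tc/tg/hdl mg/dL; fasting_glucose mmol/L; fasting_insulin uU/mL; m_adjusted mg/min/kg fat-free mass.",
  "height_cm": { "male": [171.0, 6.5], "female": [160.0, 6.0] },
  "groups": {
    "male": {
      "lean": {
        "n": 23,
        "age": [33.1, 11.4], "bmi": [22.1, 1.4], "percent_fat": [14.2, 3.6],
        "waist": [76.0, 4.5], "hip": [87.1, 5.9],
        "sbp": [122, 20], "dbp": [72, 9],
        "tc": [160, 43], "tg": [50, 17], "hdl": [48, 18],
        "fasting_glucose": [4.56, 0.58], "fasting_insulin": [4.66, 2.56],
        "m_adjusted": [11.6, 2.9]
      },
      "overweight": {
        "n": 18,
        "age": [36.9, 9.3], "bmi": [27.7, 1.7], "percent_fat": [23.2, 6.3],
        "waist": [92.8, 8.4], "hip": [97.2, 6.1],
        "sbp": [131, 21], "dbp": [76, 11],
        "tc": [210, 63], "tg": [57, 20], "hdl": [63, 21],
        "fasting_glucose": [4.42, 0.55], "fasting_insulin": [5.71, 4.39],
        "m_adjusted": [9.8, 3.3]
      },
      "obese": {
        "n": 10,
        "age": [38.3, 9.7], "bmi": [35.3, 7.4], "percent_fat": [33.6, 9.6],
        "waist": [109.0, 12.8], "hip": [117.1, 15.1],
        "sbp": [129, 10], "dbp": [84, 6],
        "tc": [275, 45], "tg": [71, 47], "hdl": [70, 32],
        "fasting_glucose": [4.93, 0.56], "fasting_insulin": [8.95, 3.60],
        "m_adjusted": [7.8, 2.9]
      }
    },
    "female": {
      "lean": {
        "n": 14,
        "age": [31.3, 12.9], "bmi": [23.0, 1.4], "percent_fat": [26.6, 6.0],
        "waist": [78.0, 6.7], "hip": [92.0, 9.1],
        "sbp": [123, 22], "dbp": [75, 9],
        "tc": [154, 61], "tg": [54, 14], "hdl": [47, 20],
        "fasting_glucose": [4.46, 0.50], "fasting_insulin": [6.72, 2.69],
        "m_adjusted": [11.5, 2.7]
      },
      "overweight": {
        "n": 9,
        "age": [35.3, 16.0], "bmi": [27.7, 1.5], "percent_fat": [32.5, 8.0],
        "waist": [85.4, 7.7], "hip": [106.9, 9.7],
        "sbp": [117, 17], "dbp": [71, 6],
        "tc": [182, 77], "tg": [47, 15], "hdl": [39, 11],
        "fasting_glucose": [4.85, 0.70], "fasting_insulin": [9.56, 5.94],
        "m_adjusted": [11.1, 3.4]
      },
      "obese": {
        "n": 13,
        "age": [34.2, 10.7], "bmi": [36.3, 5.9], "percent_fat": [40.8, 5.3],
        "waist": [102.6, 11.4], "hip": [119.8, 13.3],
        "sbp": [125, 6], "dbp": [77, 5],
        "tc": [235, 55], "tg": [71, 43], "hdl": [58, 23],
        "fasting_glucose": [4.56, 0.43], "fasting_insulin": [7.38, 3.26],
        "m_adjusted": [10.4, 3.1]
      }
    }
  }
}
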