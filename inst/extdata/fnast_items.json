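{
  "version": "1.0",
  "items": [
    {
      "item_id": "high_pitched_crying",
      "label": "High-pitched crying",
      "grade": "excessive",
      "grade_order": 1,
      "weight": 2,
      "binary_id": "high_pitched_crying"
    },
    {
      "item_id": "high_pitched_crying",
      "label": "High-pitched crying",
      "grade": "continuous",
      "grade_order": 2,
      "weight": 3,
      "binary_id": "high_pitched_crying"
    },
    {
      "item_id": "sleeps_after_feeding",
      "label": "Sleeps after feeding",
      "grade": "less_than_3h",
      "grade_order": 1,
      "weight": 1,
      "binary_id": "sleeps_lt3h"
    },
    {
      "item_id": "sleeps_after_feeding",
      "label": "Sleeps after feeding",
      "grade": "less_than_2h",
      "grade_order": 2,
      "weight": 2,
      "binary_id": "sleeps_lt3h"
    },
    {
      "item_id": "sleeps_after_feeding",
      "label": "Sleeps after feeding",
      "grade": "less_than_1h",
      "grade_order": 3,
      "weight": 3,
      "binary_id": "sleeps_lt3h"
    },
    {
      "item_id": "moro_reflex",
      "label": "Moro reflex",
      "grade": "hyperactive",
      "grade_order": 1,
      "weight": 2,
      "binary_id": "hyperactive_moro"
    },
    {
      "item_id": "moro_reflex",
      "label": "Moro reflex",
      "grade": "markedly_hyperactive",
      "grade_order": 2,
      "weight": 3,
      "binary_id": "hyperactive_moro"
    },
    {
      "item_id": "tremors_disturbed",
      "label": "Tremors when disturbed",
      "grade": "mild",
      "grade_order": 1,
      "weight": 1,
      "binary_id": "tremors_disturbed"
    },
    {
      "item_id": "tremors_disturbed",
      "label": "Tremors when disturbed",
      "grade": "moderate_severe",
      "grade_order": 2,
      "weight": 2,
      "binary_id": "tremors_disturbed"
    },
    {
      "item_id": "tremors_undisturbed",
      "label": "Tremors when undisturbed",
      "grade": "mild",
      "grade_order": 1,
      "weight": 3,
      "binary_id": "tremors_undisturbed"
    },
    {
      "item_id": "tremors_undisturbed",
      "label": "Tremors when undisturbed",
      "grade": "moderate_severe",
      "grade_order": 2,
      "weight": 4,
      "binary_id": "tremors_undisturbed"
    },
    {
      "item_id": "muscle_tone",
      "label": "Increased muscle tone",
      "grade": "increased",
      "grade_order": 1,
      "weight": 2,
      "binary_id": "increased_muscle_tone"
    },
    {
      "item_id": "excoriation",
      "label": "Excoriation",
      "grade": "present",
      "grade_order": 1,
      "weight": 1,
      "binary_id": "excoriation"
    },
    {
      "item_id": "myoclonic_jerks",
      "label": "Myoclonic jerks",
      "grade": "present",
      "grade_order": 1,
      "weight": 3,
      "binary_id": "myoclonic_jerks"
    },
    {
      "item_id": "convulsions",
      "label": "Generalized convulsions",
      "grade": "generalized",
      "grade_order": 1,
      "weight": 5,
      "binary_id": "generalized_convulsions"
    },
    {
      "item_id": "sweating",
      "label": "Sweating",
      "grade": "present",
      "grade_order": 1,
      "weight": 1,
      "binary_id": "sweating"
    },
    {
      "item_id": "body_temperature",
      "label": "Body temperature",
      "grade": "temp_37_2_to_38_3",
      "grade_order": 1,
      "weight": 1,
      "binary_id": "temp_ge_37_2"
    },
    {
      "item_id": "body_temperature",
      "label": "Body temperature",
      "grade": "temp_ge_38_4",
      "grade_order": 2,
      "weight": 2,
      "binary_id": "temp_ge_37_2"
    },
    {
      "item_id": "yawning",
      "label": "Yawning >3 times/scoring interval",
      "grade": "more_than_3",
      "grade_order": 1,
      "weight": 1,
      "binary_id": "yawning_gt3"
    },
    {
      "item_id": "mottling",
      "label": "Mottling",
      "grade": "present",
      "grade_order": 1,
      "weight": 1,
      "binary_id": "mottling"
    },
    {
      "item_id": "nasal_stuffiness",
      "label": "Nasal stuffiness",
      "grade": "present",
      "grade_order": 1,
      "weight": 1,
      "binary_id": "nasal_stuffiness"
    },
    {
      "item_id": "sneezing",
      "label": "Sneezing >3 times/scoring interval",
      "grade": "more_than_3",
      "grade_order": 1,
      "weight": 1,
      "binary_id": "sneezing_gt3"
    },
    {
      "item_id": "nasal_flaring",
      "label": "Nasal flaring",
      "grade": "present",
      "grade_order": 1,
      "weight": 2,
      "binary_id": "nasal_flaring"
    },
    {
      "item_id": "respiratory_rate",
      "label": "Respiratory rate",
      "grade": "over_60",
      "grade_order": 1,
      "weight": 1,
      "binary_id": "resp_rate_gt60"
    },
    {
      "item_id": "respiratory_rate",
      "label": "Respiratory rate",
      "grade": "over_60_with_retractions",
      "grade_order": 2,
      "weight": 2,
      "binary_id": "resp_rate_gt60"
    },
    {
      "item_id": "excessive_sucking",
      "label": "Excessive sucking",
      "grade": "present",
      "grade_order": 1,
      "weight": 1,
      "binary_id": "excessive_sucking"
    },
    {
      "item_id": "poor_feeding",
      "label": "Poor feeding",
      "grade": "present",
      "grade_order": 1,
      "weight": 2,
      "binary_id": "poor_feeding"
    },
    {
      "item_id": "vomiting",
      "label": "Vomiting",
      "grade": "regurgitation",
      "grade_order": 1,
      "weight": 2,
      "binary_id": "regurgitation"
    },
    {
      "item_id": "vomiting",
      "label": "Vomiting",
      "grade": "projectile",
      "grade_order": 2,
      "weight": 3,
      "binary_id": "regurgitation"
    },
    {
      "item_id": "stools",
      "label": "Stools",
      "grade": "loose",
      "grade_order": 1,
      "weight": 2,
      "binary_id": "loose_watery_stools"
    },
    {
      "item_id": "stools",
      "label": "Stools",
      "grade": "watery",
      "grade_order": 2,
      "weight": 3,
      "binary_id": "loose_watery_stools"
    }
  ]
}
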