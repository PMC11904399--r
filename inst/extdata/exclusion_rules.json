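{
  "comment": "Plausibility bounds for removal of unrealistically high or low derived intakes. A record is kept only if lower < value < upper (strict) for every rule. The energy rule applies to the weekly total in kJ; all other bounds are on the daily scale in the output units (g, mg or ug per day).",
  "rules": [
    {"name": "energy",        "slot": "energy_kj",      "basis": "weekly", "lower": 15000, "upper": 120000},
    {"name": "calcium",       "slot": "calcium_mg",     "basis": "daily",  "lower": null,  "upper": 2500},
    {"name": "carbohydrate",  "slot": "carbohydrate_g", "basis": "daily",  "lower": null,  "upper": 600},
    {"name": "carotene",      "slot": "carotene_ug",    "basis": "daily",  "lower": null,  "upper": 8000},
    {"name": "cholesterol",   "slot": "cholesterol_mg", "basis": "daily",  "lower": null,  "upper": 1000},
    {"name": "folate",        "slot": "folate_ug",      "basis": "daily",  "lower": null,  "upper": 700},
    {"name": "iodine",        "slot": "iodine_ug",      "basis": "daily",  "lower": null,  "upper": 450},
    {"name": "iron",          "slot": "iron_mg",        "basis": "daily",  "lower": null,  "upper": 40},
    {"name": "magnesium",     "slot": "magnesium_mg",   "basis": "daily",  "lower": null,  "upper": 700},
    {"name": "mufa",          "slot": "mufa_g",         "basis": "daily",  "lower": null,  "upper": 70},
    {"name": "niacin_eq",     "slot": "niacin_eq_mg",   "basis": "daily",  "lower": null,  "upper": 90},
    {"name": "nmes",          "slot": "nmes_g",         "basis": "daily",  "lower": null,  "upper": 350},
    {"name": "phosphorus",    "slot": "phosphorus_mg",  "basis": "daily",  "lower": null,  "upper": 3500},
    {"name": "protein",       "slot": "protein_g",      "basis": "daily",  "lower": null,  "upper": 200},
    {"name": "retinol",       "slot": "retinol_ug",     "basis": "daily",  "lower": null,  "upper": 8000},
    {"name": "riboflavin",    "slot": "riboflavin_mg",  "basis": "daily",  "lower": null,  "upper": 7},
    {"name": "selenium",      "slot": "selenium_ug",    "basis": "daily",  "lower": null,  "upper": 350},
    {"name": "starch",        "slot": "starch_g",       "basis": "daily",  "lower": null,  "upper": 400}
  ]
}
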