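{
  "id": "england_first_screens_2019_20",
  "n_women_per_year": 240000,
  "uptake": 1,
  "per_woman_cost_perfect": 6.64,
  "per_woman_cost_imperfect": 21.82,
  "barrier_removal_fraction": 1,
  "note": "Published per-woman costs of the questionnaire + breast-density strategy (routine NHS delivery vs as delivered in the trial); England first-screen volume, 2019-20 screening year"
}
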