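{
  "chip_capacity": 48,
  "chip_cost": 1343.77,
  "controls_per_batch": 1,
  "max_batch": 95,
  "staff_fixed_minutes": 2132.65021276596,
  "staff_minutes_per_slot": 16.1748936170213,
  "staff_rate": 41,
  "collection_cost_per_sample": 2.39166666666667,
  "consumables": [
    {
      "name": "beadchip_reagent_kit",
      "box_cost": 400,
      "box_size": 48,
      "usage": 1,
      "basis": "per_sample",
      "reconstructed": true
    },
    {
      "name": "prep_consumables",
      "box_cost": 59.45,
      "box_size": 4,
      "usage": 1,
      "basis": "per_sample",
      "reconstructed": true
    }
  ]
}
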