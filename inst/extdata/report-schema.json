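{
  "title": "pocketflex pipeline report",
  "sections": {
    "flexibility": [
      "pair_labels",
      "threshold_angstrom",
      "exceedance_free_probability",
      "exceedance_tethered_probability",
      "delta_probability",
      "verdict_per_pair",
      "overall_more_flexible"
    ],
    "representatives": [
      "bin_width_angstrom",
      "modal_bin_free_angstrom",
      "modal_bin_tethered_angstrom",
      "representative_frame_free",
      "representative_frame_tethered"
    ],
    "pocket": [
      "length_pair",
      "width_pair",
      "free_length_angstrom",
      "free_width_angstrom",
      "tethered_length_angstrom",
      "tethered_width_angstrom"
    ],
    "cascade": [
      "stage_labels",
      "survivors_per_stage",
      "final_survivor_count",
      "final_survivors"
    ]
  }
}
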