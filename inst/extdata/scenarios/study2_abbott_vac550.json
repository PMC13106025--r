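{
  "name": "study2_abbott_vac550",
  "device": {
    "mode": "DDI",
    "lrl_ppm": 70,
    "mtr_ppm": 130,
    "sav_ms": 140,
    "pav_ms": 200,
    "pvarp_ms": 500,
    "pvab_ms": 150,
    "timing_base": "V_V",
    "vendor": "abbott",
    "vendor_config": {
      "pmt_detection_rate_ppm": 120,
      "detection_beats": 8,
      "vpas_stability_tol_ms": 16,
      "sav_modulation_delta_ms": -50,
      "termination_ap_delay_ms": 330
    }
  },
  "heart": {
    "vac_time_ms": 570,
    "retrograde_1to1": true,
    "atrial_myo_refractory_ms": 250,
    "sense_offset_ms": 0
  },
  "duration_ms": 60000,
  "induction": "auto"
}
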