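{
  "name": "study2_boston_vac450",
  "device": {
    "mode": "DDI",
    "lrl_ppm": 70,
    "mtr_ppm": 130,
    "sav_ms": 140,
    "pav_ms": 200,
    "pvarp_ms": 500,
    "pvab_ms": 150,
    "timing_base": "V_V",
    "vendor": "boston",
    "vendor_config": {
      "detection_cycles": 16,
      "stability_window_ms": 32,
      "termination_pvarp_ext_ms": 500,
      "afr_rate_ppm": 170
    }
  },
  "heart": {
    "vac_time_ms": 468,
    "retrograde_1to1": true,
    "atrial_myo_refractory_ms": 250,
    "sense_offset_ms": 0
  },
  "duration_ms": 60000,
  "induction": "auto"
}
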