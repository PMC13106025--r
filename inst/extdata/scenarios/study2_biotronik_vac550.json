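{
  "name": "study2_biotronik_vac550",
  "device": {
    "mode": "DDI",
    "lrl_ppm": 70,
    "mtr_ppm": 130,
    "sav_ms": 140,
    "pav_ms": 200,
    "pvarp_ms": 600,
    "pvab_ms": 150,
    "timing_base": "V_V",
    "vendor": "biotronik",
    "vendor_config": {
      "va_criterion_ms": 350,
      "detection_beats": 8,
      "deviation_tol_ms": 16,
      "sav_modulation_delta_ms": -50,
      "post_ar_ap_delay_ms": 350
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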