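# shared fixture builders: all inputs are generated in code, no stored data

study1_heart <- function(vac_ms, retro = TRUE) {
  heart_params(vac_time_ms = vac_ms, retrograde_1to1 = retro)
}

# vendor-neutral DDD device used by the timing-core oracle checks
bare_ddd <- function(mtr_ppm = 130L, sav_ms = 140L, pvarp_ms = 280L, ...) {
  device_params(mode = "DDD", lrl_ppm = 70L, mtr_ppm = mtr_ppm,
                sav_ms = sav_ms, pav_ms = 200L, pvarp_ms = pvarp_ms,
                vendor = "none", ...)
}

# closed-form steady PMT cycle length: the loop locks at the larger of
# VAC + SAV and the upper-rate interval
oracle_cycle <- function(vac_ms, sav_ms, mtr_ppm) {
  max(vac_ms + sav_ms, ppm_to_interval_ms(mtr_ppm))
}

vv_intervals <- function(log) diff(log$time_ms[log$marker == "VP"])
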