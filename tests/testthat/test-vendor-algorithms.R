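# detection / termination outcomes for each manufacturer model, run through
# the Study-1 protocol (DDD, LRL 70, MTR 130, SAV 140, PAV 200/205)

expect_study1 <- function(vendor, vac, overrides, detected, terminated,
                          label = NULL) {
  out <- run_study1(vendor, vac, overrides, duration_ms = 30000L)
  lab <- label %||% sprintf("%s vac=%d", vendor, vac)
  expect_identical(out$pmt_detected, detected, label = paste(lab, "detected"))
  expect_identical(out$pmt_terminated, terminated,
                   label = paste(lab, "terminated"))
  invisible(out)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("Abbott PMT Response: rate-gated detection, termination by atrial pacing", {
  expect_study1("abbott", 468, list(pmt_detection_rate_ppm = 95), TRUE, TRUE)
  expect_study1("abbott", 468, list(pmt_detection_rate_ppm = 100), FALSE, FALSE)
  # 710 ms loop (84.5 bpm) is slower than the 90 bpm floor
  expect_study1("abbott", 570, list(pmt_detection_rate_ppm = 90), FALSE, FALSE)
  # shortening the SAV to 90 ms brings the loop above the detection rate
  out <- expect_study1("abbott", 570,
                       list(pmt_detection_rate_ppm = 90, sav_ms = 90),
                       TRUE, TRUE)
  expect_identical(out$steady_cycle_ms, 660L)
  # quiescent without retrograde conduction
  out <- run_study1("abbott", 468,
                    list(pmt_detection_rate_ppm = 90, retrograde_1to1 = FALSE),
                    duration_ms = 30000L)
  expect_false(out$pmt_induced)
  expect_identical(sum(out$log$marker == "PMT_SUSPECT"), 0L)
  # the termination atrial pace always captures (>= tissue refractory)
  log <- run_study1("abbott", 468, list(pmt_detection_rate_ppm = 95),
                    duration_ms = 30000L)$log
  term_t <- log$time_ms[log$marker == "PMT_TERMINATE"]
  expect_gt(length(term_t), 0L)
  expect_true(all(term_t %in% log$time_ms[log$marker == "AP"]))
})

test_that("BIOTRONIK PMT Protection: VA criterion bound and one-cycle PVARP extension", {
  out <- expect_study1("biotronik", 468, list(va_criterion_ms = 500), TRUE, TRUE)
  ext <- out$log[out$log$marker == "PVARP_EXT", ]
  expect_gt(nrow(ext), 0L)
  expect_true(all(grepl("550", ext$annotation)))  # criterion + 50
  expect_study1("biotronik", 570, list(va_criterion_ms = 500), FALSE, FALSE)
  expect_study1("biotronik", 468, list(), FALSE, FALSE)  # default criterion 350
})

test_that("Boston PMT Termination: MTR-locked counting, no verification, 500 ms coverage", {
  expect_study1("boston", 468, list(), FALSE, FALSE)  # 608 ms < MTR interval? no flags
  out <- expect_study1("boston", 468, list(mtr_ppm = 95), TRUE, TRUE)
  # detection is declared at the atrial sense committing the 16th
  # consecutive upper-rate cycle; that VP is delivered one MTR interval on
  first_detect <- out$log$time_ms[out$log$marker == "PMT_DETECT"][1L]
  n_mt <- sum(grepl("VP-MT", out$log$annotation) &
                out$log$time_ms <= first_detect + ppm_to_interval_ms(95))
  expect_gte(n_mt, 16L)
  # no SAV modulation anywhere (no verification phase)
  expect_false(any(grepl("SAV modulated", out$log$annotation)))
  # detected but not terminated: 570 ms exceeds the 500 ms extension
  out <- expect_study1("boston", 570, list(mtr_ppm = 80), TRUE, FALSE)
  expect_gt(sum(out$log$marker == "PVARP_EXT"), 0L)
  expect_true(out$pmt_induced)  # the PMT continues
})

test_that("Medtronic PMT Intervention: strict 400 ms ceiling", {
  expect_study1("medtronic", 468, list(), FALSE, FALSE)
  expect_study1("medtronic", 570, list(), FALSE, FALSE)
  out <- expect_study1("medtronic", 380, list(), TRUE, TRUE)
  expect_identical(out$steady_cycle_ms, 520L)  # closed-form 380 + 140
  expect_study1("medtronic", 400, list(), FALSE, FALSE)  # boundary exclusive
  expect_study1("medtronic", 399, list(), TRUE, TRUE)
})

test_that("MicroPort Anti-PMT: inclusive 470 ms limit, 500 ms ARP after the next VP", {
  expect_study1("microport", 468, list(), TRUE, TRUE)
  expect_study1("microport", 570, list(), FALSE, FALSE)
  expect_study1("microport", 470, list(), TRUE, TRUE)   # boundary inclusive
  expect_study1("microport", 471, list(), FALSE, FALSE)
})

test_that("post-AR atrial pacing responses differ by manufacturer", {
  # Abbott: no deferral -> non-capture -> sustained RNRVAS
  s <- run_study3("abbott", duration_ms = 30000L)
  expect_false(s$ap_delay_applied)
  expect_true(s$rnrvas)
  ep <- detect_rnrvas(s$log)
  expect_gt(nrow(ep), 0L)
  expect_gte(max(ep$n_cycles), 3L)
  # the 189 ms escape-AP coupling fails to capture
  nc <- s$log[s$log$marker == "AP_NONCAPTURE", ]
  expect_true(all(grepl("189 ms", nc$annotation)))

  # Medtronic NCAP: every AP >= 300 ms after the refractory sense; captures;
  # PAV alternates with A-A timing
  s <- run_study3("medtronic", duration_ms = 30000L)
  expect_true(s$ap_delay_applied)
  expect_false(s$rnrvas)
  expect_identical(s$ap_delay_pattern, "alternating PAV")
  lg <- s$log
  expect_identical(sum(lg$marker == "AP_NONCAPTURE"), 0L)
  ar_t <- lg$time_ms[lg$marker == "AR"]
  for (a in lg$time_ms[lg$marker == "AP"]) {
    prev_ar <- ar_t[ar_t < a]
    if (length(prev_ar)) expect_gte(a - max(prev_ar), 300L)
  }

  # Boston AFR: constant V-V at the lower rate, uniformly shortened PAV
  s <- run_study3("boston", duration_ms = 30000L)
  expect_true(s$ap_delay_applied)
  expect_false(s$rnrvas)
  expect_identical(s$ap_delay_pattern, "shortened PAV")
  expect_true(all(tail(vv_intervals(s$log), 10) == 857L))

  # BIOTRONIK: PAV floor of 75 ms; at LRL 70 the V-V prolongs beyond the
  # lower-rate interval (468 + 350 + 75 > 857)
  s <- run_study3("biotronik", duration_ms = 30000L)
  expect_true(s$ap_delay_applied)
  expect_false(s$rnrvas)
  expect_true(all(tail(vv_intervals(s$log), 10) == 893L))
  # ... but not when the lower rate is slow enough (60 ppm -> 1000 ms)
  s <- run_study3("biotronik", overrides = list(lrl_ppm = 60L),
                  duration_ms = 30000L)
  expect_true(all(tail(vv_intervals(s$log), 10) == 1000L))
})

test_that("MicroPort DDI semantics: Ar markers behave as inhibiting senses", {
  for (vac in c(468L, 570L)) {
    s <- run_study2("microport", vac, duration_ms = 30000L)
    lg <- s$log
    expect_false(s$ar_detected)  # no true refractory sensing
    expect_true(any(lg$marker == "AR"))
    expect_true(all(grepl("functional sense",
                          lg$annotation[lg$marker == "AR"])))
    # atrial pacing inhibited while retrograde 1:1 persists
    expect_identical(sum(lg$marker == "AP" & lg$time_ms > 2000L), 0L)
    expect_true(all(tail(vv_intervals(lg), 10) == 857L))  # VVI-like
  }
  # retrograde stops -> AP resumes at the lower-rate escape
  d <- protocol_device("microport", 2)
  log <- run_simulation(d, study1_heart(468, retro = FALSE), 20000)
  expect_gt(sum(log$marker == "AP"), 5L)
})

test_that("all detectors are quiescent without retrograde conduction", {
  for (v in c("abbott", "biotronik", "boston", "medtronic", "microport")) {
    out <- run_study1(v, 468, list(retrograde_1to1 = FALSE),
                      duration_ms = 20000L)
    expect_identical(sum(out$log$marker %in%
                           c("PMT_SUSPECT", "PMT_DETECT", "PMT_TERMINATE")),
                     0L, label = v)
  }
})

test_that("vendor config constructors enforce programmable limits", {
  expect_error(abbott_config(pmt_detection_rate_ppm = 85), ">= 90")
  expect_error(abbott_config(pmt_detection_rate_ppm = 93), "5-ppm grid")
  expect_error(biotronik_config(va_criterion_ms = 510), "<= 500")
  expect_identical(vendor_max_pvarp("biotronik"), 600L)
  expect_identical(vendor_max_pvarp("abbott"), 500L)
  expect_true(is.na(vendor_max_pvarp("microport")))
  expect_identical(vendor_timing_base("medtronic"), "A_A")
  expect_identical(vendor_timing_base("boston"), "V_V")
})
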