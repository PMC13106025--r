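test_that("study outcomes populate per protocol and respect their invariants", {
  out <- run_study1("medtronic", 570, duration_ms = 30000L)
  expect_true(out$pmt_induced)
  expect_false(out$pmt_detected)
  expect_false(out$pmt_terminated)
  expect_identical(out$steady_cycle_ms, 710L)

  out <- run_study1("abbott", 570,
                    list(pmt_detection_rate_ppm = 90, sav_ms = 90),
                    duration_ms = 30000L)
  expect_true(out$pmt_detected && out$pmt_terminated)

  out <- run_study1("boston", 468, list(retrograde_1to1 = FALSE),
                    duration_ms = 30000L)
  expect_false(out$pmt_induced)

  # pmt_terminated implies pmt_detected by construction across a spread
  for (v in c("abbott", "boston", "microport")) {
    o <- run_study1(v, 468, duration_ms = 30000L)
    expect_true(!o$pmt_terminated || o$pmt_detected)
  }

  expect_true(run_study2("biotronik", 570, duration_ms = 30000L)$ar_detected)
  expect_false(run_study2("abbott", 570, duration_ms = 30000L)$ar_detected)
  expect_false(run_study2("microport", 468, duration_ms = 30000L)$ar_detected)

  s3 <- run_study3("abbott", duration_ms = 30000L)
  expect_false(s3$ap_delay_applied)
  expect_true(s3$rnrvas)
  s3 <- run_study3("boston", duration_ms = 30000L)
  expect_true(s3$ap_delay_applied)
  expect_false(s3$rnrvas)
  # rnrvas implies no AP delay across the vendor set
  for (v in c("abbott", "biotronik", "boston", "medtronic")) {
    o <- run_study3(v, duration_ms = 30000L)
    expect_true(!isTRUE(o$rnrvas) || !isTRUE(o$ap_delay_applied), label = v)
  }
})

test_that("parameter sweeps find the programmable boundaries", {
  expect_identical(sweep_parameter("abbott", 468, "detection_rate",
                                   duration_ms = 30000L), 95L)
  expect_identical(sweep_parameter("boston", 570, "mtr",
                                   duration_ms = 30000L), 80L)
  expect_identical(sweep_parameter("abbott", 570, "sav",
                                   overrides = list(pmt_detection_rate_ppm = 90L),
                                   duration_ms = 30000L), 90L)
  expect_identical(sweep_parameter("biotronik", 468, "va_criterion",
                                   duration_ms = 30000L), 500L)
  # consistent with the closed-form boundary: largest grid rate whose
  # interval exceeds VAC + SAV
  expect_true(ppm_to_interval_ms(95) > 468 + 140 &&
                ppm_to_interval_ms(100) < 468 + 140)
  # nothing qualifies -> NA
  expect_true(is.na(sweep_parameter("biotronik", 570, "va_criterion",
                                    duration_ms = 30000L)))
})

test_that("detect_pmt distinguishes sustained tracking loops", {
  log <- run_simulation(bare_ddd(), study1_heart(570), 30000)
  p <- detect_pmt(log)
  expect_true(p$sustained)
  expect_identical(p$steady_cycle_ms, 710L)

  # DDI never sustains a tracked loop
  d <- device_params(mode = "DDI", pvarp_ms = 500, vendor = "none")
  expect_false(detect_pmt(run_simulation(d, study1_heart(570), 30000))$sustained)

  # PVARP longer than the VAC prevents induction altogether
  d <- protocol_device("biotronik", 1, list(pvarp_ms = 600L))
  expect_false(detect_pmt(run_simulation(d, study1_heart(570), 30000))$sustained)
})

test_that("detect_rnrvas returns maximal episodes only for the non-capture loop", {
  abbott <- run_study3("abbott", duration_ms = 30000L)$log
  ep <- detect_rnrvas(abbott)
  expect_gt(nrow(ep), 0L)
  expect_true(all(ep$n_cycles >= 3L))
  expect_identical(nrow(detect_rnrvas(run_study3("medtronic",
                                                 duration_ms = 30000L)$log)),
                   0L)
  no_nc <- run_simulation(bare_ddd(), study1_heart(468, retro = FALSE), 20000)
  expect_identical(nrow(detect_rnrvas(no_nc)), 0L)
})

test_that("outcomes are invariant to simulation duration beyond the protocol length", {
  for (v in c("abbott", "microport")) {
    a <- run_study1(v, 468, list(pmt_detection_rate_ppm = 95L)[v == "abbott"],
                    duration_ms = 60000L)
    b <- run_study1(v, 468, list(pmt_detection_rate_ppm = 95L)[v == "abbott"],
                    duration_ms = 120000L)
    expect_identical(a$pmt_detected, b$pmt_detected)
    expect_identical(a$pmt_terminated, b$pmt_terminated)
    expect_identical(a$steady_cycle_ms, b$steady_cycle_ms)
  }
})

test_that("a detuned setting flips its matrix cell and is reported as a mismatch", {
  # with the VA criterion left at its 350 ms default the BIOTRONIK study-1
  # cells must read No; verify via the same cell logic the report uses
  out <- run_study1("biotronik", 468, duration_ms = 30000L)
  expect_false(out$pmt_detected)
  # and a doctored expected matrix produces a reported mismatch
  tmp <- tempfile(fileext = ".csv")
  exp <- utils::read.csv(system.file("extdata", "table1_expected.csv",
                                     package = "pacesim"),
                         na.strings = character(0))
  exp$value[exp$vendor == "medtronic" & exp$study == 1 &
              exp$field == "pmt_detection"] <- "Yes"
  utils::write.csv(exp, tmp, row.names = FALSE, quote = FALSE)
  rep <- make_table1(duration_ms = 30000L, expected_path = tmp)
  expect_identical(nrow(rep$mismatches), 2L)
  expect_true(all(rep$mismatches$vendor == "medtronic"))
})
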