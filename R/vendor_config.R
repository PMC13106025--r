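#' Manufacturer algorithm configurations
#'
#' Each constructor returns the programmable settings of one manufacturer's
#' anti-PMT / atrial-protection feature set as a validated list. Values not
#' published by the manufacturers are package assumptions, chosen so that the
#' documented bench behaviours reproduce; all are configurable.
#'
#' @name vendor_configs
NULL

#' @describeIn vendor_configs Abbott "PMT Response": detection requires 8
#'   consecutive A-A intervals faster than the programmed detection rate plus
#'   a stable VP-AS interval; verification shortens the SAV for one beat; the
#'   loop is terminated by suppressing the tracked VP and delivering atrial
#'   pacing after the atrial sense. No post-AR atrial-pacing delay feature.
#' @param pmt_detection_rate_ppm Abbott PMT detection rate; programmable on a
#'   5-ppm grid with a minimum of 90 ppm. Default 120.
#' @param detection_beats consecutive qualifying beats required (8).
#' @param vpas_stability_tol_ms stability band (+/-) on the VP-AS interval.
#' @param sav_modulation_delta_ms SAV change applied for the one verification
#'   beat (negative shortens).
#' @param termination_ap_delay_ms AS-to-AP interval of the termination atrial
#'   pace.
#' @export
abbott_config <- function(pmt_detection_rate_ppm = 120L,
                          detection_beats = 8L,
                          vpas_stability_tol_ms = 16L,
                          sav_modulation_delta_ms = -50L,
                          termination_ap_delay_ms = 330L) {
  pmt_detection_rate_ppm <- as_int1(pmt_detection_rate_ppm,
                                    "pmt_detection_rate_ppm")
  if (pmt_detection_rate_ppm < 90L)
    stop("abbott: pmt_detection_rate_ppm must be >= 90 (minimum programmable value)",
         call. = FALSE)
  if (pmt_detection_rate_ppm %% 5L != 0L)
    stop("abbott: pmt_detection_rate_ppm must lie on the 5-ppm grid",
         call. = FALSE)
  structure(list(vendor = "abbott",
                 pmt_detection_rate_ppm = pmt_detection_rate_ppm,
                 detection_beats = as_int1(detection_beats, "detection_beats"),
                 vpas_stability_tol_ms = as_int1(vpas_stability_tol_ms,
                                                 "vpas_stability_tol_ms"),
                 sav_modulation_delta_ms = as_int1(sav_modulation_delta_ms,
                                                   "sav_modulation_delta_ms"),
                 termination_ap_delay_ms = as_int1(termination_ap_delay_ms,
                                                   "termination_ap_delay_ms"),
                 max_pvarp_ms = 500L),
            class = c("abbott_config", "vendor_config"))
}

#' @describeIn vendor_configs BIOTRONIK "PMT Protection": 8 consecutive VP-AS
#'   intervals below the VA criterion with small deviation, SAV-modulation
#'   verification, then a one-cycle PVARP extension 50 ms beyond the VA
#'   criterion. Post-AR atrial pacing is deferred (Atrial Upper Rate-like
#'   behaviour) with a 75-ms floor on the paced AV delay.
#' @param va_criterion_ms detection threshold on the VP-AS interval;
#'   maximum programmable value 500 ms. Default 350.
#' @param deviation_tol_ms stability band (+/-) on the VP-AS interval.
#' @param post_ar_ap_delay_ms delay from a refractory atrial sense to the
#'   earliest permitted atrial pace.
#' @export
biotronik_config <- function(va_criterion_ms = 350L,
                             detection_beats = 8L,
                             deviation_tol_ms = 16L,
                             sav_modulation_delta_ms = -50L,
                             post_ar_ap_delay_ms = 350L) {
  va_criterion_ms <- as_int1(va_criterion_ms, "va_criterion_ms")
  if (va_criterion_ms > 500L)
    stop("biotronik: va_criterion_ms must be <= 500 (maximum programmable value)",
         call. = FALSE)
  if (va_criterion_ms %% 10L != 0L)
    stop("biotronik: va_criterion_ms must lie on the 10-ms grid", call. = FALSE)
  structure(list(vendor = "biotronik",
                 va_criterion_ms = va_criterion_ms,
                 detection_beats = as_int1(detection_beats, "detection_beats"),
                 deviation_tol_ms = as_int1(deviation_tol_ms, "deviation_tol_ms"),
                 sav_modulation_delta_ms = as_int1(sav_modulation_delta_ms,
                                                   "sav_modulation_delta_ms"),
                 termination_pvarp_ext_margin_ms = 50L,
                 post_ar_ap_delay_ms = as_int1(post_ar_ap_delay_ms,
                                               "post_ar_ap_delay_ms"),
                 min_pav_ms = 75L,
                 max_pvarp_ms = 600L),
            class = c("biotronik_config", "vendor_config"))
}

#' @describeIn vendor_configs Boston Scientific "PMT Termination": counts 16
#'   consecutive ventricular paces delivered at the maximum tracking rate
#'   after an atrial sense, with the VP-AS interval confined to a 32-ms
#'   window referenced to the second flagged cycle; no AV-delay verification
#'   phase. Termination is a one-cycle PVARP extension to 500 ms. Post-AR
#'   atrial pacing is deferred by the atrial flutter response (AFR) window.
#' @param detection_cycles consecutive upper-rate cycles required (16).
#' @param stability_window_ms width of the VP-AS acceptance window.
#' @param termination_pvarp_ext_ms one-cycle PVARP extension on detection.
#' @param afr_rate_ppm atrial flutter response rate; protection window is
#'   `round(60000 / afr_rate_ppm)` ms (170 ppm -> 353 ms).
#' @export
boston_config <- function(detection_cycles = 16L,
                          stability_window_ms = 32L,
                          termination_pvarp_ext_ms = 500L,
                          afr_rate_ppm = 170L) {
  structure(list(vendor = "boston",
                 detection_cycles = as_int1(detection_cycles, "detection_cycles"),
                 stability_window_ms = as_int1(stability_window_ms,
                                               "stability_window_ms"),
                 termination_pvarp_ext_ms = as_int1(termination_pvarp_ext_ms,
                                                    "termination_pvarp_ext_ms"),
                 afr_rate_ppm = as_int1(afr_rate_ppm, "afr_rate_ppm"),
                 min_pav_ms = 30L,
                 max_pvarp_ms = 500L),
            class = c("boston_config", "vendor_config"))
}

#' @describeIn vendor_configs Medtronic "PMT Intervention": qualifying beats
#'   require a device-observed VP-AS interval strictly below 400 ms, so
#'   retrograde conduction at or beyond 400 ms is undetectable. The
#'   hypothetical intervention (one-cycle PVARP extension to 400 ms) is
#'   included so the detector's action is exercisable below the limit.
#'   Post-AR atrial pacing is deferred by the non-competitive atrial pacing
#'   (NCAP) window.
#' @param vac_detection_limit_ms strict upper bound on detectable VP-AS (400).
#' @param intervention_pvarp_ext_ms one-cycle PVARP extension on detection.
#' @param ncap_window_ms minimum interval from a refractory atrial sense to
#'   the next atrial pace.
#' @export
medtronic_config <- function(vac_detection_limit_ms = 400L,
                             detection_beats = 8L,
                             intervention_pvarp_ext_ms = 400L,
                             ncap_window_ms = 300L) {
  structure(list(vendor = "medtronic",
                 vac_detection_limit_ms = as_int1(vac_detection_limit_ms,
                                                  "vac_detection_limit_ms"),
                 detection_beats = as_int1(detection_beats, "detection_beats"),
                 intervention_pvarp_ext_ms = as_int1(intervention_pvarp_ext_ms,
                                                     "intervention_pvarp_ext_ms"),
                 ncap_window_ms = as_int1(ncap_window_ms, "ncap_window_ms"),
                 min_pav_ms = 30L,
                 max_pvarp_ms = 500L),
            class = c("medtronic_config", "vendor_config"))
}

#' @describeIn vendor_configs MicroPort CRM "Anti-PMT": 8 consecutive stable
#'   VP-AS intervals, each at most 470 ms (inclusive), SAV-modulation
#'   verification, then a 500-ms atrial refractory period applied after the
#'   next ventricular pace. The WARAD window substitutes for a PVARP and is
#'   inactive in DDI mode, where every atrial sense is annotated "Ar" but
#'   behaves as an ordinary inhibiting sense.
#' @param stability_tol_ms stability band (+/-) on the VP-AS interval.
#' @param termination_arp_ms atrial refractory period applied after the next
#'   VP on confirmed detection.
#' @export
microport_config <- function(vac_detection_limit_ms = 470L,
                             detection_beats = 8L,
                             stability_tol_ms = 16L,
                             sav_modulation_delta_ms = -50L,
                             termination_arp_ms = 500L) {
  structure(list(vendor = "microport",
                 vac_detection_limit_ms = as_int1(vac_detection_limit_ms,
                                                  "vac_detection_limit_ms"),
                 detection_beats = as_int1(detection_beats, "detection_beats"),
                 stability_tol_ms = as_int1(stability_tol_ms, "stability_tol_ms"),
                 sav_modulation_delta_ms = as_int1(sav_modulation_delta_ms,
                                                   "sav_modulation_delta_ms"),
                 termination_arp_ms = as_int1(termination_arp_ms,
                                              "termination_arp_ms"),
                 max_pvarp_ms = NA_integer_),
            class = c("microport_config", "vendor_config"))
}

pacesim_vendors <- c("none", "abbott", "biotronik", "boston", "medtronic",
                     "microport")

#' Default configuration for a vendor model
#'
#' @param vendor one of `"none"`, `"abbott"`, `"biotronik"`, `"boston"`,
#'   `"medtronic"`, `"microport"`. `"none"` is the vendor-neutral timing core
#'   with no anti-PMT or atrial-protection layer.
#' @return a `vendor_config` object, or `NULL` for `"none"`.
#' @export
vendor_default_config <- function(vendor) {
  vendor <- match.arg(vendor, pacesim_vendors)
  switch(vendor,
         none = NULL,
         abbott = abbott_config(),
         biotronik = biotronik_config(),
         boston = boston_config(),
         medtronic = medtronic_config(),
         microport = microport_config())
}

#' Maximum programmable PVARP for a vendor
#'
#' 500 ms for Abbott, Boston Scientific and Medtronic; 600 ms for BIOTRONIK;
#' `NA` for MicroPort CRM, whose WARAD window is not an extendable PVARP.
#'
#' @inheritParams vendor_default_config
#' @export
vendor_max_pvarp <- function(vendor) {
  vendor <- match.arg(vendor, pacesim_vendors)
  switch(vendor,
         none = NA_integer_,
         abbott = 500L,
         biotronik = 600L,
         boston = 500L,
         medtronic = 500L,
         microport = NA_integer_)
}

# protection window from a refractory atrial sense to the earliest AP,
# or NA when the vendor has no post-AR atrial pacing delay feature
post_ar_delay_window <- function(vendor, cfg) {
  switch(vendor,
         biotronik = cfg$post_ar_ap_delay_ms,
         boston = ppm_to_interval_ms(cfg$afr_rate_ppm),
         medtronic = cfg$ncap_window_ms,
         NA_integer_)
}

# floor on the paced AV delay used when an AP is deferred
vendor_min_pav <- function(vendor, cfg, pav_ms) {
  mp <- if (!is.null(cfg)) cfg$min_pav_ms else NULL
  if (is.null(mp)) pav_ms else mp
}

#' Default timing base for a vendor
#'
#' Medtronic paces on A-A timing (the atrial escape interval is referenced to
#' the last atrial paced/sensed event); the other models here use V-V timing.
#'
#' @inheritParams vendor_default_config
#' @export
vendor_timing_base <- function(vendor) {
  vendor <- match.arg(vendor, pacesim_vendors)
  if (vendor == "medtronic") "A_A" else "V_V"
}
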