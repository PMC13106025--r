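#' Programmed device parameters
#'
#' Bradycardia settings of a dual-chamber pacemaker plus the selected
#' manufacturer algorithm model. Rates are converted once to integer
#' millisecond intervals (`round(60000 / ppm)`) and all subsequent timing is
#' exact integer arithmetic.
#'
#' @param mode pacing mode, `"DDD"` (atrial tracking) or `"DDI"`
#'   (non-tracking; atrial senses inhibit atrial pacing but never start a
#'   sensed AV delay).
#' @param lrl_ppm lower rate limit, pulses/min.
#' @param mtr_ppm maximum tracking rate, pulses/min; must be >= `lrl_ppm`.
#' @param sav_ms sensed AV delay, ms; must be <= `pav_ms`.
#' @param pav_ms paced AV delay, ms.
#' @param pvarp_ms post-ventricular atrial refractory period, ms. Atrial
#'   senses inside it are classified as refractory (AR) and never tracked.
#' @param pvab_ms post-ventricular atrial blanking, ms; atrial activity
#'   inside it is invisible to the device. Must be <= `pvarp_ms`.
#' @param timing_base `"V_V"` (atrial escape referenced to the last
#'   ventricular pace) or `"A_A"` (referenced to the last atrial paced/sensed
#'   event). Default per vendor, see [vendor_timing_base()].
#' @param vendor manufacturer model; see [vendor_default_config()].
#' @param vendor_config optional `vendor_config` object; defaults to the
#'   vendor's factory settings.
#' @return an object of class `device_params`.
#' @export
#' @examples
#' device_params(mode = "DDD", lrl_ppm = 70, mtr_ppm = 130,
#'               sav_ms = 140, pav_ms = 200, vendor = "abbott")
device_params <- function(mode = c("DDD", "DDI"),
                          lrl_ppm = 70L, mtr_ppm = 130L,
                          sav_ms = 140L, pav_ms = 200L,
                          pvarp_ms = 280L, pvab_ms = 150L,
                          timing_base = NULL,
                          vendor = "none",
                          vendor_config = NULL) {
  mode <- match.arg(mode)
  vendor <- match.arg(vendor, pacesim_vendors)
  if (is.null(vendor_config)) vendor_config <- vendor_default_config(vendor)
  if (!is.null(vendor_config)) {
    if (!inherits(vendor_config, "vendor_config"))
      stop("vendor_config must be built with one of the *_config() constructors",
           call. = FALSE)
    if (vendor_config$vendor != vendor)
      stop(sprintf("vendor_config is for '%s' but vendor is '%s'",
                   vendor_config$vendor, vendor), call. = FALSE)
  }
  if (is.null(timing_base)) timing_base <- vendor_timing_base(vendor)
  timing_base <- match.arg(timing_base, c("V_V", "A_A"))

  lrl_ppm <- as_int1(lrl_ppm, "lrl_ppm")
  mtr_ppm <- as_int1(mtr_ppm, "mtr_ppm")
  sav_ms <- as_int1(sav_ms, "sav_ms")
  pav_ms <- as_int1(pav_ms, "pav_ms")
  pvarp_ms <- as_int1(pvarp_ms, "pvarp_ms")
  pvab_ms <- as_int1(pvab_ms, "pvab_ms")

  problems <- character(0)
  if (lrl_ppm <= 0L || mtr_ppm <= 0L)
    problems <- c(problems, "rates must be > 0 ppm")
  if (lrl_ppm > mtr_ppm)
    problems <- c(problems,
                  sprintf("lrl_ppm (%d) must be <= mtr_ppm (%d)", lrl_ppm, mtr_ppm))
  if (sav_ms <= 0L || pav_ms <= 0L || pvarp_ms <= 0L || pvab_ms <= 0L)
    problems <- c(problems, "all intervals must be > 0 ms")
  if (sav_ms > pav_ms)
    problems <- c(problems,
                  sprintf("sav_ms (%d) must be <= pav_ms (%d)", sav_ms, pav_ms))
  if (pvab_ms > pvarp_ms)
    problems <- c(problems,
                  sprintf("pvab_ms (%d) must be <= pvarp_ms (%d)", pvab_ms, pvarp_ms))
  if (length(problems)) {
    stop("invalid device parameters:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  structure(list(mode = mode,
                 lrl_ppm = lrl_ppm, mtr_ppm = mtr_ppm,
                 lrl_interval_ms = ppm_to_interval_ms(lrl_ppm),
                 mtr_interval_ms = ppm_to_interval_ms(mtr_ppm),
                 sav_ms = sav_ms, pav_ms = pav_ms,
                 pvarp_ms = pvarp_ms, pvab_ms = pvab_ms,
                 timing_base = timing_base,
                 vendor = vendor,
                 vendor_config = vendor_config),
            class = "device_params")
}

#' @export
print.device_params <- function(x, ...) {
  cat(sprintf(
    paste0("<device_params> %s, LRL %d ppm (%d ms), MTR %d ppm (%d ms), ",
           "SAV %d, PAV %d, PVARP %d, PVAB %d, %s timing, vendor %s\n"),
    x$mode, x$lrl_ppm, x$lrl_interval_ms, x$mtr_ppm, x$mtr_interval_ms,
    x$sav_ms, x$pav_ms, x$pvarp_ms, x$pvab_ms,
    sub("_", "-", x$timing_base), x$vendor))
  invisible(x)
}

#' Classify an atrial sense relative to the ventricular refractory windows
#'
#' Pure classification used by the timing engine: an atrial activation
#' visible to the device at `t` is blanked inside the post-ventricular
#' atrial blanking, a refractory sense (AR) inside the effective PVARP,
#' and otherwise a tracked sense in DDD (it starts the sensed AV delay,
#' subject to the maximum tracking rate) or a non-refractory inhibiting
#' sense in DDI.
#'
#' @param t device-observed sense time, ms.
#' @param last_vp time of the preceding ventricular pace, ms.
#' @param device a [device_params()] object.
#' @param pvarp_ms effective PVARP for this cycle (defaults to the programmed
#'   base; pass the extended value during a one-cycle extension).
#' @return one of `"blanked"`, `"refractory_sense"`, `"tracked_sense"`,
#'   `"nonrefractory_sense"`.
#' @export
#' @examples
#' d <- device_params(mode = "DDI", pvarp_ms = 500)
#' classify_atrial_sense(1468, 1000, d)  # "refractory_sense"
classify_atrial_sense <- function(t, last_vp, device,
                                  pvarp_ms = device$pvarp_ms) {
  rel <- as_int1(t, "t") - as_int1(last_vp, "last_vp")
  if (rel < device$pvab_ms) return("blanked")
  if (rel < pvarp_ms) return("refractory_sense")
  if (device$mode == "DDD") "tracked_sense" else "nonrefractory_sense"
}
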