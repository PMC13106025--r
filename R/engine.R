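#' Run the coupled device-heart simulation
#'
#' Deterministic discrete-event loop in integer milliseconds. Three pending
#' timers drive the simulation: the device's atrial escape (AP due), the
#' scheduled ventricular pace (VP due), and any in-flight retrograde atrial
#' wavefront. Coincident events are processed heart-activation first, then
#' device pacing; marker-log ties are ordered A < V < DEVICE.
#'
#' With `induction = "auto"` the run opens with the device's own atrial pace
#' at t = 0; because the substrate has sinus arrest and complete AV block,
#' every cycle is AP/AS -> AV delay -> VP, and PMT self-initiates in DDD mode
#' as soon as a retrograde sense escapes the PVARP. With `"none"` the run
#' opens at the first atrial escape instead (as if a ventricular event at
#' t = 0 started the timing cycle); the rhythm is identical up to a shift.
#'
#' @param device a [device_params()] object.
#' @param heart a [heart_params()] object.
#' @param duration_ms simulated time, ms; at least 10 lower-rate cycles.
#' @param induction `"auto"` (default) or `"none"`, see Details.
#' @return a `pacing_log`: a data frame with columns `time_ms`, `channel`
#'   (`A`, `V` or `DEVICE`), `marker` and `annotation`, carrying the run
#'   parameters and a `converged` flag as attributes. Markers: `AP`,
#'   `AP_NONCAPTURE`, `AS`, `AR`, `AS_BLANKED`, `VP`, `PVARP_EXT`,
#'   `PMT_SUSPECT`, `PMT_DETECT`, `PMT_TERMINATE`, `AP_DELAYED`.
#' @export
#' @examples
#' log <- run_simulation(device_params(vendor = "none"),
#'                       heart_params(vac_time_ms = 570), duration_ms = 15000)
#' detect_pmt(log)$steady_cycle_ms  # 710
run_simulation <- function(device, heart, duration_ms = 60000,
                           induction = c("auto", "none")) {
  induction <- match.arg(induction)
  stopifnot(inherits(device, "device_params"), inherits(heart, "heart_params"))
  duration_ms <- as_int1(duration_ms, "duration_ms")
  if (duration_ms < 10L * device$lrl_interval_ms)
    stop("duration_ms must cover at least 10 lower-rate cycles", call. = FALSE)

  mode <- device$mode
  lrl_int <- device$lrl_interval_ms
  mtr_int <- device$mtr_interval_ms
  sav <- device$sav_ms
  pav <- device$pav_ms
  pvarp <- device$pvarp_ms
  pvab <- device$pvab_ms
  vendor <- device$vendor
  vcfg <- device$vendor_config
  ar_delay <- post_ar_delay_window(vendor, vcfg)
  minpav <- vendor_min_pav(vendor, vcfg, pav)
  off <- heart$sense_offset_ms
  vac <- heart$vac_time_ms
  myo <- heart$atrial_myo_refractory_ms

  ## ---- marker log buffers (grown by doubling) ----
  cap <- 512L
  lg_t <- integer(cap); lg_ch <- character(cap)
  lg_mk <- character(cap); lg_an <- character(cap)
  n_ev <- 0L
  emit <- function(t, ch, mk, an = "") {
    n_ev <<- n_ev + 1L
    if (n_ev > length(lg_t)) {
      pad <- length(lg_t)
      lg_t <<- c(lg_t, integer(pad)); lg_ch <<- c(lg_ch, character(pad))
      lg_mk <<- c(lg_mk, character(pad)); lg_an <<- c(lg_an, character(pad))
    }
    lg_t[n_ev] <<- t; lg_ch[n_ev] <<- ch
    lg_mk[n_ev] <<- mk; lg_an[n_ev] <<- an
  }

  ## ---- device and heart state ----
  last_vp <- NA_integer_          # last ventricular pace
  last_a_dev <- NA_integer_       # device-side last atrial event (AP or AS)
  pvarp_until <- -1L; pvab_until <- -1L
  ap_due <- NA_integer_           # pending atrial escape (possibly deferred)
  ap_base <- NA_integer_          # escape before any post-AR deferral
  ap_is_term <- FALSE             # pending AP is an anti-PMT termination pace
  vp_due <- NA_integer_
  vp_tracked <- FALSE; vp_at_mtr <- FALSE
  ha_last <- NA_integer_          # heart: last atrial tissue activation
  retro_due <- NA_integer_

  ## vendor detection state machine
  vs_phase <- "idle"   # idle/counting/verifying/confirm/terminate_wait/intervening
  vs_count <- 0L
  vs_ref <- NA_integer_       # reference VP-AS interval
  vs_anchor <- NA_integer_    # Boston: cycle-2 VP-AS anchor
  vs_ext <- NA_integer_       # pending one-cycle PVARP/ARP extension

  reset_vs <- function() {
    vs_phase <<- "idle"; vs_count <<- 0L
    vs_ref <<- NA_integer_; vs_anchor <<- NA_integer_
  }

  schedule_escape <- function(t) {
    ae <- if (device$timing_base == "A_A" && !is.na(last_a_dev))
      last_a_dev + lrl_int else t + (lrl_int - pav)
    if (ae <= t) ae <- t + (lrl_int - pav)
    ap_due <<- ae; ap_base <<- ae; ap_is_term <<- FALSE
  }

  ## ---- ventricular pace ----
  do_vp <- function(t) {
    an <- if (vp_tracked) {
      if (vp_at_mtr) "tracked VP-MT (upper-rate limited)" else "tracked"
    } else "paced"
    emit(t, "V", "VP", an)
    last_vp <<- t
    vp_due <<- NA_integer_; vp_tracked <<- FALSE; vp_at_mtr <<- FALSE
    pvab_until <<- t + pvab
    eff_pvarp <- pvarp
    if (!is.na(vs_ext)) {
      eff_pvarp <- vs_ext
      emit(t, "DEVICE", "PVARP_EXT",
           sprintf("atrial refractory period %d ms for one cycle", eff_pvarp))
      vs_ext <<- NA_integer_
      vs_phase <<- "intervening"
    }
    pvarp_until <<- t + eff_pvarp
    # retrograde conduction (blocked if the atrium will still be refractory)
    if (heart$retrograde_1to1) {
      arr <- t + vac
      retro_due <<- if (is.na(ha_last) || arr - ha_last >= myo)
        arr else NA_integer_
    }
    schedule_escape(t)
  }

  ## ---- atrial pace ----
  do_ap <- function(t) {
    pav_used <- pav
    if (!ap_is_term && t > ap_base) {
      # deferred AP: shorten the paced AV delay (not below the vendor floor)
      # to hold the ventricular pace at its undeferred target
      pav_used <- max(minpav, (ap_base + pav) - t)
    }
    captured <- is.na(ha_last) || (t - ha_last) >= myo
    if (captured) {
      emit(t, "A", "AP", if (t > ap_base && !ap_is_term)
        sprintf("deferred; PAV %d ms", pav_used) else "")
      ha_last <<- t
    } else {
      emit(t, "A", "AP_NONCAPTURE",
           sprintf("stimulus %d ms after atrial activation (refractory %d ms)",
                   t - ha_last, myo))
    }
    if (ap_is_term) {
      emit(t, "DEVICE", "PMT_TERMINATE",
           "VP suppressed; atrial pace re-times the atrium")
      reset_vs()
    } else if (vs_phase != "idle" && vs_phase != "intervening") {
      reset_vs()   # an atrial pace breaks any AS-counting sequence
    }
    last_a_dev <<- t
    ap_due <<- NA_integer_; ap_base <<- NA_integer_; ap_is_term <<- FALSE
    vp_due <<- t + pav_used; vp_tracked <<- FALSE; vp_at_mtr <<- FALSE
  }

  ## ---- refractory atrial sense ----
  on_ar <- function(t) {
    if (vs_phase == "intervening") {
      emit(t, "DEVICE", "PMT_TERMINATE",
           "retrograde P within extended atrial refractory period")
      reset_vs()
    } else if (vs_phase != "idle") {
      reset_vs()
    }
    if (!is.na(ar_delay) && !is.na(ap_due) && !ap_is_term) {
      tgt <- t + ar_delay
      if (tgt > ap_due) {
        emit(t, "DEVICE", "AP_DELAYED",
             sprintf("atrial pace deferred to %d ms (%d ms after refractory sense)",
                     tgt, ar_delay))
        ap_due <<- tgt
      }
    }
  }

  ## ---- vendor detector, evaluated at each tracked atrial sense (DDD) ----
  # Returns list(sav_delta, terminate_now, msgs); msgs are DEVICE markers to
  # emit after the AS marker so the log tie order stays A < DEVICE.
  vendor_pre_as <- function(t, vas, aa) {
    sav_delta <- 0L; terminate_now <- FALSE
    msgs <- list()
    say <- function(mk, an) msgs[[length(msgs) + 1L]] <<- c(mk, an)
    if (vendor %in% c("none", "boston")) {
      if (vs_phase == "intervening") reset_vs()  # extension failed to cover
      return(list(sav_delta = sav_delta, terminate_now = FALSE, msgs = msgs))
    }
    if (vs_phase == "intervening") reset_vs()

    if (vs_phase == "terminate_wait") {   # abbott only
      return(list(sav_delta = 0L, terminate_now = TRUE, msgs = msgs))
    }
    if (vs_phase == "verifying") {
      sav_delta <- vcfg$sav_modulation_delta_ms
      vs_phase <<- "confirm"
      return(list(sav_delta = sav_delta, terminate_now = FALSE, msgs = msgs))
    }
    if (vs_phase == "confirm") {
      tol <- switch(vendor, abbott = vcfg$vpas_stability_tol_ms,
                    biotronik = vcfg$deviation_tol_ms,
                    microport = vcfg$stability_tol_ms, 0L)
      if (!is.na(vs_ref) && abs(vas - vs_ref) <= tol) {
        say("PMT_DETECT", "VP-AS unchanged under AV-delay modulation")
        if (vendor == "abbott") {
          vs_phase <<- "terminate_wait"
        } else if (vendor == "biotronik") {
          vs_ext <<- vcfg$va_criterion_ms + vcfg$termination_pvarp_ext_margin_ms
          reset_vs()
        } else {  # microport
          vs_ext <<- vcfg$termination_arp_ms
          reset_vs()
        }
      } else {
        reset_vs()
      }
      return(list(sav_delta = 0L, terminate_now = FALSE, msgs = msgs))
    }

    ## idle / counting
    qual <- switch(vendor,
      abbott = {
        det_int <- ppm_to_interval_ms(vcfg$pmt_detection_rate_ppm)
        !is.na(aa) && aa < det_int &&
          (vs_count == 0L || abs(vas - vs_ref) <= vcfg$vpas_stability_tol_ms)
      },
      biotronik = vas < vcfg$va_criterion_ms &&
        (vs_count == 0L || abs(vas - vs_ref) <= vcfg$deviation_tol_ms),
      medtronic = vas < vcfg$vac_detection_limit_ms,
      microport = vas <= vcfg$vac_detection_limit_ms &&
        (vs_count == 0L || abs(vas - vs_ref) <= vcfg$stability_tol_ms))
    if (isTRUE(qual)) {
      if (vs_count == 0L) vs_ref <<- vas
      vs_count <<- vs_count + 1L
      vs_phase <<- "counting"
      if (vs_count >= vcfg$detection_beats) {
        say("PMT_SUSPECT",
            sprintf("%d consecutive qualifying beats", vs_count))
        if (vendor == "medtronic") {
          # no AV-delay verification phase
          say("PMT_DETECT",
              sprintf("VP-AS < %d ms for %d beats", vcfg$vac_detection_limit_ms,
                      vs_count))
          vs_ext <<- vcfg$intervention_pvarp_ext_ms
          reset_vs()
        } else {
          vs_phase <<- "verifying"
        }
      }
    } else {
      reset_vs()
    }
    list(sav_delta = sav_delta, terminate_now = FALSE, msgs = msgs)
  }

  # Boston counts ventricular paces delivered at the MTR boundary after an
  # atrial sense; evaluated once the VP for this sense has been scheduled.
  vendor_post_as <- function(t, vas, at_mtr) {
    if (vendor != "boston") return(invisible())
    if (at_mtr) {
      vs_count <<- vs_count + 1L
      if (vs_count == 2L) vs_anchor <<- vas
      ok <- vs_count < 3L || abs(vas - vs_anchor) <= vcfg$stability_window_ms
      if (!ok) {
        reset_vs(); vs_count <<- 1L; vs_phase <<- "counting"
      } else if (vs_count >= vcfg$detection_cycles) {
        emit(t, "DEVICE", "PMT_SUSPECT",
             sprintf("%d consecutive upper-rate VP after AS", vs_count))
        emit(t, "DEVICE", "PMT_DETECT",
             "VP-AS within stability window from second upper-rate cycle")
        vs_ext <<- vcfg$termination_pvarp_ext_ms
        reset_vs()
      } else {
        vs_phase <<- "counting"
      }
    } else {
      reset_vs()
    }
    invisible()
  }

  handle_tracked_as <- function(t, vas) {
    aa <- if (!is.na(last_a_dev)) t - last_a_dev else NA_integer_
    act <- vendor_pre_as(t, vas, aa)
    if (act$terminate_now) {
      emit(t, "A", "AS", "tracked; VP suppressed for PMT termination")
      last_a_dev <<- t
      ap_due <<- t + vcfg$termination_ap_delay_ms
      ap_base <<- ap_due; ap_is_term <<- TRUE
      vp_due <<- NA_integer_; vp_tracked <<- FALSE; vp_at_mtr <<- FALSE
      return(invisible())
    }
    sav_eff <- max(0L, sav + act$sav_delta)
    emit(t, "A", "AS", if (act$sav_delta != 0L)
      sprintf("tracked; SAV modulated to %d ms", sav_eff)
      else sprintf("tracked; VP-AS %d ms", vas))
    for (m in act$msgs) emit(t, "DEVICE", m[[1L]], m[[2L]])
    last_a_dev <<- t
    ap_due <<- NA_integer_; ap_base <<- NA_integer_
    vp_t <- t + sav_eff
    bound <- last_vp + mtr_int
    vp_t <- max(vp_t, bound)
    vp_due <<- vp_t; vp_tracked <<- TRUE; vp_at_mtr <<- vp_t == bound
    vendor_post_as(t, vas, vp_t == bound)
    invisible()
  }

  handle_ddi_sense <- function(t) {
    last_a_dev <<- t
    ap_due <<- NA_integer_; ap_base <<- NA_integer_; ap_is_term <<- FALSE
    if (is.na(vp_due)) {
      vp_due <<- last_vp + lrl_int
      vp_tracked <<- FALSE; vp_at_mtr <<- FALSE
    }
    invisible()
  }

  ## ---- retrograde atrial activation arriving at the atrium ----
  do_retro <- function(t) {
    retro_due <<- NA_integer_
    # re-check tissue refractoriness: an intervening captured AP may block it
    if (!is.na(ha_last) && (t - ha_last) < myo) return(invisible())
    ha_last <<- t
    td <- t + off                      # device-observed time
    rel <- td - last_vp
    if (rel < pvab) {
      emit(t, "A", "AS_BLANKED", "within post-ventricular atrial blanking")
      return(invisible())
    }
    if (mode == "DDI" && vendor == "microport") {
      # WARAD is inactive in DDI: annotated Ar, behaves as an ordinary sense
      emit(t, "A", "AR", "functional sense (WARAD inactive in DDI)")
      handle_ddi_sense(t)
      return(invisible())
    }
    if (td < pvarp_until) {
      emit(t, "A", "AR", sprintf("VP-AS %d ms within atrial refractory period", rel))
      on_ar(t)
    } else if (mode == "DDD") {
      handle_tracked_as(t, rel)
    } else {
      emit(t, "A", "AS", sprintf("VP-AS %d ms; atrial pacing inhibited", rel))
      handle_ddi_sense(t)
    }
    invisible()
  }

  ## ---- main loop ----
  if (induction == "auto") {
    ap_due <- 0L; ap_base <- 0L
  } else {
    ap_due <- lrl_int - pav; ap_base <- ap_due
  }
  repeat {
    cand <- c(ap_due, vp_due, retro_due)
    if (all(is.na(cand))) break
    t <- min(cand, na.rm = TRUE)
    if (t > duration_ms) break
    if (!is.na(retro_due) && retro_due == t) {
      do_retro(t)
    } else if (!is.na(vp_due) && vp_due == t) {
      do_vp(t)
    } else {
      do_ap(t)
    }
  }

  log <- data.frame(time_ms = lg_t[seq_len(n_ev)],
                    channel = lg_ch[seq_len(n_ev)],
                    marker = lg_mk[seq_len(n_ev)],
                    annotation = lg_an[seq_len(n_ev)],
                    stringsAsFactors = FALSE)
  class(log) <- c("pacing_log", "data.frame")
  attr(log, "device") <- device
  attr(log, "heart") <- heart
  attr(log, "duration_ms") <- duration_ms
  attr(log, "induction") <- induction
  vp_times <- log$time_ms[log$marker == "VP"]
  attr(log, "converged") <- length(vp_times) >= 6L &&
    diff(range(diff(utils::tail(vp_times, 6L)))) <= 2L
  log
}

#' @export
print.pacing_log <- function(x, n = 20L, ...) {
  d <- attr(x, "device"); h <- attr(x, "heart")
  cat(sprintf("<pacing_log> %d events over %d ms (%s, vendor %s, VAC %d ms)%s\n",
              nrow(x), attr(x, "duration_ms"), d$mode, d$vendor, h$vac_time_ms,
              if (isTRUE(attr(x, "converged"))) "" else " [no steady state]"))
  print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat(sprintf("... %d more events\n", nrow(x) - n))
  invisible(x)
}
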