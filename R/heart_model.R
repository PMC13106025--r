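#' Heart substrate parameters
#'
#' Describes the simulated patient: sinus arrest (no intrinsic atrial
#' activity), complete AV block (no antegrade conduction), and -- when
#' `retrograde_1to1` is `TRUE` -- fixed-delay 1:1 retrograde
#' ventriculoatrial conduction (VAC). Atrial myocardial refractoriness
#' governs both capture of atrial pacing stimuli and retrograde block.
#'
#' @param vac_time_ms retrograde conduction time in ms: the interval from a
#'   ventricular activation to the retrograde atrial activation it conducts.
#'   The bench scenarios use the device-measured values 468 ms and 570 ms
#'   (nominal simulator settings 450 and 550 ms).
#' @param retrograde_1to1 logical; if `FALSE` no retrograde conduction occurs.
#' @param atrial_myo_refractory_ms atrial tissue refractory period in ms after
#'   any atrial activation. A pacing stimulus (or a retrograde wavefront)
#'   arriving earlier than this after the last atrial activation is
#'   ineffective. Default 250 ms.
#' @param sense_offset_ms difference between the tissue conduction time and
#'   the interval the device observes (sensing-filter latency). Default 0:
#'   scenarios quote device-measured VAC directly.
#' @return an object of class `heart_params`.
#' @export
#' @examples
#' heart_params(vac_time_ms = 468)
heart_params <- function(vac_time_ms = 468L, retrograde_1to1 = TRUE,
                         atrial_myo_refractory_ms = 250L,
                         sense_offset_ms = 0L) {
  vac_time_ms <- as_int1(vac_time_ms, "vac_time_ms")
  atrial_myo_refractory_ms <- as_int1(atrial_myo_refractory_ms,
                                      "atrial_myo_refractory_ms")
  sense_offset_ms <- as_int1(sense_offset_ms, "sense_offset_ms")
  problems <- character(0)
  if (vac_time_ms <= 0L) problems <- c(problems, "vac_time_ms must be > 0")
  if (atrial_myo_refractory_ms < 0L)
    problems <- c(problems, "atrial_myo_refractory_ms must be >= 0")
  if (sense_offset_ms < 0L)
    problems <- c(problems, "sense_offset_ms must be >= 0")
  if (!is.logical(retrograde_1to1) || length(retrograde_1to1) != 1L ||
      is.na(retrograde_1to1))
    problems <- c(problems, "retrograde_1to1 must be TRUE or FALSE")
  if (length(problems)) {
    stop("invalid heart parameters:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(list(vac_time_ms = vac_time_ms,
                 retrograde_1to1 = retrograde_1to1,
                 atrial_myo_refractory_ms = atrial_myo_refractory_ms,
                 sense_offset_ms = sense_offset_ms),
            class = "heart_params")
}

#' @export
print.heart_params <- function(x, ...) {
  cat(sprintf(
    "<heart_params> VAC %d ms (1:1 retrograde: %s), atrial refractory %d ms, sense offset %d ms\n",
    x$vac_time_ms, if (x$retrograde_1to1) "yes" else "no",
    x$atrial_myo_refractory_ms, x$sense_offset_ms))
  invisible(x)
}

#' Fresh heart state
#'
#' Tracks the last atrial and ventricular activation times and any pending
#' retrograde atrial activation. All fields start as `NA` (no activity yet).
#'
#' @return a list with fields `last_atrial_activation_ms`,
#'   `last_ventricular_activation_ms`, `pending_retrograde_ms`.
#' @export
new_heart_state <- function() {
  list(last_atrial_activation_ms = NA_integer_,
       last_ventricular_activation_ms = NA_integer_,
       pending_retrograde_ms = NA_integer_)
}

#' Heart response to a ventricular activation
#'
#' A (paced) ventricular activation at time `t` conducts retrogradely to the
#' atrium after `vac_time_ms`, unless retrograde conduction is absent or the
#' wavefront would arrive while the atrium is still refractory from its last
#' activation, in which case it blocks.
#'
#' @param t activation time in ms (>= 0).
#' @param state heart state, as from [new_heart_state()].
#' @param params a [heart_params()] object.
#' @return a list with `state` (updated) and `atrial_time` (the scheduled
#'   retrograde atrial activation time, or `NA` on block).
#' @export
#' @examples
#' hp <- heart_params(vac_time_ms = 450)
#' st <- new_heart_state()
#' st$last_atrial_activation_ms <- 0L
#' heart_on_ventricular_activation(1000, st, hp)$atrial_time  # 1450
heart_on_ventricular_activation <- function(t, state, params) {
  t <- as_int1(t, "t")
  stopifnot(t >= 0L, inherits(params, "heart_params"))
  state$last_ventricular_activation_ms <- t
  atrial_time <- NA_integer_
  if (params$retrograde_1to1) {
    arrival <- t + params$vac_time_ms
    last_a <- state$last_atrial_activation_ms
    if (is.na(last_a) ||
        arrival - last_a >= params$atrial_myo_refractory_ms) {
      atrial_time <- arrival
    }
  }
  state$pending_retrograde_ms <- atrial_time
  list(state = state, atrial_time = atrial_time)
}

#' Heart response to an atrial pacing stimulus
#'
#' The stimulus captures unless it falls within the atrial myocardial
#' refractory period after the last atrial activation. Capture updates the
#' last-activation time; a non-captured stimulus leaves the tissue untouched.
#'
#' @inheritParams heart_on_ventricular_activation
#' @return a list with `state` (updated) and `outcome`, one of `"captured"`
#'   or `"non_captured"`.
#' @export
heart_on_atrial_pace <- function(t, state, params) {
  t <- as_int1(t, "t")
  stopifnot(inherits(params, "heart_params"))
  last_a <- state$last_atrial_activation_ms
  if (!is.na(last_a) && t - last_a < params$atrial_myo_refractory_ms) {
    outcome <- "non_captured"
  } else {
    outcome <- "captured"
    state$last_atrial_activation_ms <- t
  }
  list(state = state, outcome = outcome)
}
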