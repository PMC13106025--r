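#' Detect sustained pacemaker-mediated tachycardia in an event log
#'
#' A PMT episode is sustained when at least `min_cycles` consecutive
#' VP -> tracked-AS -> VP cycles occur with cycle-to-cycle V-V variation at
#' most `tol_ms`. The steady cycle length is the most frequent V-V interval
#' of the longest such run. The integer engine is exact, so the tolerance is
#' a guard for future noise features, not a fudge factor.
#'
#' @param log a `pacing_log` from [run_simulation()].
#' @param min_cycles minimum run length (default 8, the smallest vendor
#'   detection count).
#' @param tol_ms allowed V-V variation within the run.
#' @return list with `sustained` (logical), `steady_cycle_ms` (integer or
#'   `NA`) and `n_cycles` (length of the longest stable tracked run).
#' @export
detect_pmt <- function(log, min_cycles = 8L, tol_ms = 2L) {
  vp <- log[log$marker == "VP", , drop = FALSE]
  none <- list(sustained = FALSE, steady_cycle_ms = NA_integer_, n_cycles = 0L)
  if (nrow(vp) < min_cycles + 1L) return(none)
  iv <- diff(vp$time_ms)                    # interval i ends at VP i+1
  trk <- grepl("tracked", vp$annotation)[-1L]
  r <- rle(trk)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sustained <- FALSE; steady <- NA_integer_; best_n <- 0L
  for (k in which(r$values & r$lengths >= min_cycles)) {
    seg <- iv[starts[k]:ends[k]]
    # longest stretch within the segment whose range stays <= tol_ms
    i0 <- 1L
    for (j in seq_along(seg)) {
      while (max(seg[i0:j]) - min(seg[i0:j]) > tol_ms) i0 <- i0 + 1L
      len <- j - i0 + 1L
      if (len >= min_cycles && len > best_n) {
        sustained <- TRUE
        best_n <- len
        tab <- table(seg[i0:j])
        steady <- as.integer(names(tab)[which.max(tab)])
      }
    }
  }
  list(sustained = sustained, steady_cycle_ms = steady, n_cycles = best_n)
}

#' Detect repetitive nonreentrant ventriculoatrial synchrony (RNRVAS)
#'
#' An RNRVAS episode is at least `min_cycles` consecutive cycles of
#' atrial pace into refractory tissue (non-capture), ventricular pace, and
#' retrograde atrial sense within the refractory period:
#' `AP_NONCAPTURE -> VP -> AR`, with no other atrial event interposed.
#'
#' @param log a `pacing_log`.
#' @param min_cycles minimum consecutive qualifying cycles (default 3).
#' @return data frame of maximal episodes with columns `start_ms`, `end_ms`,
#'   `n_cycles`; zero rows when none occur.
#' @export
detect_rnrvas <- function(log, min_cycles = 3L) {
  keep <- log$marker %in% c("AP", "AP_NONCAPTURE", "AS", "AR", "VP")
  mk <- log$marker[keep]
  tm <- log$time_ms[keep]
  # qualifying cycle: AP_NONCAPTURE immediately followed by VP then AR
  starts <- which(mk == "AP_NONCAPTURE")
  qual <- vapply(starts, function(i) {
    i + 2L <= length(mk) && mk[i + 1L] == "VP" && mk[i + 2L] == "AR"
  }, logical(1))
  episodes <- data.frame(start_ms = integer(0), end_ms = integer(0),
                         n_cycles = integer(0))
  if (!any(qual)) return(episodes)
  qi <- starts[qual]
  # consecutive cycles: the next qualifying AP_NONCAPTURE follows with only
  # the VP and AR of this cycle in between (index gap of exactly 3)
  run_start <- qi[1L]; n <- 1L
  flush <- function(s, e, n) {
    if (n >= min_cycles)
      episodes <<- rbind(episodes,
                         data.frame(start_ms = tm[s], end_ms = tm[e + 2L],
                                    n_cycles = n))
  }
  if (length(qi) > 1L) {
    for (j in 2L:length(qi)) {
      if (qi[j] - qi[j - 1L] == 3L) {
        n <- n + 1L
      } else {
        flush(run_start, qi[j - 1L], n)
        run_start <- qi[j]; n <- 1L
      }
    }
  }
  flush(run_start, qi[length(qi)], n)
  episodes
}

#' Write / read a marker-channel event CSV
#'
#' Plain UTF-8 CSV with header `time_ms,channel,marker,annotation` and LF
#' line endings; byte-identical across repeated runs of the same scenario.
#'
#' @param log a `pacing_log`.
#' @param path output file path.
#' @return `write_event_csv` returns `path` invisibly; `read_event_csv`
#'   returns a data frame in event-log column layout.
#' @export
write_event_csv <- function(log, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  q <- function(x) {
    need <- grepl('[",\n]', x)
    x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
    x
  }
  lines <- c("time_ms,channel,marker,annotation",
             paste(log$time_ms, log$channel, log$marker, q(log$annotation),
                   sep = ","))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_event_csv
#' @export
read_event_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c("integer", "character", "character",
                                 "character"))
}

#' Render an event log as an ASCII ladder diagram
#'
#' Two rails (A above, V below) with one character column per `ms_per_col`
#' milliseconds, wrapped at `width` columns per row, for eyeball comparison
#' with marker-channel tracings. Symbols: `P` atrial pace, `x` non-captured
#' atrial pace, `S` atrial sense, `r` refractory atrial sense, `b` blanked
#' sense, `V` ventricular pace, `!` ventricular pace at the upper-rate
#' boundary.
#'
#' @param log a `pacing_log`.
#' @param ms_per_col milliseconds per character column (default 10).
#' @param width characters per ladder row (default 72).
#' @return character vector of lines, invisibly; also printed.
#' @export
render_ladder <- function(log, ms_per_col = 10L, width = 72L) {
  if (nrow(log) == 0L) return(invisible(character(0)))
  sym <- c(AP = "P", AP_NONCAPTURE = "x", AS = "S", AR = "r",
           AS_BLANKED = "b", VP = "V")
  ev <- log[log$marker %in% names(sym), , drop = FALSE]
  ncol_total <- floor(max(ev$time_ms) / ms_per_col) + 1L
  a_rail <- rep(".", ncol_total)
  v_rail <- rep(".", ncol_total)
  for (i in seq_len(nrow(ev))) {
    cl <- floor(ev$time_ms[i] / ms_per_col) + 1L
    ch <- sym[[ev$marker[i]]]
    if (ev$marker[i] == "VP" && grepl("VP-MT", ev$annotation[i])) ch <- "!"
    if (ev$channel[i] == "A") a_rail[cl] <- ch else v_rail[cl] <- ch
  }
  out <- character(0)
  for (s in seq(1L, ncol_total, by = width)) {
    e <- min(s + width - 1L, ncol_total)
    out <- c(out,
             sprintf("t=%-8d", (s - 1L) * ms_per_col),
             paste0("A: ", paste(a_rail[s:e], collapse = "")),
             paste0("V: ", paste(v_rail[s:e], collapse = "")),
             "")
  }
  cat(out, sep = "\n")
  invisible(out)
}
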