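# Scalar descriptors of spindle responses: initial burst, dynamic
# response, dynamic index, and force-recovery time.

trace_signal <- function(trace, signal = NULL) {
  if (is.data.frame(trace)) {
    if (is.null(signal)) {
      signal <- if ("rtotal_au" %in% names(trace)) "rtotal_au"
                else if ("stress" %in% names(trace)) "stress"
                else stop("cannot infer signal column; pass `signal`",
                          call. = FALSE)
    }
    list(time = trace$time_s, x = trace[[signal]])
  } else {
    stop("trace must be a data frame with a time_s column", call. = FALSE)
  }
}

# First strict interior local maximum of x on index window [i1, i2].
# Ties are broken toward earlier time by taking the first match.
first_local_max <- function(x, i1, i2) {
  i1 <- max(i1, 2L)
  i2 <- min(i2, length(x) - 1L)
  if (i2 < i1) return(NA_integer_)
  idx <- seq(i1, i2)
  hit <- x[idx] > x[idx - 1L] & x[idx] > x[idx + 1L]
  if (!any(hit)) NA_integer_ else idx[which(hit)[1L]]
}

#' Initial burst of a stretch response
#'
#' Magnitude of the transient peak at stretch onset: the first interior
#' local maximum of the signal in the onset portion of the ramp, minus
#' the baseline (mean over the `baseline_window` seconds preceding
#' onset). The burst is produced by short-range stiffness -- pre-attached
#' cross-bridges dragged until they are forcibly detached -- so its peak
#' must occur while that transient lasts, within roughly
#' (detachment strain)/(stretch amplitude) of the ramp; the search is
#' therefore limited to the first `window_frac` of the ramp window
#' (default one quarter). This keeps late peaks -- the length-reversal
#' peak at a triangle apex, or the delayed force-recovery overshoot of a
#' conditioned fibre -- from being mistaken for an onset burst. A burst
#' is deemed present when its magnitude exceeds `epsilon_frac` of the
#' `reference` burst (for sweep comparisons; with no reference, any
#' positive magnitude counts).
#'
#' @param trace A `spindle_trace` or `fibre_trace` (or any data frame with
#'   `time_s` plus the `signal` column).
#' @param onset Stretch onset time, s.
#' @param ramp_end End of the ramp (or triangle apex) time, s.
#' @param baseline_window Pre-onset averaging window, s.
#' @param reference Reference burst magnitude for the presence test
#'   (typically the conditioning or unconditioned burst), or `NULL`.
#' @param epsilon_frac Presence threshold as a fraction of `reference`.
#' @param baseline_at Time point whose preceding window defines the
#'   baseline (defaults to `onset`; for a test stretch following a
#'   conditioning cycle, pass the conditioning onset so both bursts share
#'   the resting baseline).
#' @param window_frac Fraction of the ramp window, from onset, searched
#'   for the burst peak.
#' @param signal Signal column name (defaults to `rtotal_au` for spindle
#'   traces, `stress` for fibre traces).
#' @return List with `value` (a.u., 0 when no burst), `burst_present`,
#'   `peak_time` (s or NA) and `baseline`.
#' @export
initial_burst <- function(trace, onset, ramp_end, baseline_window = 0.5,
                          reference = NULL, epsilon_frac = 0.02,
                          baseline_at = NULL, window_frac = 0.25,
                          signal = NULL) {
  s <- trace_signal(trace, signal)
  if (onset < min(s$time) || onset > max(s$time)) {
    stop("stretch onset lies outside the trace", call. = FALSE)
  }
  baseline_at <- baseline_at %||% onset
  base_idx <- s$time >= baseline_at - baseline_window &
    s$time < baseline_at
  if (!any(base_idx)) {
    stop("trace does not cover the pre-onset baseline window",
         call. = FALSE)
  }
  baseline <- mean(s$x[base_idx])
  i1 <- which(s$time >= onset)[1L]
  window_end <- onset + window_frac * (ramp_end - onset)
  i2 <- min(max(which(s$time <= window_end)),
            max(which(s$time <= ramp_end)) - 2L)
  ipk <- first_local_max(s$x, i1, i2)
  if (is.na(ipk)) {
    return(list(value = 0, burst_present = FALSE, peak_time = NA_real_,
                baseline = baseline))
  }
  value <- s$x[ipk] - baseline
  if (value < 0) value <- 0
  eps <- if (is.null(reference)) 0 else epsilon_frac * reference
  list(value = value, burst_present = value > eps,
       peak_time = s$time[ipk], baseline = baseline)
}

#' Dynamic response of a ramp stretch
#'
#' Rise of the receptor potential during the ramp after the initial
#' burst: a least-squares line is fitted from the signal's minimum after
#' the burst peak (or from ramp start when no burst is present) to the end
#' of the ramp, and the fitted rise over the fit interval
#' (`slope * interval`) is reported; the raw slope is returned as well.
#' The burst peak is located with the same onset window as
#' [initial_burst()].
#'
#' @inheritParams initial_burst
#' @param ramp_window Two-element numeric, start and end of the ramp, s.
#' @return List with `rise` (a.u.), `slope` (a.u. per s) and `fit_start`
#'   (s).
#' @export
dynamic_response <- function(trace, ramp_window, signal = NULL,
                             window_frac = 0.25) {
  s <- trace_signal(trace, signal)
  i1 <- which(s$time >= ramp_window[1])[1L]
  i2 <- max(which(s$time <= ramp_window[2]))
  if (is.na(i1) || i2 <= i1) {
    stop("ramp window lies outside the trace", call. = FALSE)
  }
  iwin <- min(max(which(s$time <= ramp_window[1] +
                          window_frac * diff(ramp_window))), i2 - 2L)
  ipk <- first_local_max(s$x, i1, iwin)
  istart <- if (is.na(ipk)) i1 else {
    seg <- seq(ipk, i2)
    seg[which.min(s$x[seg])]
  }
  if (i2 - istart < 1L) istart <- i1
  tt <- s$time[istart:i2]
  fit <- lm(s$x[istart:i2] ~ tt)
  slope <- unname(coef(fit)[2])
  list(rise = slope * (s$time[i2] - s$time[istart]), slope = slope,
       fit_start = s$time[istart])
}

#' Dynamic index of a ramp-and-hold response
#'
#' Difference between the peak response late in the ramp (after the
#' post-burst minimum when a burst is present) and the response at the end
#' of the hold phase.
#'
#' @inheritParams dynamic_response
#' @param hold_end Time at which the hold-phase response is read, s.
#' @return Dynamic index, a.u.
#' @export
dynamic_index <- function(trace, ramp_window, hold_end, signal = NULL,
                          window_frac = 0.25) {
  s <- trace_signal(trace, signal)
  i1 <- which(s$time >= ramp_window[1])[1L]
  i2 <- max(which(s$time <= ramp_window[2]))
  iwin <- min(max(which(s$time <= ramp_window[1] +
                          window_frac * diff(ramp_window))), i2 - 2L)
  ipk <- first_local_max(s$x, i1, iwin)
  istart <- if (is.na(ipk)) i1 else {
    seg <- seq(ipk, i2)
    seg[which.min(s$x[seg])]
  }
  peak <- max(s$x[istart:i2])
  ihold <- which.min(abs(s$time - hold_end))
  peak - s$x[ihold]
}

#' Recovery time of a response after a shortening
#'
#' Time after the second (test) stretch onset at which the signal first
#' exceeds its pre-conditioning resting value by a small threshold,
#' `epsilon_frac` of the conditioning-phase peak above that resting value.
#' A shortened fibre falls slack and its stress collapses; this measures
#' how long the response takes to "reappear" on the next stretch.
#'
#' @inheritParams initial_burst
#' @param second_onset Test-stretch onset time, s.
#' @param cond_onset Conditioning-stretch onset (baseline and peak are
#'   referenced to this), s.
#' @param epsilon_frac Threshold as a fraction of the conditioning peak
#'   above baseline.
#' @return Recovery time in seconds (0 when already above threshold at
#'   onset), or `NA` if the threshold is never exceeded.
#' @export
recovery_time <- function(trace, second_onset, cond_onset,
                          baseline_window = 0.5, epsilon_frac = 0.01,
                          signal = NULL) {
  s <- trace_signal(trace, signal)
  if (second_onset < min(s$time) || second_onset > max(s$time)) {
    stop("second stretch onset lies outside the trace", call. = FALSE)
  }
  base_idx <- s$time >= cond_onset - baseline_window & s$time < cond_onset
  baseline <- mean(s$x[base_idx])
  cond_idx <- s$time >= cond_onset & s$time < second_onset
  peak <- if (any(cond_idx)) max(s$x[cond_idx]) else baseline
  thresh <- baseline + epsilon_frac * max(peak - baseline, 0)
  after <- which(s$time >= second_onset)
  hit <- after[s$x[after] > thresh]
  if (!length(hit)) return(NA_real_)
  s$time[hit[1L]] - second_onset
}

#' Extract the standard feature set from a ramp-and-hold response
#'
#' Convenience wrapper applying [initial_burst()], [dynamic_response()]
#' and [dynamic_index()] using the stretch timing recorded in the trace's
#' protocol events.
#'
#' @param trace A trace produced by [simulate_spindle()] (or
#'   [simulate_fibre()]) from a [ramp_hold()] protocol.
#' @param signal Signal column (see [initial_burst()]).
#' @return One-row data frame with `initial_burst`, `burst_present`,
#'   `dynamic_response`, `dynamic_slope`, `dynamic_index`.
#' @export
extract_features <- function(trace, signal = NULL) {
  ev <- attr(trace, "protocol_events")
  if (is.null(ev) || is.null(ev$onset)) {
    stop("trace carries no ramp-and-hold protocol events", call. = FALSE)
  }
  ib <- initial_burst(trace, ev$onset, ev$ramp_end, signal = signal)
  dr <- dynamic_response(trace, c(ev$onset, ev$ramp_end), signal = signal)
  di <- dynamic_index(trace, c(ev$onset, ev$ramp_end), ev$hold_end,
                      signal = signal)
  data.frame(initial_burst = ib$value, burst_present = ib$burst_present,
             dynamic_response = dr$rise, dynamic_slope = dr$slope,
             dynamic_index = di)
}
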