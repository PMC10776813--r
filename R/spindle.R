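#' Half-wave rectified yank of a force trace
#'
#' Yank is the time derivative of force. It is computed with a causal
#' first-order backward difference (the first sample is set to zero, since
#' no earlier sample exists) and half-wave rectified: negative rates are
#' replaced by zero, so only rising force contributes to the dynamic
#' component of the receptor potential.
#'
#' @param force_trace Numeric force (stress) series on a uniform grid.
#' @param dt Sampling interval, s.
#' @param time Optional time stamps; if supplied they are checked for
#'   uniform spacing `dt`.
#' @return Rectified derivative series of the same length.
#' @export
yank <- function(force_trace, dt, time = NULL) {
  if (length(force_trace) < 2) {
    stop("force trace needs at least two samples", call. = FALSE)
  }
  if (!is.null(time)) {
    steps <- diff(time)
    if (any(abs(steps - dt) > 1e-9 * max(dt, 1))) {
      stop("yank requires uniform sampling at dt", call. = FALSE)
    }
  }
  d <- c(0, diff(force_trace) / dt)
  pmax(d, 0)
}

#' Ia-afferent receptor potential from bag and chain stress traces
#'
#' Phenomenological receptor-potential model: the bag pathway contributes
#' its force plus the half-wave rectified yank (weight `k_yb`), the chain
#' pathway its force only, and the weighted sum is divided by the fixed
#' force-to-potential conversion `scale`:
#' \deqn{r_{total}(t) = \left(k_{fc} F_c(t) + k_{fb} F_b(t) +
#'       k_{yb} \lfloor dF_b/dt \rfloor_+\right) / \mathrm{scale}}
#' Units are arbitrary; with the default weights, equal steady bag and
#' chain stresses contribute in the ratio 0.4 : 0.5.
#'
#' @param bag_stress,chain_stress Equal-length, time-aligned stress series
#'   (N m^-2) on a uniform grid.
#' @param weights A [receptor_weights()].
#' @param dt Sampling interval, s.
#' @param time Optional time stamps for the output.
#' @return A data frame of class `spindle_trace` with columns `time_s`,
#'   `bag_au`, `chain_au`, `rtotal_au`; `rtotal_au` is exactly the sum of
#'   the two components at every sample.
#' @export
receptor_potential <- function(bag_stress, chain_stress,
                               weights = receptor_weights(),
                               dt = 1e-4, time = NULL) {
  n <- length(bag_stress)
  if (length(chain_stress) != n) {
    stop("bag and chain traces must have equal length", call. = FALSE)
  }
  if (is.null(time)) time <- (seq_len(n) - 1) * dt
  bag_au <- (weights$k_fb * bag_stress +
               weights$k_yb * yank(bag_stress, dt)) / weights$scale
  chain_au <- weights$k_fc * chain_stress / weights$scale
  out <- data.frame(time_s = time, bag_au = bag_au, chain_au = chain_au,
                    rtotal_au = bag_au + chain_au)
  class(out) <- c("spindle_trace", "data.frame")
  out
}
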