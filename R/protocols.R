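# Imposed-length protocols. Lengths are specified in % of the resting
# half-sarcomere length L0 and stored in nm on a uniform sampling grid
# (default 10 kHz); the simulator interpolates onto its own dt.

protocol_frame <- function(time, length_nm, pCa, kind, events, meta) {
  out <- data.frame(time_s = time, length_nm = length_nm, pCa = pCa)
  attr(out, "events") <- events
  attr(out, "metadata") <- c(list(kind = kind), meta)
  class(out) <- c("length_protocol", "data.frame")
  out
}

piecewise_linear <- function(knot_t, knot_len, pCa, sample_rate, kind,
                             events, meta) {
  keep <- !duplicated(knot_t)
  knot_t <- knot_t[keep]
  knot_len <- knot_len[keep]
  time <- seq(0, knot_t[length(knot_t)], by = 1 / sample_rate)
  len <- approx(knot_t, knot_len, xout = time, rule = 2)$y
  protocol_frame(time, len, rep(pCa, length(time)), kind, events, meta)
}

#' Ramp-and-hold stretch protocol
#'
#' Constant length at \eqn{L_0} for `pre_hold` seconds (the activation
#' equilibration phase), a linear ramp of the given velocity up to
#' `amplitude`, then a hold at the stretched length until `total` seconds.
#'
#' @param velocity Ramp velocity, %L0 per second.
#' @param amplitude Stretch amplitude, %L0.
#' @param pre_hold Pre-stretch hold duration at L0, s.
#' @param total Total protocol duration (including `pre_hold`), s.
#' @param L0 Resting half-sarcomere length, nm.
#' @param pCa Activation level, held constant.
#' @param sample_rate Protocol sampling rate, Hz.
#' @return A `length_protocol` data frame (`time_s`, `length_nm`, `pCa`)
#'   with stretch timing in `attr(, "events")`.
#' @examples
#' p <- ramp_hold(36, 5.6)
#' attr(p, "events")$ramp_end - attr(p, "events")$onset # ~0.156 s
#' @export
ramp_hold <- function(velocity = 36, amplitude = 5.6, pre_hold = 2,
                      total = 3, L0 = 1300, pCa = 6.4,
                      sample_rate = 1e4) {
  if (velocity <= 0) stop("velocity must be positive", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be non-negative", call. = FALSE)
  ramp_dur <- amplitude / velocity
  if (pre_hold + ramp_dur > total) {
    stop("ramp does not fit inside the total protocol duration",
         call. = FALSE)
  }
  knot_t <- c(0, pre_hold, pre_hold + ramp_dur, total)
  knot_len <- L0 * c(1, 1, 1 + amplitude / 100, 1 + amplitude / 100)
  events <- list(onset = pre_hold, ramp_end = pre_hold + ramp_dur,
                 hold_end = total)
  piecewise_linear(knot_t, knot_len, pCa, sample_rate, "ramp_hold", events,
                   list(velocity = velocity, amplitude = amplitude,
                        L0 = L0, pCa = pCa))
}

#' Paired triangular stretch-shorten protocol
#'
#' A conditioning symmetric stretch-shorten triangle, an inter-stretch
#' interval (ISI) at rest length, a test triangle, and a trailing hold.
#' Both triangles use the same velocity on the way up and down. This is
#' the protocol used to probe history dependence: the conditioning cycle
#' detaches the resting cross-bridge population so the test-cycle response
#' reports how far it has rebuilt.
#'
#' @param velocity Stretch and shorten speed, %L0 per second.
#' @param cond_amplitude Conditioning-triangle amplitude, %L0 (0 gives an
#'   unconditioned test stretch).
#' @param test_amplitude Test-triangle amplitude, %L0.
#' @param isi Inter-stretch interval between the triangles, s.
#' @param pre_hold Pre-stretch activation hold, s.
#' @param trailing Hold at L0 after the test triangle, s.
#' @inheritParams ramp_hold
#' @return A `length_protocol`; `attr(, "events")` holds `cond_onset`,
#'   `cond_apex`, `cond_end`, `test_onset`, `test_apex`, `test_end`, `end`.
#' @export
triangle_pair <- function(velocity = 12, cond_amplitude = 5.6,
                          test_amplitude = 5.6, isi = 0, pre_hold = 2,
                          trailing = 1, L0 = 1300, pCa = 6.4,
                          sample_rate = 1e4) {
  if (velocity <= 0) stop("velocity must be positive", call. = FALSE)
  if (cond_amplitude < 0 || test_amplitude < 0) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  if (isi < 0) stop("isi must be non-negative", call. = FALSE)
  cd <- cond_amplitude / velocity
  td <- test_amplitude / velocity
  ev <- list(
    cond_onset = pre_hold,
    cond_apex = pre_hold + cd,
    cond_end = pre_hold + 2 * cd,
    test_onset = pre_hold + 2 * cd + isi,
    test_apex = pre_hold + 2 * cd + isi + td,
    test_end = pre_hold + 2 * cd + isi + 2 * td,
    end = pre_hold + 2 * cd + isi + 2 * td + trailing
  )
  knot_t <- unique(c(0, ev$cond_onset, ev$cond_apex, ev$cond_end,
                     ev$test_onset, ev$test_apex, ev$test_end, ev$end))
  lookup <- function(t) {
    lvl <- rep(1, length(t))
    up1 <- t > ev$cond_onset & t <= ev$cond_apex
    dn1 <- t > ev$cond_apex & t <= ev$cond_end
    up2 <- t > ev$test_onset & t <= ev$test_apex
    dn2 <- t > ev$test_apex & t <= ev$test_end
    lvl[up1] <- 1 + (t[up1] - ev$cond_onset) * velocity / 100
    lvl[dn1] <- 1 + (ev$cond_end - t[dn1]) * velocity / 100
    lvl[up2] <- 1 + (t[up2] - ev$test_onset) * velocity / 100
    lvl[dn2] <- 1 + (ev$test_end - t[dn2]) * velocity / 100
    lvl
  }
  piecewise_linear(knot_t, L0 * lookup(knot_t), pCa, sample_rate,
                   "triangle_pair", ev,
                   list(velocity = velocity,
                        cond_amplitude = cond_amplitude,
                        test_amplitude = test_amplitude, isi = isi,
                        L0 = L0, pCa = pCa))
}

#' Sinusoidal stretch-shorten protocol
#'
#' After the activation pre-hold, the length follows a raised cosine
#' starting at \eqn{L_0} and moving first into stretch:
#' \deqn{L(t) = L_0 \left(1 + \frac{a}{2}(1 - \cos 2\pi f t)\right)}
#' so the peak-to-baseline excursion equals `amplitude` (%L0) and each
#' cycle returns to the resting length.
#'
#' @param amplitude Peak length change, %L0.
#' @param frequency Oscillation frequency, Hz.
#' @param n_cycles Number of complete cycles.
#' @inheritParams ramp_hold
#' @return A `length_protocol`; `attr(, "events")` holds `onset`, `period`
#'   and `end`.
#' @export
sinusoid_protocol <- function(amplitude, frequency = 1, n_cycles = 3,
                              pre_hold = 2, L0 = 1300, pCa = 6.4,
                              sample_rate = 1e4) {
  if (amplitude < 0) stop("amplitude must be non-negative", call. = FALSE)
  if (frequency <= 0) stop("frequency must be positive", call. = FALSE)
  t_end <- pre_hold + n_cycles / frequency
  time <- seq(0, t_end, by = 1 / sample_rate)
  a <- amplitude / 100
  phase <- pmax(time - pre_hold, 0)
  len <- L0 * (1 + a / 2 * (1 - cos(2 * pi * frequency * phase)))
  protocol_frame(time, len, rep(pCa, length(time)), "sinusoid",
                 list(onset = pre_hold, period = 1 / frequency,
                      end = t_end),
                 list(amplitude = amplitude, frequency = frequency,
                      n_cycles = n_cycles, L0 = L0, pCa = pCa))
}
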