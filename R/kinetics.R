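#' Thick/thin filament overlap fraction
#'
#' Fraction of actin sites within reach of myosin heads at the current
#' half-sarcomere length:
#' \deqn{n_{ov} = \frac{l_{thin} - (l_{hs} - l_{thick})}{l_{thick} - l_{bare}}}
#' clamped to \[0, 1\] (the linear ramp exceeds those bounds at extreme
#' lengths).
#'
#' @param hs_length Half-sarcomere length, nm (vectorized).
#' @param geometry A [filament_geometry()].
#' @return Overlap fraction in \[0, 1\].
#' @examples
#' filament_overlap(1300, filament_geometry()) # 635/735
#' @export
filament_overlap <- function(hs_length, geometry = filament_geometry()) {
  if (any(hs_length <= 0)) stop("hs_length must be positive", call. = FALSE)
  denom <- geometry$length_thick_filament - geometry$length_bare_zone
  if (denom <= 0) {
    stop("invalid geometry: thick filament not longer than bare zone",
         call. = FALSE)
  }
  raw <- (geometry$length_thin_filament -
            (hs_length - geometry$length_thick_filament)) / denom
  pmin(pmax(raw, 0), 1)
}

#' Strain-dependent myosin attachment rate f(dx)
#'
#' Gaussian-shaped attachment rate, peaking at zero strain:
#' \deqn{f(\Delta x) = f_0 \exp(-k_{cb} \Delta x^2 / c_f)}
#' where \eqn{f_0} is the fibre's attachment slope, \eqn{k_{cb}} the
#' cross-bridge stiffness and \eqn{c_f} the thermal-energy constant.
#'
#' @param strain Cross-bridge strain, nm (vectorized).
#' @param xb A [crossbridge_params()].
#' @return Attachment rate, s^-1.
#' @export
attachment_rate <- function(strain, xb = crossbridge_params()) {
  xb$attach_slope * exp(-xb$cb_stiffness * strain^2 / xb$const_f)
}

#' Strain-dependent myosin detachment rate g(dx)
#'
#' Piecewise cubic detachment rate about the breakpoint strain (default
#' -5 nm, the zero-force strain):
#' \deqn{g(\Delta x) = \max(g_0 + c_{\pm} (\Delta x - x_b)^3,\; 0) +
#'       g_{off}}
#' with the signed cubic (coefficient 0.3 above the breakpoint, 0.2
#' below). Above the breakpoint, detachment rises steeply with strain
#' (highly strained bridges are ripped off). Below it, the cubic is
#' negative, so the tuned part falls to zero and the rate bottoms out at
#' the fibre-specific floor \eqn{g_{off}} (`detach_extra_offset`):
#' strongly compressed bridges release only slowly, at 0.5 s^-1 in the
#' bag fibre versus 10 s^-1 in the chain. These floors set the fibres'
#' force-recovery timescales after a shortening, and with them the
#' spindle's history dependence.
#'
#' @param strain Cross-bridge strain, nm (vectorized).
#' @param xb A [crossbridge_params()].
#' @return Detachment rate, s^-1 (always >= `detach_extra_offset`).
#' @export
detachment_rate <- function(strain, xb = crossbridge_params()) {
  d <- strain - xb$detach_breakpoint
  coeff <- ifelse(d < 0, xb$detach_coeff_below, xb$detach_coeff_above)
  pmax(xb$detach_offset + coeff * d^3, 0) + xb$detach_extra_offset
}

#' Instantaneous state of one half-sarcomere fibre
#'
#' Bundles the evolving quantities of the simulation: time, half-sarcomere
#' length, activated-actin fraction and the bound-myosin fraction per
#' strain bin. Derived quantities (`n_overlap`, `cb_attached`, `stress`)
#' are computed on construction. Attached and detached myosin fractions
#' sum to one by construction.
#'
#' @param params A [fibre_params()].
#' @param grid A [strain_grid()].
#' @param hs_length Half-sarcomere length, nm.
#' @param actin_activated Activated-actin fraction.
#' @param bound_myosin Bound-myosin fraction per strain bin (defaults to
#'   all zero).
#' @param time Simulation time, s.
#' @return An object of class `fibre_state`.
#' @export
fibre_state <- function(params, grid = strain_grid(),
                        hs_length = params$geometry$resting_length_L0,
                        actin_activated = 0,
                        bound_myosin = rep(0, length(grid$centres)),
                        time = 0) {
  if (length(bound_myosin) != length(grid$centres)) {
    stop("bound_myosin must have one entry per strain bin", call. = FALSE)
  }
  if (any(bound_myosin < 0) || actin_activated < 0) {
    stop("state fractions must be non-negative", call. = FALSE)
  }
  cb <- sum(bound_myosin)
  if (cb > actin_activated + 1e-12) {
    stop("state corruption: cb_attached exceeds actin_activated",
         call. = FALSE)
  }
  st <- structure(list(
    time = time,
    hs_length = hs_length,
    actin_activated = actin_activated,
    bound_myosin = bound_myosin,
    grid = grid,
    n_overlap = filament_overlap(hs_length, params$geometry),
    cb_attached = cb,
    stress = NA_real_
  ), class = "fibre_state")
  st$stress <- stress(st, params, grid)
  st
}

#' Time derivative of the activated-actin fraction
#'
#' Calcium-driven activation balance with inter-filament cooperativity:
#' activation proceeds at `k_on * Ca` over the actin still available within
#' the overlap zone, enhanced by bound myosin (`k_coop * A / n_overlap`);
#' deactivation at `k_off` acts only on activated sites not occupied by a
#' cross-bridge, enhanced by the inactive fraction. When the overlap is
#' zero both cooperativity ratios are defined as zero and the activation
#' term vanishes.
#'
#' @param state A [fibre_state()].
#' @param thin A [thin_filament_params()].
#' @param Ca Calcium concentration, molar.
#' @return dA/dt, s^-1.
#' @export
actin_derivative <- function(state, thin, Ca) {
  A <- state$actin_activated
  nov <- state$n_overlap
  cb <- state$cb_attached
  if (nov <= 0) {
    act <- 0
    deact <- thin$k_off * (A - cb)
  } else {
    act <- thin$k_on * Ca * (nov - A) * (1 + thin$k_coop * A / nov)
    deact <- thin$k_off * (A - cb) * (1 + thin$k_coop * (nov - A) / nov)
  }
  act - deact
}

# Normalized attachment-window weights over the strain grid: new
# cross-bridges form near zero strain with the f(dx) profile as weights.
attachment_weights <- function(grid, xb) {
  f <- attachment_rate(grid$centres, xb)
  s <- sum(f)
  if (s <= 0) rep(0, length(f)) else f / s
}

#' Time derivatives of the bound-myosin distribution
#'
#' Two-state kinetics per strain bin: attachment flux
#' `f(dx_i) * w_i * M_detached * (A - cb_attached)` (with `w` the
#' normalized attachment-window weights, so new bridges form near zero
#' strain) and first-order detachment `g(dx_i) * bound_i`. The detached
#' pool derivative is minus the bin sum, so total myosin is conserved
#' exactly.
#'
#' @param state A [fibre_state()].
#' @param xb A [crossbridge_params()].
#' @param grid A [strain_grid()] (defaults to the grid the state was
#'   built on).
#' @return List with `bound` (per-bin derivative, s^-1) and `detached`
#'   (scalar derivative, s^-1).
#' @export
myosin_derivatives <- function(state, xb, grid = state$grid) {
  avail <- state$actin_activated - state$cb_attached
  if (avail < -1e-12) {
    stop("state corruption: cb_attached exceeds actin_activated",
         call. = FALSE)
  }
  avail <- max(avail, 0)
  detached <- 1 - state$cb_attached
  f <- attachment_rate(grid$centres, xb)
  w <- attachment_weights(grid, xb)
  g <- detachment_rate(grid$centres, xb)
  dbound <- f * w * detached * avail - g * state$bound_myosin
  list(bound = dbound, detached = -sum(dbound))
}

#' Half-sarcomere stress
#'
#' Sum of cross-bridge spring forces and the parallel passive element,
#' expressed as stress (N m^-2):
#' \deqn{\sigma = 10^{-9} \rho_{cb} \sum_i k_{cb} (\Delta x_i + x_{ps}) M_i +
#'       k_{pas} (l_{hs} - l_{slack})}
#' Each bound bridge is a spring pre-strained by the power-stroke
#' displacement \eqn{x_{ps}}, so its force vanishes at the
#' detachment-rate minimum rather than at the attachment strain. The
#' passive term is signed linear; it goes negative below the slack length
#' by design.
#'
#' @param state A [fibre_state()].
#' @param params A [fibre_params()].
#' @param grid A [strain_grid()] (defaults to the grid the state was
#'   built on).
#' @return Stress, N m^-2.
#' @export
stress <- function(state, params, grid = state$grid) {
  cb_term <- 1e-9 * params$xb$cb_density * params$xb$cb_stiffness *
    sum((grid$centres + params$xb$power_stroke) * state$bound_myosin)
  pas_term <- params$passive$passive_stiffness *
    (state$hs_length - params$passive$length_slack)
  cb_term + pas_term
}

# Mass-conserving linear-interpolation shift of a binned distribution by
# `shift_bins` bins (any real number). Mass pushed beyond the grid is
# returned in `lost`.
shift_distribution <- function(bound, shift_bins) {
  n <- length(bound)
  k <- floor(shift_bins)
  frac <- shift_bins - k
  out <- numeric(n)
  lost <- 0
  for (j in seq_len(n)) {
    m <- bound[j]
    if (m == 0) next
    d1 <- j + k
    d2 <- j + k + 1
    if (d1 >= 1 && d1 <= n) out[d1] <- out[d1] + (1 - frac) * m
    else lost <- lost + (1 - frac) * m
    if (frac > 0) {
      if (d2 >= 1 && d2 <= n) out[d2] <- out[d2] + frac * m
      else lost <- lost + frac * m
    }
  }
  list(bound = out, lost = lost)
}

#' Advance a fibre state by one time step
#'
#' Operator-split integration step: (1) kinetics sub-step -- explicit Euler
#' for the activated-actin fraction and exponential Euler per strain bin
#' for the bound-myosin distribution (attachment flux frozen over the
#' step, detachment integrated exactly); (2) advection sub-step -- the
#' bound distribution is translated along the strain axis by the realized
#' length change with mass-conserving linear interpolation onto the grid.
#'
#' The commanded length acts as an upper bound on the realized
#' half-sarcomere length: when imposing it would make the total stress
#' negative, the fibre falls slack (it buckles rather than bear
#' compression), the realized length stays at the zero-stress length
#' (obtained in closed form, since stress is linear in the advection
#' shift), and the fibre carries zero stress until the command
#' re-engages it. Set `allow_slack = FALSE` to impose the length
#' unconditionally.
#'
#' This is the reference (pure R) implementation of the step used by the
#' compiled trace simulator; the two are held to agreement in the tests.
#'
#' @param state A [fibre_state()].
#' @param dt Time step, s.
#' @param next_length Commanded half-sarcomere length at `time + dt`, nm.
#' @param allow_slack Permit the fibre to fall slack instead of bearing
#'   negative stress.
#' @param Ca Calcium concentration, molar.
#' @param params A [fibre_params()].
#' @param grid A [strain_grid()].
#' @param overflow_tol Maximum tolerated occupancy of the outermost strain
#'   bins after the advection sub-step (bridges advected past the edge are
#'   forcibly detached; the grid must be wide enough for that to be
#'   negligible).
#' @return The updated `fibre_state`.
#' @export
advance <- function(state, dt, next_length, Ca, params,
                    grid = strain_grid(), overflow_tol = 1e-6,
                    allow_slack = FALSE) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)

  # kinetics sub-step
  dA <- actin_derivative(state, params$thin, Ca)
  A_new <- min(max(state$actin_activated + dt * dA, state$cb_attached), 1)

  avail <- max(state$actin_activated - state$cb_attached, 0)
  detached <- 1 - state$cb_attached
  f <- attachment_rate(grid$centres, params$xb)
  w <- attachment_weights(grid, params$xb)
  g <- detachment_rate(grid$centres, params$xb)
  a_flux <- f * w * detached * avail
  decay <- exp(-g * dt)
  gain <- ifelse(g > 0, (1 - decay) / g, dt)
  bound <- state$bound_myosin * decay + a_flux * gain

  # advection sub-step: every attached bridge's strain grows with the
  # realized half-sarcomere length change
  delta <- next_length - state$hs_length
  if (allow_slack) {
    cb_scale <- 1e-9 * params$xb$cb_density * params$xb$cb_stiffness
    cb_now <- sum(bound)
    sx <- sum((grid$centres + params$xb$power_stroke) * bound)
    # stress after a shift d: cb_scale*(sx + d*cb) + k_pas*(L + d - slack)
    slope <- cb_scale * cb_now + params$passive$passive_stiffness
    s_cmd <- cb_scale * sx + params$passive$passive_stiffness *
      (state$hs_length - params$passive$length_slack) + slope * delta
    if (s_cmd < 0 && slope > 0) {
      delta <- delta - s_cmd / slope  # zero-stress length (> commanded)
    }
  }
  if (delta != 0) {
    sh <- shift_distribution(bound, delta / grid$width)
    edge <- max(sh$bound[1], sh$bound[length(sh$bound)])
    if (edge > overflow_tol) {
      stop("strain-grid overflow: outermost-bin occupancy reached ",
           format(edge), "; widen the grid", call. = FALSE)
    }
  } else {
    sh <- list(bound = bound, lost = 0)
  }

  fibre_state(params, grid,
              hs_length = state$hs_length + delta,
              actin_activated = A_new,
              bound_myosin = sh$bound,
              time = state$time + dt)
}
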