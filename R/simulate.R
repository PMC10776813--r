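#' Simulate one intrafusal fibre through a stretch protocol
#'
#' Integrates the half-sarcomere model (thin-filament activation, two-state
#' cross-bridge distribution, passive element) along an imposed length and
#' calcium protocol. The protocol is resampled onto the integration grid by
#' linear interpolation; integration uses the operator-split step of
#' [advance()] implemented in compiled code for speed.
#'
#' Simulations are fully deterministic; there is no randomness anywhere in
#' the model.
#'
#' @param protocol A length/activation protocol as produced by
#'   [ramp_hold()], [triangle_pair()] or [sinusoid_protocol()], i.e. a
#'   data frame with columns `time_s`, `length_nm`, `pCa`.
#' @param params A [fibre_params()].
#' @param dt Integration time step, s. The default (0.1 ms) keeps
#'   `dt * g(dx)` well below one for the largest detachment rates on the
#'   default grid; adequacy is enforced by a refinement test.
#' @param grid A [strain_grid()].
#' @param init Optional initial [fibre_state()]; defaults to zero bound
#'   myosin and zero activated actin at the protocol's starting length.
#' @param record_distribution Snapshot stride for the bound distribution
#'   (0 = do not record; `k` = keep every k-th sample).
#' @param overflow_tol Maximum tolerated occupancy of the outermost strain
#'   bins. Bridges advected past the grid edge are forcibly detached
#'   (returned to the detached pool, so myosin is still conserved); the
#'   grid is adequate only while the edge bins stay essentially empty, and
#'   an error is raised otherwise.
#' @param allow_slack Let the fibre fall slack (zero stress, realized
#'   length above the command) instead of bearing negative stress; see
#'   [advance()].
#' @return A data frame of class `fibre_trace` with columns `time_s`,
#'   `commanded_nm` (imposed length), `length_nm` (realized length;
#'   differs from the command only while slack), `pCa`, `n_overlap`,
#'   `actin_activated`, `cb_attached`, `stress`, and attributes `params`,
#'   `grid`, `final_state`, `distribution` (matrix or NULL) and
#'   `protocol_events`.
#' @examples
#' \donttest{
#' tr <- simulate_fibre(ramp_hold(), fibre_params("bag"))
#' max(tr$stress)
#' }
#' @export
simulate_fibre <- function(protocol, params, dt = 1e-4,
                           grid = strain_grid(), init = NULL,
                           record_distribution = 0, overflow_tol = 1e-6,
                           allow_slack = FALSE) {
  stopifnot(is.data.frame(protocol),
            all(c("time_s", "length_nm", "pCa") %in% names(protocol)))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)

  t_end <- max(protocol$time_s)
  time <- seq(0, t_end, by = dt)
  len <- approx(protocol$time_s, protocol$length_nm, xout = time,
                rule = 2)$y
  pca <- approx(protocol$time_s, protocol$pCa, xout = time, rule = 2)$y
  ca <- pca_to_molar(pca)

  if (is.null(init)) {
    init <- fibre_state(params, grid, hs_length = len[1])
  }

  g <- detachment_rate(grid$centres, params$xb)
  f <- attachment_rate(grid$centres, params$xb)
  w <- attachment_weights(grid, params$xb)
  decay <- exp(-g * dt)
  gain <- ifelse(g > 0, (1 - decay) / g, dt)

  res <- sim_fibre_cpp(
    length_nm = len, ca_molar = ca, dt = dt,
    k_on = params$thin$k_on, k_off = params$thin$k_off,
    k_coop = params$thin$k_coop,
    centres = grid$centres, bin_width = grid$width,
    attach_coeff = f * w, g_rate = g, decay = decay, gain = gain,
    cb_scale = 1e-9 * params$xb$cb_density * params$xb$cb_stiffness,
    power_stroke = params$xb$power_stroke,
    passive_stiffness = params$passive$passive_stiffness,
    length_slack = params$passive$length_slack,
    l_thin = params$geometry$length_thin_filament,
    l_thick = params$geometry$length_thick_filament,
    l_bare = params$geometry$length_bare_zone,
    actin0 = init$actin_activated, bound0 = init$bound_myosin,
    dist_stride = as.integer(record_distribution),
    allow_slack = allow_slack
  )
  if (res$edge_occupancy > overflow_tol) {
    stop("strain-grid overflow: outermost-bin occupancy reached ",
         format(res$edge_occupancy), "; widen the grid", call. = FALSE)
  }

  out <- data.frame(
    time_s = time, commanded_nm = len, length_nm = res$length_real,
    pCa = pca,
    n_overlap = res$n_overlap,
    actin_activated = res$actin_activated,
    cb_attached = res$cb_attached,
    stress = res$stress
  )
  attr(out, "params") <- params
  attr(out, "grid") <- grid
  attr(out, "final_state") <- fibre_state(
    params, grid, hs_length = res$length_real[length(time)],
    actin_activated = res$actin_activated[length(time)],
    bound_myosin = res$bound_final, time = t_end)
  attr(out, "distribution") <-
    if (record_distribution > 0) res$distribution else NULL
  attr(out, "forced_detached") <- res$forced_detached
  attr(out, "edge_occupancy") <- res$edge_occupancy
  attr(out, "protocol_events") <- attr(protocol, "events")
  class(out) <- c("fibre_trace", "data.frame")
  out
}

#' Simulate both intrafusal fibres and the Ia receptor potential
#'
#' Runs the bag and chain fibres through the same protocol and combines
#' their stress traces into the receptor potential via
#' [receptor_potential()].
#'
#' @inheritParams simulate_fibre
#' @param bag,chain [fibre_params()] for the two fibres.
#' @param weights A [receptor_weights()].
#' @return A `spindle_trace` data frame (see [receptor_potential()]) with
#'   additional columns `length_nm`, `bag_stress`, `chain_stress` and the
#'   protocol's event annotation in `attr(, "protocol_events")`.
#' @export
simulate_spindle <- function(protocol,
                             bag = fibre_params("bag"),
                             chain = fibre_params("chain"),
                             weights = receptor_weights(),
                             dt = 1e-4, grid = strain_grid()) {
  tb <- simulate_fibre(protocol, bag, dt = dt, grid = grid)
  tc <- simulate_fibre(protocol, chain, dt = dt, grid = grid)
  out <- receptor_potential(tb$stress, tc$stress, weights = weights,
                            dt = dt, time = tb$time_s)
  out$length_nm <- tb$length_nm
  out$bag_stress <- tb$stress
  out$chain_stress <- tc$stress
  attr(out, "protocol_events") <- attr(protocol, "events")
  attr(out, "weights") <- weights
  out
}
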