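#' Thick/thin filament geometry of the half-sarcomere
#'
#' Structural constants of the contractile unit. All lengths are in
#' nanometres. The defaults are the values used for both intrafusal fibres:
#' thin filament 1120 nm, thick filament 815 nm, bare zone 80 nm, resting
#' half-sarcomere length \eqn{L_0} = 1300 nm.
#'
#' @param length_thin_filament Thin (actin) filament length, nm.
#' @param length_thick_filament Thick (myosin) filament length, nm.
#' @param length_bare_zone Length of the myosin-free bare zone, nm.
#' @param resting_length_L0 Resting end-to-end half-sarcomere length, nm.
#' @return An object of class `filament_geometry`.
#' @export
filament_geometry <- function(length_thin_filament = 1120,
                              length_thick_filament = 815,
                              length_bare_zone = 80,
                              resting_length_L0 = 1300) {
  g <- list(
    length_thin_filament = length_thin_filament,
    length_thick_filament = length_thick_filament,
    length_bare_zone = length_bare_zone,
    resting_length_L0 = resting_length_L0
  )
  if (any(unlist(g) <= 0)) {
    stop("all filament lengths must be positive", call. = FALSE)
  }
  if (length_bare_zone >= length_thick_filament) {
    stop("length_bare_zone must be smaller than length_thick_filament",
         call. = FALSE)
  }
  structure(g, class = "filament_geometry")
}

#' Thin-filament (actin) activation parameters
#'
#' Rate constants of calcium-mediated actin-site activation. `k_on` is the
#' second-order activation rate (per molar per second), `k_off` the
#' deactivation rate (per second), and `k_coop` the dimensionless
#' inter-filament cooperativity gain by which bound myosin biases
#' activation over deactivation.
#'
#' @param k_on Activation rate constant, M^-1 s^-1.
#' @param k_off Deactivation rate constant, s^-1.
#' @param k_coop Cooperativity coefficient, dimensionless.
#' @return An object of class `thin_filament_params`.
#' @export
thin_filament_params <- function(k_on = 8e7, k_off = 200, k_coop = 1) {
  if (k_on < 0 || k_off < 0 || k_coop < 0) {
    stop("thin-filament rate constants must be non-negative", call. = FALSE)
  }
  structure(list(k_on = k_on, k_off = k_off, k_coop = k_coop),
            class = "thin_filament_params")
}

#' Two-state cross-bridge rate and stiffness parameters
#'
#' Parameters of the strain-dependent attachment rate
#' \eqn{f(\Delta x) = f_0 \exp(-k_{cb}\Delta x^2 / c_f)} and the piecewise
#' cubic detachment rate
#' \eqn{g(\Delta x) = \max(g_0 + c_\pm (\Delta x - x_b)^3, 0) + g_{off}}
#' (see [detachment_rate()]), together
#' with the spring constant of an attached head, the power-stroke
#' displacement setting the zero-force strain, and the areal density of
#' heads used to convert bound fractions to stress.
#'
#' `attach_slope` and `detach_offset` are the two per-fibre tuned rates
#' (bag: 600 and 7 s^-1; chain: 400 and 300 s^-1).
#' `detach_extra_offset` is the fixed per-fibre vertical offset of the
#' detachment curve (bag 0.5, chain 10 s^-1).
#'
#' @param attach_slope Peak attachment rate at zero strain, s^-1.
#' @param detach_offset Tuned vertical offset of the detachment curve, s^-1.
#' @param detach_extra_offset Fixed additional detachment offset, s^-1.
#' @param detach_coeff_below Cubic coefficient below the breakpoint,
#'   s^-1 nm^-3.
#' @param detach_coeff_above Cubic coefficient at or above the breakpoint,
#'   s^-1 nm^-3.
#' @param detach_breakpoint Strain of minimum detachment rate, nm.
#' @param power_stroke Power-stroke displacement, nm: a bridge attaching
#'   at strain 0 is pre-strained by its power stroke, so the spring force
#'   of a bound bridge is `cb_stiffness * (strain + power_stroke)` and the
#'   force zero coincides with the detachment-rate minimum.
#' @param cb_density Cross-bridges per unit cross-sectional area, m^-2.
#' @param cb_stiffness Stiffness of one cross-bridge, pN nm^-1.
#' @param const_f Thermal-energy constant setting the attachment window
#'   width, pN nm.
#' @return An object of class `crossbridge_params`.
#' @export
crossbridge_params <- function(attach_slope = 600,
                               detach_offset = 7,
                               detach_extra_offset = 0.5,
                               detach_coeff_below = 0.2,
                               detach_coeff_above = 0.3,
                               detach_breakpoint = -5,
                               power_stroke = 5,
                               cb_density = 6.9e16,
                               cb_stiffness = 0.001,
                               const_f = 7.2e-2) {
  p <- list(
    attach_slope = attach_slope,
    detach_offset = detach_offset,
    detach_extra_offset = detach_extra_offset,
    detach_coeff_below = detach_coeff_below,
    detach_coeff_above = detach_coeff_above,
    detach_breakpoint = detach_breakpoint,
    power_stroke = power_stroke,
    cb_density = cb_density,
    cb_stiffness = cb_stiffness,
    const_f = const_f
  )
  nonneg <- c("attach_slope", "detach_offset", "detach_extra_offset",
              "detach_coeff_below", "detach_coeff_above", "cb_density",
              "cb_stiffness", "const_f")
  if (any(unlist(p[nonneg]) < 0)) {
    stop("cross-bridge rates and stiffnesses must be non-negative",
         call. = FALSE)
  }
  structure(p, class = "crossbridge_params")
}

#' Parallel passive-element parameters
#'
#' Linear elastic element in parallel with the cross-bridges. Stress
#' contribution is `passive_stiffness * (hs_length - length_slack)`, signed
#' (compressive below slack; no clipping).
#'
#' @param passive_stiffness Passive stiffness, N m^-2 nm^-1.
#' @param length_slack Slack length of the passive element, nm.
#' @return An object of class `passive_params`.
#' @export
passive_params <- function(passive_stiffness = 90, length_slack = 1050) {
  if (passive_stiffness < 0) {
    stop("passive_stiffness must be non-negative", call. = FALSE)
  }
  structure(list(passive_stiffness = passive_stiffness,
                 length_slack = length_slack),
            class = "passive_params")
}

#' Complete parameter bundle for one intrafusal fibre
#'
#' Assembles geometry, thin-filament, cross-bridge and passive parameters
#' for either the dynamic bag1 fibre (`"bag"`) or the static bag2/chain
#' fibre (`"chain"`). Per-fibre defaults:
#'
#' \tabular{lcc}{
#'                      \tab bag   \tab chain \cr
#' attach slope (s^-1)  \tab 600   \tab 400   \cr
#' detach offset (s^-1) \tab 7     \tab 300   \cr
#' extra offset (s^-1)  \tab 0.5   \tab 10    \cr
#' passive (N m^-2 nm^-1) \tab 90  \tab 250   \cr
#' slack length (nm)    \tab 1050  \tab 1200
#' }
#'
#' Individual components can be overridden via `...` using the component
#' argument names of [thin_filament_params()] / [crossbridge_params()] /
#' [passive_params()] (e.g. `k_coop = 0`, `detach_offset = 70`).
#'
#' @param fibre `"bag"` or `"chain"`.
#' @param ... Named overrides of any thin-filament, cross-bridge or passive
#'   parameter, or `geometry = filament_geometry(...)`.
#' @return An object of class `fibre_params` with components `fibre`,
#'   `geometry`, `thin`, `xb`, `passive`.
#' @examples
#' bag <- fibre_params("bag")
#' chain_nocoop <- fibre_params("chain", k_coop = 0)
#' @export
fibre_params <- function(fibre = c("bag", "chain"), ...) {
  fibre <- match.arg(fibre)
  dots <- list(...)
  geometry <- dots$geometry %||% filament_geometry()
  dots$geometry <- NULL

  defaults <- switch(fibre,
    bag = list(attach_slope = 600, detach_offset = 7,
               detach_extra_offset = 0.5,
               passive_stiffness = 90, length_slack = 1050),
    chain = list(attach_slope = 400, detach_offset = 300,
                 detach_extra_offset = 10,
                 passive_stiffness = 250, length_slack = 1200)
  )

  take <- function(ctor, names_in) {
    args <- defaults[intersect(names(defaults), names_in)]
    args <- modifyList(args, dots[intersect(names(dots), names_in)])
    do.call(ctor, args)
  }
  thin_names <- names(formals(thin_filament_params))
  xb_names <- names(formals(crossbridge_params))
  pas_names <- names(formals(passive_params))
  unknown <- setdiff(names(dots), c(thin_names, xb_names, pas_names))
  if (length(unknown)) {
    stop("unknown fibre parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  structure(list(
    fibre = fibre,
    geometry = geometry,
    thin = take(thin_filament_params, thin_names),
    xb = take(crossbridge_params, xb_names),
    passive = take(passive_params, pas_names)
  ), class = "fibre_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fibre_params <- function(x, ...) {
  cat("<fibre_params> ", x$fibre, " fibre\n", sep = "")
  cat("  thin filament: k_on ", format(x$thin$k_on), " /M/s, k_off ",
      x$thin$k_off, " /s, k_coop ", x$thin$k_coop, "\n", sep = "")
  cat("  cross-bridges: attach slope ", x$xb$attach_slope,
      " /s, detach offset ", x$xb$detach_offset, " + ",
      x$xb$detach_extra_offset, " /s\n", sep = "")
  cat("  passive: ", x$passive$passive_stiffness, " N/m^2/nm, slack ",
      x$passive$length_slack, " nm\n", sep = "")
  invisible(x)
}

#' Receptor-potential weighting constants
#'
#' Weights of the phenomenological Ia receptor-potential model: the
#' potential is the weighted sum of chain force, bag force and half-wave
#' rectified bag yank, divided by a fixed force-to-potential conversion
#' `scale` so that responses come out in order-one arbitrary units.
#'
#' @param k_fb Weight on bag-fibre force, a.u.
#' @param k_fc Weight on chain-fibre force, a.u.
#' @param k_yb Weight on (rectified) bag-fibre yank, a.u.
#' @param scale Force-to-receptor-potential conversion divisor, a.u.
#' @return An object of class `receptor_weights`.
#' @export
receptor_weights <- function(k_fb = 0.4, k_fc = 0.5, k_yb = 0.005,
                             scale = 2e5) {
  if (any(c(k_fb, k_fc, k_yb, scale) < 0) || scale == 0) {
    stop("receptor weights must be non-negative and scale positive",
         call. = FALSE)
  }
  structure(list(k_fb = k_fb, k_fc = k_fc, k_yb = k_yb, scale = scale),
            class = "receptor_weights")
}

#' Cross-bridge strain grid
#'
#' Uniform discretization of cross-bridge strain used to resolve the bound
#' myosin distribution. Bin centres are placed at
#' `lower + width/2, ..., upper - width/2`. The default grid (0.25 nm bins
#' over -150..+40 nm) brackets the detachment-rate breakpoint at -5 nm and
#' is wide enough that bound mass advected to the edges has detached to
#' negligible levels for the shipped protocols. It is asymmetric because
#' the two sides die off very differently: extension-side detachment grows
#' as the cube of strain (bridges beyond +15 nm detach at >2000 s^-1),
#' while compressed bridges release only at the slow floor rate, so the
#' compression tail stretches tens of nm during a shorten. The simulator
#' raises an error if the outermost bins are ever populated above
#' tolerance.
#'
#' @param lower Lower strain bound, nm (must be < detachment breakpoint).
#' @param upper Upper strain bound, nm.
#' @param width Bin width, nm.
#' @return An object of class `strain_grid` with elements `centres`,
#'   `width`, `lower`, `upper`.
#' @export
strain_grid <- function(lower = -150, upper = 40, width = 0.25) {
  if (upper <= lower || width <= 0) {
    stop("invalid strain grid bounds", call. = FALSE)
  }
  n <- round((upper - lower) / width)
  if (abs(n * width - (upper - lower)) > 1e-9) {
    stop("grid width must divide the grid span evenly", call. = FALSE)
  }
  structure(list(
    centres = lower + width * (seq_len(n) - 0.5),
    width = width, lower = lower, upper = upper
  ), class = "strain_grid")
}

#' Convert pCa to molar calcium concentration
#'
#' @param pCa Negative decimal logarithm of the calcium concentration.
#' @return Calcium concentration in molar, `10^(-pCa)`.
#' @examples
#' pca_to_molar(6.4) # ~3.98e-7 M
#' @export
pca_to_molar <- function(pCa) {
  if (any(pCa <= 0)) stop("pCa must be positive", call. = FALSE)
  10^(-pCa)
}
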