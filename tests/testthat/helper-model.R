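# Shared fixtures: small grids, fast protocols, and an exact single-bin
# reference solution used as an independent oracle for the engine.

# One strain bin centred at 0: the engine reduces to the scalar two-state
# ODE db/dt = f0 (1 - b)(A0 - b) - g0 b.
single_bin_grid <- function() strain_grid(-0.25, 0.25, 0.5)

# Parameters that freeze everything except a flat attachment/detachment
# pair (f = f0 at strain 0, g = g0 everywhere, actin clamped at A0).
single_bin_params <- function(f0 = 2, g0 = 3) {
  fibre_params("bag", attach_slope = f0, detach_offset = g0,
               detach_extra_offset = 0, detach_coeff_below = 0,
               detach_coeff_above = 0, k_on = 0, k_off = 0)
}

# Closed-form solution of the constant-coefficient Riccati equation
# db/dt = f0 b^2 - (f0 (1 + A0) + g0) b + f0 A0 with b(0) = 0.
two_state_closed_form <- function(t, f0, g0, A0) {
  B <- f0 * (1 + A0) + g0
  disc <- sqrt(B^2 - 4 * f0^2 * A0)
  r1 <- (B - disc) / (2 * f0)
  r2 <- (B + disc) / (2 * f0)
  k <- f0 * (r2 - r1)
  r1 * r2 * (1 - exp(-k * t)) / (r2 - r1 * exp(-k * t))
}

# Isometric protocol at L0 (pure kinetics, no advection).
isometric_protocol <- function(t_end = 1, pCa = 6.4, L0 = 1300) {
  data.frame(time_s = c(0, t_end), length_nm = c(L0, L0),
             pCa = c(pCa, pCa))
}

# Rate-free cross-bridge parameters: no attachment, no detachment, so the
# only dynamics left is advection of whatever is bound.
frozen_params <- function() {
  fibre_params("bag", attach_slope = 0, detach_offset = 0,
               detach_extra_offset = 0, detach_coeff_below = 0,
               detach_coeff_above = 0, k_on = 0, k_off = 0)
}
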