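# Sweep drivers reproducing the study designs: the thin-filament ablation
# ladder, the myosin rate sweep, and the three history-dependence sweeps.

#' Thin-filament model variants
#'
#' The ablation ladder used to isolate the contribution of each
#' thin-filament mechanism: `"activation_only"` (sites activate but never
#' deactivate: `k_off = 0`, `k_coop = 0`), `"activation_plus_deactivation"`
#' (`k_coop = 0`), and `"full_with_cooperativity"` (`k_coop = 1`).
#'
#' @param variant Variant name (abbreviations allowed; `"full"` matches
#'   the cooperativity variant).
#' @return List of thin-filament overrides (`k_off`, `k_coop`) plus the
#'   resolved `name`.
#' @export
model_variant <- function(variant = c("full_with_cooperativity",
                                      "activation_only",
                                      "activation_plus_deactivation")) {
  variant <- match.arg(variant)
  switch(variant,
    activation_only = list(name = variant, k_off = 0, k_coop = 0),
    activation_plus_deactivation = list(name = variant, k_off = 200,
                                        k_coop = 0),
    full_with_cooperativity = list(name = variant, k_off = 200,
                                   k_coop = 1)
  )
}

#' Bag and chain parameter sets for a model variant
#'
#' Builds the paired [fibre_params()] for a thin-filament variant with the
#' given myosin rates (defaults are the tuned final rates: bag attachment
#' 600, bag detachment 7, chain attachment 400, chain detachment 300 s^-1).
#'
#' @param variant A thin-filament variant name (see [model_variant()]).
#' @param b_f,b_g Bag attachment slope and detachment offset, s^-1.
#' @param c_f,c_g Chain attachment slope and detachment offset, s^-1.
#' @return List with `bag` and `chain` [fibre_params()].
#' @export
model_fibres <- function(variant = "full_with_cooperativity",
                         b_f = 600, b_g = 7, c_f = 400, c_g = 300) {
  v <- model_variant(variant)
  list(
    bag = fibre_params("bag", attach_slope = b_f, detach_offset = b_g,
                       k_off = v$k_off, k_coop = v$k_coop),
    chain = fibre_params("chain", attach_slope = c_f, detach_offset = c_g,
                         k_off = v$k_off, k_coop = v$k_coop)
  )
}

#' Thin-filament ablation ladder
#'
#' Runs the paired-triangle stretch-shorten protocol (and optionally the
#' ramp-and-hold) for each thin-filament variant and reports the recovery
#' time of bag stress, chain stress and total receptor potential after the
#' second stretch onset.
#'
#' @param variants Character vector of variant names.
#' @param velocity,amplitude Triangle velocity (%L0/s) and amplitude
#'   (%L0).
#' @param dt Integration step, s.
#' @param keep_traces Keep the simulated traces in `attr(, "traces")`.
#' @return Data frame with one row per variant and columns
#'   `bag_recovery_s`, `chain_recovery_s`, `rtotal_recovery_s`.
#' @export
run_thin_filament_ladder <- function(variants = c("activation_only",
                                                  "activation_plus_deactivation",
                                                  "full_with_cooperativity"),
                                     velocity = 12, amplitude = 5.6,
                                     dt = 1e-4, keep_traces = FALSE) {
  proto <- triangle_pair(velocity = velocity, cond_amplitude = amplitude,
                         test_amplitude = amplitude, isi = 0)
  ev <- attr(proto, "events")
  traces <- list()
  rows <- lapply(variants, function(v) {
    fb <- model_fibres(v)
    tr <- simulate_spindle(proto, bag = fb$bag, chain = fb$chain, dt = dt)
    if (keep_traces) traces[[v]] <<- tr
    rec <- function(sig) recovery_time(tr, ev$test_onset, ev$cond_onset,
                                       signal = sig)
    data.frame(variant = v,
               bag_recovery_s = rec("bag_stress"),
               chain_recovery_s = rec("chain_stress"),
               rtotal_recovery_s = rec("rtotal_au"))
  })
  out <- do.call(rbind, rows)
  if (keep_traces) attr(out, "traces") <- traces
  out
}

#' Myosin rate sweep over the ramp-and-hold protocol
#'
#' Simulates the ramp-and-hold stretch for every combination of the
#' supplied bag detachment offsets and chain attachment slopes (the two
#' rates the receptor potential is most sensitive to), with the remaining
#' rates fixed, and extracts the receptor-potential features.
#'
#' @param b_g_values Bag detachment offsets to scan, s^-1.
#' @param c_f_values Chain attachment slopes to scan, s^-1.
#' @param b_f,c_g Fixed bag attachment slope / chain detachment offset,
#'   s^-1.
#' @param velocity,amplitude Ramp velocity (%L0/s) and amplitude (%L0).
#' @param dt Integration step, s.
#' @return Data frame with the rate combination and `initial_burst`,
#'   `dynamic_response`, `dynamic_slope`, `dynamic_index` per row.
#' @export
run_rate_sweep <- function(b_g_values = 7 * c(0.1, 1, 10),
                           c_f_values = 400 * c(1, 10),
                           b_f = 600, c_g = 300,
                           velocity = 36, amplitude = 5.6, dt = 1e-4) {
  proto <- ramp_hold(velocity = velocity, amplitude = amplitude)
  grid_df <- expand.grid(b_g = b_g_values, c_f = c_f_values,
                         KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid_df)), function(i) {
    fb <- model_fibres("full_with_cooperativity", b_f = b_f,
                       b_g = grid_df$b_g[i], c_f = grid_df$c_f[i],
                       c_g = c_g)
    tr <- simulate_spindle(proto, bag = fb$bag, chain = fb$chain, dt = dt)
    cbind(data.frame(b_f = b_f, b_g = grid_df$b_g[i],
                     c_f = grid_df$c_f[i], c_g = c_g),
          extract_features(tr))
  })
  do.call(rbind, rows)
}

burst_pair <- function(tr, ev, reference = NULL) {
  # conditioning and test bursts referenced to the common pre-conditioning
  # resting baseline (well defined for every ISI, including 0)
  cond <- initial_burst(tr, ev$cond_onset, ev$cond_apex)
  test <- initial_burst(tr, ev$test_onset, ev$test_apex,
                        reference = reference %||% cond$value,
                        baseline_at = ev$cond_onset)
  list(cond = cond, test = test)
}

#' Inter-stretch-interval sweep of paired triangular stretches
#'
#' Paired stretch-shorten triangles with varying rest interval between
#' them; reports the conditioning- and test-stretch initial bursts of the
#' receptor potential and whether a detectable burst is present on the
#' test stretch (threshold: 2% of the conditioning burst).
#'
#' @param isis Inter-stretch intervals to scan, s.
#' @param velocity,amplitude Triangle velocity (%L0/s) and amplitude
#'   (%L0).
#' @param fibres Paired parameters from [model_fibres()].
#' @param dt Integration step, s.
#' @return Data frame with columns `isi`, `cond_burst`, `test_burst`,
#'   `ratio_pct`, `burst_present`.
#' @export
isi_sweep <- function(isis = seq(0, 10, by = 0.1), velocity = 12,
                      amplitude = 5.6, fibres = model_fibres(),
                      dt = 1e-4) {
  rows <- lapply(isis, function(isi) {
    proto <- triangle_pair(velocity = velocity, cond_amplitude = amplitude,
                           test_amplitude = amplitude, isi = isi)
    ev <- attr(proto, "events")
    tr <- simulate_spindle(proto, bag = fibres$bag, chain = fibres$chain,
                           dt = dt)
    b <- burst_pair(tr, ev)
    data.frame(isi = isi, cond_burst = b$cond$value,
               test_burst = b$test$value,
               ratio_pct = 100 * b$test$value / b$cond$value,
               burst_present = b$test$burst_present)
  })
  do.call(rbind, rows)
}

#' Conditioning-amplitude sweep of paired triangular stretches
#'
#' Back-to-back triangles (ISI 0) with a varying conditioning amplitude
#' and a fixed test amplitude; reports the test-stretch initial burst
#' relative to the unconditioned (0 %L0 conditioning) burst.
#'
#' @param cond_amplitudes Conditioning amplitudes to scan, %L0.
#' @param test_amplitude Fixed test amplitude, %L0.
#' @inheritParams isi_sweep
#' @return Data frame with columns `cond_amplitude`, `test_burst`,
#'   `ratio_pct` (of the unconditioned burst), `burst_present`.
#' @export
amplitude_sweep <- function(cond_amplitudes = seq(0, 5.6, by = 0.1),
                            test_amplitude = 5.6, velocity = 12,
                            fibres = model_fibres(), dt = 1e-4) {
  one <- function(amp, reference = NULL) {
    proto <- triangle_pair(velocity = velocity, cond_amplitude = amp,
                           test_amplitude = test_amplitude, isi = 0)
    ev <- attr(proto, "events")
    tr <- simulate_spindle(proto, bag = fibres$bag, chain = fibres$chain,
                           dt = dt)
    initial_burst(tr, ev$test_onset, ev$test_apex, reference = reference,
                  baseline_at = ev$cond_onset)
  }
  uncond <- one(0)$value
  rows <- lapply(cond_amplitudes, function(amp) {
    b <- one(amp, reference = uncond)
    data.frame(cond_amplitude = amp, test_burst = b$value,
               ratio_pct = 100 * b$value / uncond,
               burst_present = b$burst_present)
  })
  do.call(rbind, rows)
}

#' Sinusoid amplitude sweep
#'
#' Three sinusoidal stretch-shorten cycles at 1 Hz over a range of
#' amplitudes; reports the peak receptor potential of each cycle relative
#' to a zero-amplitude control simulation (subtracting the control trace
#' removes the residual slow equilibration of the resting fibre, so the
#' response vanishes as amplitude goes to zero). The first cycle carries
#' the initial burst; the second and third report the steady cyclic
#' response whose growth with amplitude is non-linear (steep at small
#' amplitudes, shallow at large).
#'
#' @param amplitudes Peak amplitudes to scan, %L0.
#' @param frequency Oscillation frequency, Hz.
#' @param n_cycles Number of cycles.
#' @inheritParams isi_sweep
#' @return Data frame with `amplitude` and `peak_cycle1` ..
#'   `peak_cycle<n>`.
#' @export
sinusoid_sweep <- function(amplitudes = c(0.0016, 0.016, 0.05, 0.16, 0.5,
                                          1.0, 1.6),
                           frequency = 1, n_cycles = 3,
                           fibres = model_fibres(), dt = 1e-4) {
  run <- function(a) {
    proto <- sinusoid_protocol(a, frequency = frequency,
                               n_cycles = n_cycles)
    tr <- simulate_spindle(proto, bag = fibres$bag, chain = fibres$chain,
                           dt = dt)
    list(trace = tr, events = attr(proto, "events"))
  }
  control <- run(0)
  rows <- lapply(amplitudes, function(a) {
    sim <- run(a)
    ev <- sim$events
    resp <- sim$trace$rtotal_au - control$trace$rtotal_au
    peaks <- vapply(seq_len(n_cycles), function(k) {
      win <- sim$trace$time_s >= ev$onset + (k - 1) * ev$period &
        sim$trace$time_s <= ev$onset + k * ev$period
      max(resp[win])
    }, numeric(1))
    row <- data.frame(amplitude = a)
    row[paste0("peak_cycle", seq_len(n_cycles))] <- as.list(peaks)
    row
  })
  do.call(rbind, rows)
}

#' All three history-dependence sweeps
#'
#' Convenience driver running the ISI sweep, the conditioning-amplitude
#' sweep and the sinusoid amplitude sweep with the tuned final model.
#'
#' @param isis,cond_amplitudes,sin_amplitudes Sweep grids.
#' @inheritParams isi_sweep
#' @return Named list of the three sweep tables.
#' @export
run_history_sweeps <- function(isis = seq(0, 10, by = 0.1),
                               cond_amplitudes = seq(0, 5.6, by = 0.1),
                               sin_amplitudes = c(0.0016, 0.016, 0.05,
                                                  0.16, 0.5, 1.0, 1.6),
                               fibres = model_fibres(), dt = 1e-4) {
  list(
    isi = isi_sweep(isis, fibres = fibres, dt = dt),
    amplitude = amplitude_sweep(cond_amplitudes, fibres = fibres, dt = dt),
    sinusoid = sinusoid_sweep(sin_amplitudes, fibres = fibres, dt = dt)
  )
}
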