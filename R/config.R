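# YAML model configuration and delimited trace I/O.
#
# The config mirrors the model's published parameter names verbatim
# (k_on, k_off, k_coop, b_f, b_g, c_f, c_g, offset_bag, offset_chain,
# passive_stiffness_bag, length_slack_bag, ...), so a file documents a
# complete, re-simulatable model.

#' Read a model configuration file
#'
#' Parses a YAML configuration into bag/chain [fibre_params()] and
#' [receptor_weights()]. Any omitted key falls back to the tuned default.
#' See `system.file("extdata", "tuned_model.yaml", package = "spindlesim")`
#' for the reference file.
#'
#' @param path Path to a YAML file.
#' @return List with `bag`, `chain` ([fibre_params()]) and `weights`
#'   ([receptor_weights()]).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geom <- cfg$geometry %||% list()
  geometry <- filament_geometry(
    length_thin_filament = geom$length_thin_filament %||% 1120,
    length_thick_filament = geom$length_thick_filament %||% 815,
    length_bare_zone = geom$length_bare_zone %||% 80,
    resting_length_L0 = geom$L0 %||% 1300
  )
  thin <- cfg$thin %||% list()
  xb <- cfg$crossbridge %||% list()
  bag <- cfg$bag %||% list()
  chain <- cfg$chain %||% list()

  common <- list(
    geometry = geometry,
    k_on = thin$k_on %||% 8e7,
    k_off = thin$k_off %||% 200,
    k_coop = thin$k_coop %||% 1,
    cb_density = xb$cb_density %||% 6.9e16,
    cb_stiffness = xb$cb_stiffness %||% 0.001,
    const_f = xb$const_f %||% 7.2e-2
  )
  bag_params <- do.call(fibre_params, c(list("bag"), common, list(
    attach_slope = bag$b_f %||% 600,
    detach_offset = bag$b_g %||% 7,
    detach_extra_offset = bag$offset_bag %||% 0.5,
    passive_stiffness = bag$passive_stiffness_bag %||% 90,
    length_slack = bag$length_slack_bag %||% 1050
  )))
  chain_params <- do.call(fibre_params, c(list("chain"), common, list(
    attach_slope = chain$c_f %||% 400,
    detach_offset = chain$c_g %||% 300,
    detach_extra_offset = chain$offset_chain %||% 10,
    passive_stiffness = chain$passive_stiffness_chain %||% 250,
    length_slack = chain$length_slack_chain %||% 1200
  )))
  w <- cfg$weights %||% list()
  weights <- receptor_weights(
    k_fb = w$kfb %||% 0.4, k_fc = w$kfc %||% 0.5,
    k_yb = w$kyb %||% 0.005, scale = w$scale %||% 2e5
  )
  list(bag = bag_params, chain = chain_params, weights = weights)
}

#' Write a model configuration file
#'
#' Serializes bag/chain [fibre_params()] and [receptor_weights()] to YAML
#' in the layout read by [read_model_config()].
#'
#' @param model List with `bag`, `chain` and `weights` components.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  b <- model$bag; ch <- model$chain; w <- model$weights
  cfg <- list(
    geometry = list(
      length_thin_filament = b$geometry$length_thin_filament,
      length_thick_filament = b$geometry$length_thick_filament,
      length_bare_zone = b$geometry$length_bare_zone,
      L0 = b$geometry$resting_length_L0
    ),
    thin = list(k_on = b$thin$k_on, k_off = b$thin$k_off,
                k_coop = b$thin$k_coop),
    crossbridge = list(cb_density = b$xb$cb_density,
                       cb_stiffness = b$xb$cb_stiffness,
                       const_f = b$xb$const_f),
    bag = list(b_f = b$xb$attach_slope, b_g = b$xb$detach_offset,
               offset_bag = b$xb$detach_extra_offset,
               passive_stiffness_bag = b$passive$passive_stiffness,
               length_slack_bag = b$passive$length_slack),
    chain = list(c_f = ch$xb$attach_slope, c_g = ch$xb$detach_offset,
                 offset_chain = ch$xb$detach_extra_offset,
                 passive_stiffness_chain = ch$passive$passive_stiffness,
                 length_slack_chain = ch$passive$length_slack),
    weights = list(kfb = w$k_fb, kfc = w$k_fc, kyb = w$k_yb,
                   scale = w$scale)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write / read a simulation trace as a delimited table
#'
#' Traces (protocols, fibre traces, spindle traces) are plain data frames;
#' these helpers round-trip them through CSV so external traces can be
#' injected into the feature-extraction stage.
#'
#' @param trace A data frame trace.
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` the
#'   data frame.
#' @export
write_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  read.csv(path)
}
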