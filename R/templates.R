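#' Render the noiseless per-channel ERP template of one condition
#'
#' Each component contributes an additive Gaussian pulse
#' `A * exp(-(t - mu)^2 / (2 * sigma^2))` centred at its peak latency, with
#' its signed amplitude and per-channel weighting.  Standards carry
#' obligatory responses only; deviants add their deviance-related
#' components.
#'
#' @param condition condition name (bookkeeping only).
#' @param components list of [component_spec()]s to superpose.
#' @param config a [paradigm_config()] defining the epoch grid.
#' @param channels channel names; defaults to [default_channels()].
#' @return numeric matrix, channels x samples, microvolts; channel names as
#'   rownames, sample times (ms) as the `time_ms` attribute.
#' @export
render_template <- function(condition, components, config,
                            channels = default_channels()) {
  t_ms <- epoch_times(config)
  out <- matrix(0, length(channels), length(t_ms),
                dimnames = list(channels, NULL))
  for (comp in components) {
    stopifnot(inherits(comp, "component_spec"))
    if (comp$peak_latency_ms < t_ms[1] || comp$peak_latency_ms > t_ms[length(t_ms)]) {
      stopf("component '%s' peak latency %g ms lies outside the epoch [%g, %g] ms",
            comp$name, comp$peak_latency_ms, t_ms[1], t_ms[length(t_ms)])
    }
    w <- comp$channel_weights %||% rep(1, length(channels))
    if (!is.null(names(w))) w <- w[channels]
    if (length(w) != length(channels) || anyNA(w)) {
      stopf("channel weights of component '%s' do not cover the montage",
            comp$name)
    }
    pulse <- comp$amplitude_uV *
      exp(-(t_ms - comp$peak_latency_ms)^2 / (2 * comp$width_ms^2))
    out <- out + outer(w, pulse)
  }
  attr(out, "time_ms") <- t_ms
  attr(out, "condition") <- condition
  out
}

#' Obligatory and deviance template pair for every condition
#'
#' @param config a [paradigm_config()].
#' @param components per-condition component sets, as from
#'   [default_components()].
#' @param channels montage channel names.
#' @return named list per condition: `list(obligatory =, deviance =)`
#'   channel x sample matrices.  `obligatory + deviance` is the full evoked
#'   template; the deviance part is what `block_presence_gain` scales.
#' @export
condition_templates <- function(config, components = default_components(),
                                channels = default_channels()) {
  lapply(stats::setNames(names(components), names(components)), function(cond) {
    list(obligatory = render_template(cond, components[[cond]]$obligatory,
                                      config, channels),
         deviance = render_template(cond, components[[cond]]$deviance,
                                    config, channels))
  })
}
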