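#' Detect a component peak within its search window
#'
#' Most negative (negative polarity) or most positive (positive polarity)
#' sample of the difference series inside the search window; ties resolve
#' to the earliest latency.
#'
#' @param values numeric difference series (ROI mean, deviant - standard).
#' @param time_ms per-sample times; taken from `attr(values, "time_ms")`
#'   when omitted.
#' @param window a [component_window()].
#' @return list with `peak_latency_ms` and `peak_amplitude_uV`.
#' @export
find_peak <- function(values, window, time_ms = NULL) {
  time_ms <- time_ms %||% attr(values, "time_ms")
  stopifnot(length(values) == length(time_ms))
  idx <- which(time_ms >= window$search_window_ms[1] &
                 time_ms <= window$search_window_ms[2])
  if (length(idx) == 0) stopf("search window contains no samples")
  v <- values[idx]
  k <- if (window$polarity == "negative") which.min(v) else which.max(v)
  list(peak_latency_ms = time_ms[idx[k]], peak_amplitude_uV = unname(v[k]))
}

#' Cohen's d on window-mean amplitudes
#'
#' Computes the standardized effect of `a` versus `b` on per-observation
#' mean amplitudes over a time window.  Paired design: `mean(diff) /
#' sd(diff)` across pairs.  Independent design: difference of group means
#' over the pooled SD across observations.  The small-sample bias-corrected
#' estimate (Hedges g) is returned alongside.
#'
#' @param a,b observations x samples matrices (paired: matched rows).
#' @param design `"paired"` or `"independent"`.
#' @param window_ms time window over which amplitudes are averaged.
#' @param time_ms per-sample times; default from `attr(a, "time_ms")`.
#' @return list with `d`, `hedges_g`, `window_ms`, `clipped` (window clipped
#'   at epoch bounds), `zero_variance` (d is signed infinity).
#' @export
cohens_d <- function(a, b, design = c("paired", "independent"),
                     window_ms, time_ms = NULL) {
  design <- match.arg(design)
  a <- as.matrix(a); b <- as.matrix(b)
  time_ms <- time_ms %||% attr(a, "time_ms") %||% seq_len(ncol(a))
  clipped <- window_ms[1] < time_ms[1] || window_ms[2] > time_ms[length(time_ms)]
  win <- pmax(pmin(window_ms, time_ms[length(time_ms)]), time_ms[1])
  idx <- which(time_ms >= win[1] & time_ms <= win[2])
  wa <- rowMeans(a[, idx, drop = FALSE])
  wb <- rowMeans(b[, idx, drop = FALSE])
  if (design == "paired") {
    stopifnot(length(wa) == length(wb))
    dif <- wa - wb
    s <- stats::sd(dif)
    num <- mean(dif)
    nu <- length(dif) - 1
  } else {
    na <- length(wa); nb <- length(wb)
    s <- sqrt(((na - 1) * stats::var(wa) + (nb - 1) * stats::var(wb)) /
                (na + nb - 2))
    num <- mean(wa) - mean(wb)
    nu <- na + nb - 2
  }
  zero_var <- s == 0
  d <- if (zero_var) {
    if (zero_var) warning("zero variance in effect-size window; d is signed infinity")
    sign(num) * Inf
  } else {
    num / s
  }
  j <- 1 - 3 / (4 * nu - 1)               # Hedges small-sample correction
  list(d = d, hedges_g = j * d, window_ms = win, clipped = clipped,
       zero_variance = zero_var, n = if (design == "paired") nu + 1 else nu + 2)
}

#' Peak-anchored effect sizes over 50 and 100 ms windows
#'
#' Detects the component peak on the mean difference series, then computes
#' Cohen's d over 50 ms and 100 ms windows centred on the peak latency
#' (clipped at the epoch bounds and flagged when clipping occurs).
#'
#' @param a,b observations x samples matrices.
#' @param design `"paired"` or `"independent"`.
#' @param window a [component_window()].
#' @param time_ms per-sample times.
#' @return an `effect_size` list: `component`, `peak_latency_ms`,
#'   `peak_amplitude_uV`, `d_50`, `d_100`, `g_50`, `g_100`, `clipped`,
#'   `design`.
#' @export
effect_size <- function(a, b, design = c("paired", "independent"),
                        window = component_window("MMN"), time_ms = NULL) {
  design <- match.arg(design)
  time_ms <- time_ms %||% attr(a, "time_ms")
  diff_mean <- colMeans(as.matrix(a)) - colMeans(as.matrix(b))
  pk <- find_peak(diff_mean, window, time_ms)
  e50 <- cohens_d(a, b, design, pk$peak_latency_ms + c(-25, 25), time_ms)
  e100 <- cohens_d(a, b, design, pk$peak_latency_ms + c(-50, 50), time_ms)
  structure(
    list(component = window$name, peak_latency_ms = pk$peak_latency_ms,
         peak_amplitude_uV = pk$peak_amplitude_uV,
         d_50 = e50$d, d_100 = e100$d,
         g_50 = e50$hedges_g, g_100 = e100$hedges_g,
         clipped = e50$clipped || e100$clipped, design = design),
    class = "effect_size"
  )
}

#' Mean amplitude over an export window
#'
#' @param values numeric ROI difference series.
#' @param window_ms time window.
#' @param time_ms per-sample times; default from `attr(values, "time_ms")`.
#' @return scalar mean amplitude in microvolts.
#' @export
window_mean_amplitude <- function(values, window_ms, time_ms = NULL) {
  time_ms <- time_ms %||% attr(values, "time_ms")
  stopifnot(length(values) == length(time_ms))
  if (window_ms[1] < time_ms[1] - 1e-9 ||
      window_ms[2] > time_ms[length(time_ms)] + 1e-9) {
    stopf("window [%g, %g] ms lies outside the epoch [%g, %g] ms",
          window_ms[1], window_ms[2], time_ms[1], time_ms[length(time_ms)])
  }
  idx <- which(time_ms >= window_ms[1] & time_ms <= window_ms[2])
  if (length(idx) == 0) stopf("window contains no samples")
  mean(values[idx])
}
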