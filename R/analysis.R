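#' Chloride-transient amplitude metrics
#'
#' Quantifies a stimulus-evoked chloride transient: the baseline is the
#' mean over the pre-stimulus window, the extremes are taken over the
#' post-onset trace, and the manifest amplitude selects the
#' larger-magnitude deviation (ties resolved toward the maximum branch):
#' `delta = min - baseline` if `|min - baseline| > |max - baseline|`,
#' otherwise `delta = max - baseline`.
#'
#' @param trace chloride concentration time series, mM.
#' @param time time grid, ms (same length as `trace`).
#' @param onset stimulus onset, ms.
#' @param baseline_window length of the pre-onset baseline window, ms
#'   (default 100).
#' @return An object of class `transient_metrics`: `baseline`, `cl_min`,
#'   `cl_max`, `delta_min`, `delta_max`, `delta` (the manifest amplitude),
#'   all mM.
#' @export
delta_cl <- function(trace, time, onset, baseline_window = 100) {
  stopifnot(length(trace) == length(time))
  base_idx <- time >= onset - baseline_window & time < onset
  if (!any(base_idx)) stop("empty baseline window")
  post_idx <- time >= onset
  if (!any(post_idx)) stop("trace does not cover the stimulus")
  baseline <- mean(trace[base_idx])
  cl_min <- min(trace[post_idx])
  cl_max <- max(trace[post_idx])
  dmin <- cl_min - baseline
  dmax <- cl_max - baseline
  manifest <- if (abs(dmin) > abs(dmax)) dmin else dmax
  structure(list(baseline = baseline, cl_min = cl_min, cl_max = cl_max,
                 delta_min = dmin, delta_max = dmax, delta = manifest),
            class = "transient_metrics")
}

#' @export
print.transient_metrics <- function(x, ...) {
  cat(sprintf(paste0("<transient_metrics> baseline %.3f mM, ",
                     "delta_min %.4f / delta_max %.4f, manifest %.4f mM\n"),
              x$baseline, x$delta_min, x$delta_max, x$delta))
  invisible(x)
}

#' Glutamatergic enhancement of the chloride transient
#'
#' The additional chloride change attributable to glutamatergic
#' co-stimulation: difference of the manifest transient amplitudes with and
#' without the co-stimulus.
#'
#' @param metrics_co [delta_cl()] metrics of the co-stimulation run.
#' @param metrics_gaba metrics of the GABA-only run.
#' @return Numeric, mM.
#' @export
delta_g <- function(metrics_co, metrics_gaba) {
  stopifnot(inherits(metrics_co, "transient_metrics"),
            inherits(metrics_gaba, "transient_metrics"))
  metrics_co$delta - metrics_gaba$delta
}

#' Mean dendritic chloride trace
#'
#' Unweighted mean across the mid-dendrite probes of all terminal
#' dendrites, emulating a dendritic-compartment average.
#'
#' @param result a `sim_result` whose probe set contains a probe at the
#'   mid-length (x in [0.4, 0.6]) of every terminal dendritic section.
#' @param morph the [morphology()] the result was computed on.
#' @return data.frame with `time` (ms) and `cl` (mM).
#' @export
mean_dendritic_cl <- function(result, morph) {
  s <- morph$sections
  terminal <- s$name[s$role == "dend" & !(s$name %in% s$parent)]
  pr <- result$probes
  cols <- vapply(terminal, function(sec) {
    j <- which(pr$section == sec & pr$x >= 0.4 & pr$x <= 0.6)
    if (length(j) == 0) NA_integer_ else j[1]
  }, 1L)
  if (anyNA(cols))
    stop("missing mid-dendrite probes for: ",
         paste(terminal[is.na(cols)], collapse = ", "))
  data.frame(time = result$time, cl = rowMeans(result$cl[, cols, drop = FALSE]))
}

#' Phase-plane trajectory of a chloride transient
#'
#' Central-difference rate of change (mM/s) against the deviation from
#' baseline (mM). Zero crossings of the rate mark the transient extremes.
#'
#' @param trace chloride time series, mM (uniformly sampled).
#' @param time ms.
#' @param baseline baseline concentration, mM (e.g. from [delta_cl()]).
#' @param smooth optional boxcar width in samples (default 0 = off).
#' @return data.frame with `delta` (mM) and `rate` (mM/s).
#' @export
phase_plane <- function(trace, time, baseline, smooth = 0) {
  stopifnot(length(trace) == length(time), length(trace) >= 3)
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    trace <- stats::filter(trace, k, sides = 2)
  }
  n <- length(trace)
  dt_ms <- time[2] - time[1]
  rate <- c(NA, (trace[3:n] - trace[1:(n - 2)]) / (2 * dt_ms), NA) * 1e3
  out <- data.frame(delta = trace - baseline, rate = rate)
  out[!is.na(out$rate), ]
}

#' Monoexponential decay fit over distance
#'
#' Least-squares fit of `A exp(-x / lambda)`, seeded from a log-linear
#' regression when all values are positive (direct nonlinear fit
#' otherwise).
#'
#' @param distances um.
#' @param values amplitudes (mM or mV).
#' @return An object of class `fit_result`: `amplitude`, `lambda` (um),
#'   `r_squared`, `non_identifiable`.
#' @export
fit_exp_decay <- function(distances, values) {
  stopifnot(length(distances) == length(values))
  if (length(values) < 3) stop("need at least 3 points")
  if (sd(values) < 1e-12 * max(abs(values), 1e-300)) {
    warning("constant values: decay length is non-identifiable")
    return(structure(list(amplitude = mean(values), lambda = Inf,
                          r_squared = 1, non_identifiable = TRUE),
                     class = "fit_result"))
  }
  start <- if (all(values > 0)) {
    co <- coef(lm(log(values) ~ distances))
    list(A = exp(co[[1]]), lambda = max(-1 / co[[2]], 1))
  } else {
    list(A = max(abs(values)), lambda = diff(range(distances)) / 2)
  }
  fit <- tryCatch(
    nls(values ~ A * exp(-distances / lambda), start = start,
        control = stats::nls.control(maxiter = 500, scaleOffset = 1,
                                     warnOnly = TRUE)),
    error = function(e) {
      if (requireNamespace("minpack.lm", quietly = TRUE))
        minpack.lm::nlsLM(values ~ A * exp(-distances / lambda), start = start)
      else stop(e)
    })
  co <- coef(fit)
  pred <- co[["A"]] * exp(-distances / co[["lambda"]])
  r2 <- 1 - sum((values - pred)^2) / sum((values - mean(values))^2)
  structure(list(amplitude = co[["A"]], lambda = co[["lambda"]],
                 r_squared = r2, non_identifiable = FALSE),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> A = %.4g, lambda = %.4g um, R2 = %.3f%s\n",
              x$amplitude, x$lambda, x$r_squared,
              if (x$non_identifiable) " (non-identifiable)" else ""))
  invisible(x)
}

#' Cross-correlogram of AMPA relative to GABA event times
#'
#' Histogram of all pairwise time differences (AMPA minus GABA) within
#' `+/- window`, normalized to relative occurrence.
#'
#' @param ampa_times,gaba_times ms.
#' @param bin bin width, ms.
#' @param window half-width, ms.
#' @return data.frame with `lag` (bin centers, ms), `count` and `rel`
#'   (count / total).
#' @export
crosscorrelogram <- function(ampa_times, gaba_times, bin = 1, window = 50) {
  if (bin <= 0) stop("bin must be positive")
  d <- as.vector(outer(ampa_times, gaba_times, "-"))
  breaks <- seq(-window, window, by = bin)
  d <- d[d >= breaks[1] & d <= breaks[length(breaks)]]
  idx <- findInterval(d, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  tot <- sum(counts)
  data.frame(lag = breaks[-1] - bin / 2, count = counts,
             rel = if (tot > 0) counts / tot else 0)
}

#' Mean and standard deviation across repetitions
#'
#' @param values numeric vector (one entry per seed/repetition).
#' @return List with `mean`, `sd`, `n`.
#' @export
repetition_stats <- function(values) {
  list(mean = mean(values), sd = sd(values), n = length(values))
}
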