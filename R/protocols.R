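#' Event schedule
#'
#' Timed activations of named synapses.
#'
#' @param synapse character vector of synapse ids.
#' @param time onset times, ms (all >= 0).
#' @return data.frame of class `event_schedule` with columns `synapse`,
#'   `time`.
#' @export
event_schedule <- function(synapse = character(0), time = numeric(0)) {
  if (length(synapse) != length(time)) stop("synapse and time lengths differ")
  if (any(time < 0)) stop("event times must be >= 0")
  structure(data.frame(synapse = as.character(synapse), time = time,
                       stringsAsFactors = FALSE),
            class = c("event_schedule", "data.frame"))
}

#' Write / read an event schedule as CSV
#'
#' Two-column CSV (`synapse_id`, `time_ms`) so that schedules can be
#' versioned as plain-text fixtures.
#'
#' @param schedule an [event_schedule()].
#' @param path file path.
#' @return `path` (write) or an `event_schedule` (read).
#' @export
write_schedule <- function(schedule, path) {
  write.csv(data.frame(synapse_id = schedule$synapse, time_ms = schedule$time),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  event_schedule(d$synapse_id, d$time_ms)
}

#' Place synapses on the dendritic tree
#'
#' @param morph a [morphology()].
#' @param n number of synapses.
#' @param rule placement rule: `"uniform"` samples positions uniformly over
#'   total dendritic length; `"proximal25"`/`"distal25"` restrict the
#'   normalized position within each dendrite to the proximal/distal
#'   quarter (section choice still length-weighted); `"colocalized"` copies
#'   the locations in `with`.
#' @param seed integer seed.
#' @param with existing placement (data.frame `section`, `x`) for the
#'   colocalized rule; if `n` is smaller, a random subset is paired.
#' @param sections optional restriction to a set of section names.
#' @return data.frame with columns `section`, `x`.
#' @export
place_synapses <- function(morph, n, rule = c("uniform", "proximal25",
                                              "distal25", "colocalized"),
                           seed = NULL, with = NULL, sections = NULL) {
  rule <- match.arg(rule)
  if (n < 0) stop("n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (rule == "colocalized") {
    if (is.null(with)) stop("colocalized rule requires `with` locations")
    idx <- if (n == nrow(with)) seq_len(n) else sample(nrow(with), n, replace = n > nrow(with))
    return(data.frame(section = with$section[idx], x = with$x[idx],
                      stringsAsFactors = FALSE))
  }
  s <- morph$sections
  dend <- s[s$role == "dend", , drop = FALSE]
  if (!is.null(sections)) dend <- dend[dend$name %in% sections, , drop = FALSE]
  if (nrow(dend) == 0 || sum(dend$length) <= 0)
    stop("target region has zero dendritic length")
  sec <- sample(dend$name, n, replace = TRUE, prob = dend$length)
  x <- switch(rule,
    uniform = runif(n),
    proximal25 = runif(n, 0, 0.25),
    distal25 = runif(n, 0.75, 1))
  data.frame(section = sec, x = x, stringsAsFactors = FALSE)
}

#' GDP barrage specification
#'
#' Statistical surrogate for the synaptic bombardment during a giant
#' depolarizing potential: 534 GABAergic and 107 AMPA inputs, each firing
#' once, with onset times drawn from normal distributions (GABA: mu 600 ms,
#' AMPA: mu 650 ms) truncated by resampling into the simulation window.
#' The printed defaults use very wide sigmas relative to the window, which
#' makes the truncated distribution near-uniform; `compact = TRUE` selects
#' the compact preset (sigma 90/85 ms) that produces a GDP-like surge.
#'
#' @param n_gaba,n_ampa synapse counts (defaults 534 and 107).
#' @param mu_gaba,sigma_gaba,mu_ampa,sigma_ampa normal timing parameters,
#'   ms.
#' @param window event window, ms (default 1300).
#' @param compact logical; use the compact timing preset.
#' @return An object of class `gdp_spec`.
#' @export
gdp_spec <- function(n_gaba = 534, n_ampa = 107, mu_gaba = 600,
                     sigma_gaba = 9000, mu_ampa = 650, sigma_ampa = 8500,
                     window = 1300, compact = FALSE) {
  if (n_gaba < 0 || n_ampa < 0) stop("counts must be >= 0")
  if (window <= 0) stop("window must be positive")
  if (compact) { sigma_gaba <- 90; sigma_ampa <- 85 }
  structure(list(n_gaba = n_gaba, n_ampa = n_ampa, mu_gaba = mu_gaba,
                 sigma_gaba = sigma_gaba, mu_ampa = mu_ampa,
                 sigma_ampa = sigma_ampa, window = window),
            class = "gdp_spec")
}

rnorm_trunc <- function(n, mu, sigma, lo, hi, max_iter = 10000) {
  out <- rnorm(n, mu, sigma)
  for (it in seq_len(max_iter)) {
    bad <- which(out < lo | out > hi)
    if (length(bad) == 0) return(out)
    out[bad] <- rnorm(length(bad), mu, sigma)
  }
  stop("truncation by resampling did not converge")
}

#' Generate a GDP-like event schedule
#'
#' Places the synapses on the dendritic tree and draws exactly one onset
#' time per synapse from the spec's truncated normal distributions.
#' Synapse ids are `gdp_gaba<i>` and `gdp_ampa<i>`.
#'
#' @param spec a [gdp_spec()].
#' @param morph a [morphology()].
#' @param seed integer seed (placement and timing).
#' @param placement placement rule passed to [place_synapses()] for GABA
#'   synapses.
#' @param ampa_placement rule for AMPA synapses (`"uniform"` or
#'   `"colocalized"`, which pairs each AMPA synapse with a GABA location).
#' @param ampa_sections,gaba_sections optional section restrictions.
#' @return List with `gaba`, `ampa` (location data.frames) and `schedule`
#'   (an [event_schedule()]).
#' @export
gdp_schedule <- function(spec, morph, seed = 1, placement = "uniform",
                         ampa_placement = "uniform", ampa_sections = NULL,
                         gaba_sections = NULL) {
  stopifnot(inherits(spec, "gdp_spec"))
  set.seed(seed)
  gloc <- place_synapses(morph, spec$n_gaba, placement, sections = gaba_sections)
  aloc <- if (ampa_placement == "colocalized")
    place_synapses(morph, spec$n_ampa, "colocalized", with = gloc)
  else place_synapses(morph, spec$n_ampa, ampa_placement,
                      sections = ampa_sections)
  tg <- rnorm_trunc(spec$n_gaba, spec$mu_gaba, spec$sigma_gaba, 0, spec$window)
  ta <- rnorm_trunc(spec$n_ampa, spec$mu_ampa, spec$sigma_ampa, 0, spec$window)
  list(gaba = gloc, ampa = aloc,
       schedule = event_schedule(
         c(sprintf("gdp_gaba%d", seq_len(spec$n_gaba)),
           sprintf("gdp_ampa%d", seq_len(spec$n_ampa))),
         c(tg, ta)))
}

#' Random-train specification
#'
#' 20 Hz stimulation of 100 GABA and 100 AMPA synapses used for the
#' temporal-decorrelation experiments.
#'
#' @param n_gaba,n_ampa synapse counts.
#' @param rate stimulation rate, Hz. With `rate_mode = "population"` (the
#'   default) this is the aggregate rate of the whole population: events
#'   arrive as one Poisson process at `rate` and each event activates a
#'   randomly chosen synapse, which keeps the event count compatible with
#'   the refractory decorrelation (a 37 ms refractory period around every
#'   GABA event is only satisfiable when events are sparse). With
#'   `"per_synapse"` every synapse fires independently at `rate`.
#' @param duration ms.
#' @param mode `"random"` (independent Poisson trains), `"correlated"`
#'   (AMPA events copied from the GABA events) or `"refractory"`
#'   (random, then AMPA times redrawn until separated from every GABA time
#'   by more than `refractory`).
#' @param refractory ms.
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(n_gaba = 100, n_ampa = 100, rate = 20, duration = 1000,
                       mode = c("random", "correlated", "refractory"),
                       refractory = 0,
                       rate_mode = c("population", "per_synapse")) {
  mode <- match.arg(mode)
  rate_mode <- match.arg(rate_mode)
  if (rate <= 0) stop("rate must be positive")
  if (refractory < 0) stop("refractory must be >= 0")
  if (duration < 0) stop("duration must be >= 0")
  structure(list(n_gaba = n_gaba, n_ampa = n_ampa, rate = rate,
                 duration = duration, mode = mode, refractory = refractory,
                 rate_mode = rate_mode),
            class = "train_spec")
}

#' Generate a 20 Hz train schedule
#'
#' Each synapse fires as an independent Poisson process at the stated rate
#' over the stated duration. In correlated mode AMPA synapse i receives
#' exactly the event times of GABA synapse i; in refractory mode AMPA
#' times are decorrelated from all GABA times with [decorrelate()].
#' Synapse ids are `tr_gaba<i>` / `tr_ampa<i>`.
#'
#' @param spec a [train_spec()].
#' @param seed integer seed.
#' @return An [event_schedule()].
#' @export
train_schedule <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "train_spec"))
  set.seed(seed)
  draw <- function(n, prefix) {
    if (spec$rate_mode == "population") {
      n_ev <- stats::rpois(1, spec$rate * spec$duration / 1e3)
      data.frame(synapse = sprintf("%s%d", prefix,
                                   sample.int(n, n_ev, replace = TRUE)),
                 time = runif(n_ev, 0, spec$duration),
                 stringsAsFactors = FALSE)
    } else {
      counts <- stats::rpois(n, spec$rate * spec$duration / 1e3)
      data.frame(synapse = rep(sprintf("%s%d", prefix, seq_len(n)), counts),
                 time = runif(sum(counts), 0, spec$duration),
                 stringsAsFactors = FALSE)
    }
  }
  g <- draw(spec$n_gaba, "tr_gaba")
  a <- switch(spec$mode,
    random = draw(spec$n_ampa, "tr_ampa"),
    correlated = {
      if (spec$n_ampa != spec$n_gaba)
        stop("correlated mode requires equal synapse counts")
      data.frame(synapse = sub("^tr_gaba", "tr_ampa", g$synapse),
                 time = g$time, stringsAsFactors = FALSE)
    },
    refractory = {
      a0 <- draw(spec$n_ampa, "tr_ampa")
      a0$time <- decorrelate(a0$time, g$time, spec$refractory,
                             window = spec$duration)
      a0
    })
  event_schedule(c(g$synapse, a$synapse), c(g$time, a$time))
}

#' Temporally decorrelate AMPA from GABA event times
#'
#' Redraws every AMPA time that falls within the refractory distance of
#' any GABA time (rejection sampling, uniform redraw over the window) until
#' all pairwise distances exceed the refractory period. Event count is
#' preserved.
#'
#' @param ampa_times,gaba_times ms.
#' @param refractory ms (>= 0).
#' @param window redraw window, ms.
#' @param max_iter rejection-sampling cap per event (default 10000).
#' @return Decorrelated AMPA times.
#' @export
decorrelate <- function(ampa_times, gaba_times, refractory, window,
                        max_iter = 10000) {
  if (refractory < 0) stop("refractory must be >= 0")
  if (refractory == 0 || length(gaba_times) == 0) return(ampa_times)
  gs <- sort(gaba_times)
  clear <- function(t) {
    i <- findInterval(t, gs)
    lo <- if (i >= 1) t - gs[i] else Inf
    hi <- if (i < length(gs)) gs[i + 1] - t else Inf
    min(lo, hi) > refractory
  }
  vapply(ampa_times, function(t) {
    for (it in seq_len(max_iter)) {
      if (clear(t)) return(t)
      t <- runif(1, 0, window)
    }
    stop("decorrelation infeasible: window too crowded for refractory ",
         refractory, " ms")
  }, numeric(1))
}

#' Per-latency schedules for an AMPA/GABA timing scan
#'
#' For a single GABA synapse activated at `gaba_onset`, builds one schedule
#' per latency with the AMPA onset at `gaba_onset + latency` (negative
#' latency: AMPA first).
#'
#' @param gaba_onset ms.
#' @param latencies numeric vector, ms.
#' @param gaba_id,ampa_id synapse ids used in the schedules.
#' @return Named list of [event_schedule()]s (names are the latencies).
#' @export
latency_scan <- function(gaba_onset, latencies, gaba_id = "gaba",
                         ampa_id = "ampa") {
  out <- lapply(latencies, function(l)
    event_schedule(c(gaba_id, ampa_id), c(gaba_onset, gaba_onset + l)))
  names(out) <- as.character(latencies)
  out
}
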