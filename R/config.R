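# polynomial rolling hash of the deparsed config (mod 2^31 - 1), for
# provenance stamping of outputs
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Scan one parameter of the single-synapse protocol
#'
#' Runs [ampa_enhancement()] once per grid value of the named parameter
#' and collects the manifest transient amplitudes and the glutamatergic
#' enhancement.
#'
#' @param param one of `"g_ampa"`, `"tau_ampa"`, `"tau_gaba"`, `"latency"`,
#'   `"cl0"`, `"ampa_pos"`, `"cm"`.
#' @param grid numeric vector of parameter values.
#' @param ... fixed baseline parameters passed to [ampa_enhancement()].
#' @return data.frame with `value`, `delta_gaba`, `delta_co`, `delta_g`
#'   (mM).
#' @export
scan_parameter <- function(param, grid, ...) {
  alias <- c(g_ampa = "g_glu", tau_ampa = "tau_glu", tau_gaba = "tau_gaba",
             latency = "latency", cl0 = "cl0", ampa_pos = "glu_pos",
             cm = "cm")
  if (!param %in% names(alias))
    stop("unknown scan parameter '", param, "'; valid: ",
         paste(names(alias), collapse = ", "))
  if (length(grid) == 0) stop("empty grid")
  rows <- lapply(grid, function(v) {
    args <- list(...)
    args[[alias[[param]]]] <- v
    r <- do.call(ampa_enhancement, args)
    data.frame(value = v, delta_gaba = r$metrics_gaba$delta,
               delta_co = r$metrics_co$delta, delta_g = r$delta_g)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- param
  out
}

#' Run an experiment described by a YAML configuration
#'
#' The configuration has the blocks `experiment` (one of `single`,
#' `scan`, `tonic_ampa`, `distance_scan`, `tau_gaba_scan`,
#' `latency_profile`, `gdp`, `train`), `seed`, `params` (arguments of the
#' corresponding experiment function) and optionally `output: dir`. Result
#' tables are written as CSV, metrics as JSON; every output embeds the
#' config hash and seed.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir overrides the configured output directory.
#' @return The experiment value (table or list), invisibly when writing.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  known <- c("experiment", "seed", "params", "output")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         if (is.character(config)) paste0(" in ", config) else "")
  if (is.null(cfg$experiment)) stop("config is missing the 'experiment' key")
  params <- cfg$params %||% list()
  seed <- cfg$seed %||% 1L
  fns <- list(
    single = ampa_enhancement, scan = scan_parameter,
    tonic_ampa = tonic_ampa_experiment, distance_scan = distance_scan,
    tau_gaba_scan = tau_gaba_scan, latency_profile = latency_profile,
    gdp = gdp_experiment, train = train_experiment)
  if (!cfg$experiment %in% names(fns))
    stop("unknown experiment '", cfg$experiment, "'; valid: ",
         paste(names(fns), collapse = ", "))
  set.seed(seed)
  if (cfg$experiment %in% c("gdp", "train") && is.null(params$seeds))
    params$seeds <- seq_len(9) + (seed - 1) * 9
  value <- do.call(fns[[cfg$experiment]], params)
  dir <- out_dir %||% cfg$output$dir
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    stamp <- list(experiment = cfg$experiment, seed = seed,
                  config_hash = config_hash(cfg),
                  package_version = as.character(utils::packageVersion("chloridyn")))
    tab <- if (is.data.frame(value)) value else
      if (!is.null(value$table)) value$table else NULL
    if (!is.null(tab)) {
      path <- file.path(dir, paste0(cfg$experiment, ".csv"))
      con <- file(path, "w")
      writeLines(sprintf("# experiment=%s seed=%d config_hash=%s",
                         stamp$experiment, stamp$seed, stamp$config_hash), con)
      write.csv(tab, con, row.names = FALSE)
      close(con)
    }
    for (nm in c("gaba", "co"))  # single-run protocols: full traces
      if (inherits(value[[nm]], "sim_result"))
        write_sim_csv(value[[nm]], file.path(dir, paste0("traces_", nm, ".csv")))
    metrics <- c(stamp, list(result = .metrics_for_json(value)))
    jsonlite::write_json(metrics, file.path(dir, paste0(cfg$experiment, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(value))
  }
  value
}

.metrics_for_json <- function(value) {
  if (is.data.frame(value)) return(value)
  if (is.list(value)) {
    keep <- intersect(names(value), c("table", "fit", "delta_g",
                                      "metrics_gaba", "metrics_co"))
    return(lapply(value[keep], function(v)
      if (is.data.frame(v)) v else unclass(v)))
  }
  value
}

#' Write small deterministic fixtures
#'
#' Writes a toy SWC morphology, a small event-schedule CSV, and a golden
#' metrics JSON produced by a coarse single-synapse run. Byte-identical
#' across runs for a fixed seed.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return Character vector of the written paths.
#' @export
make_fixtures <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  swc <- c("# toy morphology",
           "1 1 0 0 0 5 -1",
           "2 3 5 0 0 0.5 1",
           "3 3 55 0 0 0.5 2",
           "4 3 105 0 0 0.5 3",
           "5 3 55 50 0 0.4 3",
           "6 3 55 100 0 0.4 5")
  swc_path <- file.path(dir, "toy.swc")
  writeLines(swc, swc_path)
  set.seed(seed)
  sched <- event_schedule(sprintf("syn%d", sample(1:5, 10, replace = TRUE)),
                          round(sort(runif(10, 0, 500)), 3))
  sched_path <- file.path(dir, "schedule.csv")
  write_schedule(sched, sched_path)
  r <- ampa_enhancement(cl0 = 5, n_nodes = 21, dt = 0.1, onset = 150,
                        post = 250, record_every = 1)
  gold <- list(seed = seed, cl0 = 5,
               delta_gaba = r$metrics_gaba$delta,
               delta_co = r$metrics_co$delta, delta_g = r$delta_g)
  gold_path <- file.path(dir, "golden_metrics.json")
  jsonlite::write_json(gold, gold_path, auto_unbox = TRUE, digits = 12)
  c(swc_path, sched_path, gold_path)
}
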