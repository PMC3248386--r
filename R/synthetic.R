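# Synthetic measurement sets with the statistical structure of the imaging
# experiments: per-cell normalized translocation ratios at scheduled times,
# summarized as mean +/- SEM over n cells. Per-cell noise is additive
# Gaussian on the normalized ratio, truncated at zero; the default noise
# level (sd 0.4 per cell) gives SEMs near 0.18 at n = 5, matching the
# per-point variability reported for the imaging data.

#' Sample a synthetic measurement set from a trace
#'
#' For each scheduled time, draws `n_cells` independent per-cell values equal
#' to the noise-free normalized translocation plus Gaussian noise (truncated
#' at 0), and records their mean and SEM (= sd / sqrt(n)).
#'
#' @param trace a `translocation_trace`.
#' @param schedule sample times; defaults to [default_schedule()] of the
#'   trace's protocol.
#' @param n_cells number of pseudo-cells (>= 1), default 8.
#' @param noise_sd per-cell standard deviation on the normalized ratio,
#'   default 0.4.
#' @param seed RNG seed; the same seed reproduces the set exactly.
#' @return a `measurement_set`: data.frame with columns `time`, `mean`, `sem`
#'   and attributes `n_cells`, `noise_sd`, `seed`, `protocol`.
#' @export
sample_measurements <- function(trace, schedule = NULL, n_cells = 8,
                                noise_sd = 0.4, seed = 1) {
  stopifnot(inherits(trace, "translocation_trace"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  truth <- normalized_translocation(trace, schedule)
  set.seed(seed)
  mu <- numeric(nrow(truth))
  sem <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cells <- pmax(0, truth$value[i] + stats::rnorm(n_cells, 0, noise_sd))
    mu[i] <- mean(cells)
    sem[i] <- if (n_cells > 1) stats::sd(cells) / sqrt(n_cells) else 0
  }
  structure(data.frame(time = truth$time, mean = mu, sem = sem),
            n_cells = as.integer(n_cells), noise_sd = noise_sd,
            seed = as.integer(seed), protocol = trace$protocol$name,
            class = c("measurement_set", "data.frame"))
}

#' Generate a fitting suite of synthetic measurement sets
#'
#' Simulates each named protocol once under `true_params` and samples one
#' measurement set per protocol (seeds derived as `seed + index`). The
#' returned list is directly usable as the `datasets` argument of
#' [sse_objective()] and [fit_stage()]; its `"manifest"` attribute records the
#' true parameters and generator settings.
#'
#' @param true_params a `model_parameters` object.
#' @param protocols character vector of packaged protocol names.
#' @param n_cells,noise_sd,seed see [sample_measurements()].
#' @param dt solver step for the generating simulations.
#' @param schedules optional named list of sample-time vectors overriding
#'   [default_schedule()] for specific protocols (e.g. 1-min within-pulse
#'   frames for a test pulse).
#' @return list of `list(protocol =, measurements =)` entries.
#' @export
make_recovery_suite <- function(true_params, protocols, n_cells = 8,
                                noise_sd = 0.4, seed = 1, dt = 0.01,
                                schedules = NULL) {
  suite <- vector("list", length(protocols))
  for (i in seq_along(protocols)) {
    pr <- paper_protocol(protocols[i])
    tr <- simulate_protocol(pr, true_params, dt = dt)
    suite[[i]] <- list(protocol = pr,
                       measurements = sample_measurements(
                         tr, schedule = schedules[[protocols[i]]],
                         n_cells = n_cells, noise_sd = noise_sd,
                         seed = seed + i))
  }
  names(suite) <- protocols
  attr(suite, "manifest") <- list(
    true_params = lapply(unclass(true_params)[.param_names], as.numeric),
    protocols = protocols, n_cells = n_cells, noise_sd = noise_sd,
    seed = seed, dt = dt)
  suite
}

#' Datasets consumed by each construction stage
#'
#' The protocols whose measurements each stage of the incremental model
#' construction was fit to: the core/homologous stages use the massed
#' protocol with both inhibitors; the PKA stage the anisomycin pair; the AD
#' stage the KT5720 pair; the D stage the seven drug-free datasets (massed,
#' spaced, and the five two-pulse washes).
#'
#' @param stage stage name.
#' @return character vector of packaged protocol names.
#' @export
stage_protocols <- function(stage = c("base", "homologous", "pka", "ad", "d")) {
  stage <- match.arg(stage)
  switch(stage,
    base = "massed90_aniso_kt",
    homologous = "massed90_aniso_kt",
    pka = c("massed90_aniso", "spaced5x5_15_aniso"),
    ad = c("massed90_kt", "spaced5x5_15_kt"),
    d = c("massed90", "spaced5x5_15", "twopulse_5_5", "twopulse_5_10",
          "twopulse_5_15", "twopulse_5_30", "twopulse_5_45"))
}

#' Write / read a measurement set as CSV with a JSON manifest
#'
#' The CSV has columns `time`, `mean`, `sem`; the manifest stores `n_cells`,
#' `noise_sd`, `seed` and the source protocol name.
#'
#' @param ms a `measurement_set`.
#' @param file CSV path.
#' @param manifest_file optional JSON path (default: `file` with `.json`).
#' @export
write_measurements <- function(ms, file, manifest_file = NULL) {
  utils::write.csv(data.frame(time = ms$time, mean = ms$mean, sem = ms$sem),
                   file, row.names = FALSE)
  if (is.null(manifest_file)) manifest_file <- sub("\\.csv$", ".json", file)
  jsonlite::write_json(
    list(n_cells = attr(ms, "n_cells"), noise_sd = attr(ms, "noise_sd"),
         seed = attr(ms, "seed"), protocol = attr(ms, "protocol")),
    manifest_file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(file, manifest_file = NULL) {
  df <- utils::read.csv(file)
  if (is.null(manifest_file)) manifest_file <- sub("\\.csv$", ".json", file)
  man <- if (file.exists(manifest_file))
    jsonlite::read_json(manifest_file, simplifyVector = TRUE) else list()
  structure(df, n_cells = man$n_cells, noise_sd = man$noise_sd,
            seed = man$seed, protocol = man$protocol,
            class = c("measurement_set", "data.frame"))
}
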