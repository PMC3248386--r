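# Staged least-squares estimation mirroring the model's incremental
# construction: the core translocation component first, then homologous
# desensitization, the PKA-mediated pathway, the AD pathway, and finally the
# D pathway. Each stage frees only its own parameters and holds all earlier
# ones fixed. The local optimizer is bounded Levenberg-Marquardt
# (minpack.lm::nls.lm) from multiple seeded starts.

# Parameters each stage may free.
.stage_free <- list(
  base = c("kA1", "kA2", "kA3", "kDAGp", "kDAGd"),
  homologous = c("kA4", "kA5"),
  pka = c("kB1", "kB2", "kB2a", "kB2b", "Vm", "K5HT", "cAMP_basal", "Kfpka",
          "Kbpka", "kcAMPd"),
  ad = c("kC1", "kC2", "kC2a", "kC2b", "kS1", "kS1a", "kS1b", "kS2"),
  d = c("kD1", "kD1a", "kD1b", "kD2a", "kD2b", "kD3", "kD3a", "kD3b",
        "kS3", "kS3a", "kS3b", "kS4", "delayD", "intPKA")
)

#' Parameters belonging to a fitting stage
#' @param stage one of `"base"`, `"homologous"`, `"pka"`, `"ad"`, `"d"`.
#' @return character vector of parameter names the stage may free.
#' @export
stage_parameters <- function(stage = c("base", "homologous", "pka", "ad", "d")) {
  .stage_free[[match.arg(stage)]]
}

# Residual vector (normalized model minus measured mean), optionally
# SEM-weighted, across all datasets. `datasets` is a list of
# list(protocol =, measurements =) entries.
.fit_residuals <- function(params, datasets, dt = 0.01, weighted = FALSE) {
  unlist(lapply(datasets, function(ds) {
    pr <- ds$protocol
    if (is.character(pr)) pr <- paper_protocol(pr)
    ms <- ds$measurements
    t_end <- max(pr$duration, max(ms$time))
    tr <- simulate_protocol(pr, params, dt = dt, t_end = t_end)
    model <- normalized_translocation(tr, schedule = ms$time)$value
    r <- model - ms$mean
    if (weighted) {
      w <- ifelse(ms$sem > 0, 1 / ms$sem, 1)
      r <- r * w
    }
    r
  }))
}

#' Sum-of-squares objective
#'
#' Sum over datasets and time points of (normalized model - measured mean)^2.
#' Residuals are unweighted by default; `weighted = TRUE` divides each
#' residual by its SEM.
#'
#' @param params a `model_parameters` object.
#' @param datasets list of `list(protocol =, measurements =)` entries, e.g.
#'   from [make_recovery_suite()].
#' @param dt solver step size.
#' @param weighted logical; weight residuals by 1/SEM.
#' @return non-negative scalar.
#' @export
sse_objective <- function(params, datasets, dt = 0.01, weighted = FALSE) {
  sum(.fit_residuals(params, datasets, dt = dt, weighted = weighted)^2)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken about the mean
#' of the measurements.
#'
#' @param model_values model predictions.
#' @param measured a `measurement_set` (its `mean` column is used) or a
#'   numeric vector; same length as `model_values`, length >= 2.
#' @return scalar <= 1.
#' @export
r_squared <- function(model_values, measured) {
  y <- if (is.data.frame(measured)) measured$mean else measured
  if (length(y) != length(model_values) || length(y) < 2)
    stop("model and measured series must have equal length >= 2")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    stop("undefined R^2: measurements have zero variance")
  1 - sum((y - model_values)^2) / ss_tot
}

#' Fit one construction stage
#'
#' Minimizes the least-squares distance between the normalized model output
#' and the measured means over the stage's datasets, freeing only
#' `free_params` (which must belong to the stage) and holding every other
#' parameter fixed. Optimization is bounded Levenberg-Marquardt from
#' `n_starts` starts: the first at `start` (default: the current values in
#' `params`), the rest drawn log-uniformly within the bounds (seeded).
#'
#' @param stage stage name, see [stage_parameters()].
#' @param free_params parameters to fit; subset of the stage's set. May be
#'   empty, in which case the objective is evaluated at `params` and nothing
#'   changes.
#' @param datasets list of `list(protocol =, measurements =)` entries.
#' @param params full parameter set supplying the fixed values.
#' @param bounds optional list with named numeric vectors `lower`, `upper`
#'   over `free_params`; default is a factor-of-50 box around the start.
#' @param start optional named start values for `free_params`.
#' @param n_starts number of optimizer starts.
#' @param seed RNG seed for the extra starts.
#' @param dt solver step used inside the objective.
#' @param weighted weight residuals by 1/SEM.
#' @param maxiter per-start iteration cap.
#' @return a `fit_result`: fitted values, fixed parameters, objective,
#'   per-dataset R^2, optimizer diagnostics. Non-convergence is flagged in
#'   `converged`, not raised.
#' @export
fit_stage <- function(stage, free_params, datasets,
                      params = param_preset("table1_primary"), bounds = NULL,
                      start = NULL, n_starts = 1, seed = 1, dt = 0.01,
                      weighted = FALSE, maxiter = 50) {
  stage <- match.arg(stage, names(.stage_free))
  validate_parameters(params)
  bad <- setdiff(free_params, .stage_free[[stage]])
  if (length(bad))
    stop("parameter(s) not in stage '", stage, "': ",
         paste(bad, collapse = ", "), "; allowed: ",
         paste(.stage_free[[stage]], collapse = ", "))

  fixed <- unclass(params)
  if (length(free_params) == 0L) {
    obj <- sse_objective(params, datasets, dt = dt, weighted = weighted)
    return(structure(list(stage = stage, par = numeric(0), params = params,
                          fixed = fixed, objective = obj,
                          r_squared = .fit_r2(params, datasets, dt),
                          iterations = 0L, converged = TRUE, seed = seed,
                          n_starts = 0L),
                     class = "fit_result"))
  }

  if (is.null(start)) start <- unlist(fixed[free_params])
  start <- start[free_params]
  if (any(is.na(start))) stop("start values missing for some free parameters")
  if (is.null(bounds))
    bounds <- list(lower = start / 50, upper = start * 50)
  lower <- bounds$lower[free_params]
  upper <- bounds$upper[free_params]
  if (any(start < lower) || any(start > upper))
    stop("start values outside bounds")

  with_free <- function(v) {
    p <- utils::modifyList(fixed, as.list(stats::setNames(as.numeric(v),
                                                          free_params)))
    structure(p[.param_names], class = "model_parameters")
  }
  resid_fn <- function(v) {
    out <- tryCatch(.fit_residuals(with_free(v), datasets, dt = dt,
                                   weighted = weighted),
                    error = function(e) NULL)
    # a diverged simulation is a very bad fit, not a fatal error
    if (is.null(out)) rep(1e6, 8L) else out
  }

  set.seed(seed)
  starts <- vector("list", n_starts)
  starts[[1]] <- start
  if (n_starts > 1) {
    lo <- pmax(lower, 1e-300)
    for (s in 2:n_starts)
      starts[[s]] <- exp(stats::runif(length(start), log(lo), log(upper)))
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[[s]], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- sum(fit$fvec^2)
    if (is.null(best) || obj < best$obj)
      best <- list(fit = fit, obj = obj, start_id = s)
  }
  if (is.null(best))
    return(structure(list(stage = stage,
                          par = stats::setNames(start, free_params),
                          params = params, fixed = fixed[setdiff(.param_names,
                                                                 free_params)],
                          objective = NA_real_, r_squared = NA,
                          iterations = 0L, converged = FALSE, seed = seed,
                          n_starts = n_starts),
                     class = "fit_result"))

  fitted <- stats::setNames(as.numeric(best$fit$par), free_params)
  out_params <- with_free(fitted)
  structure(list(stage = stage, par = fitted, params = out_params,
                 fixed = fixed[setdiff(.param_names, free_params)],
                 objective = best$obj,
                 r_squared = .fit_r2(out_params, datasets, dt),
                 iterations = best$fit$niter,
                 converged = best$fit$info %in% 1:4,
                 info = best$fit$info, start_id = best$start_id,
                 seed = seed, n_starts = n_starts),
            class = "fit_result")
}

# Per-dataset R^2 at a parameter set.
.fit_r2 <- function(params, datasets, dt) {
  vapply(datasets, function(ds) {
    pr <- ds$protocol
    if (is.character(pr)) pr <- paper_protocol(pr)
    ms <- ds$measurements
    tr <- simulate_protocol(pr, params, dt = dt,
                            t_end = max(pr$duration, max(ms$time)))
    model <- normalized_translocation(tr, schedule = ms$time)$value
    tryCatch(r_squared(model, ms), error = function(e) NA_real_)
  }, 0)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> stage '", x$stage, "', objective = ",
      format(x$objective, digits = 6), ", converged = ", x$converged,
      " (", x$iterations, " iterations)\n", sep = "")
  if (length(x$par)) {
    cat("  fitted:\n")
    print(signif(x$par, 6))
  }
  if (length(x$r_squared) && !all(is.na(x$r_squared)))
    cat("  per-dataset R^2: ",
        paste(format(x$r_squared, digits = 4), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit a `fit_result`.
#' @param file JSON path.
#' @export
write_fit_result <- function(fit, file) {
  jsonlite::write_json(
    list(stage = fit$stage, par = as.list(fit$par),
         objective = fit$objective,
         r_squared = as.list(fit$r_squared),
         iterations = fit$iterations, converged = fit$converged,
         seed = fit$seed, n_starts = fit$n_starts),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
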