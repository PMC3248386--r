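# Local parameter-sensitivity analysis: each parameter is perturbed by +/-5%
# and +/-50% with all others held at their values; the perturbed model is
# re-simulated under a massed and a spaced reference protocol and the change
# in fit classified High / Medium / Low.
#
# Fit-change metric: the reference dataset is the noise-free normalized
# translocation of the unperturbed model, so the unperturbed SSE is exactly
# zero and a ratio to it is undefined. The change in fit is therefore
# measured on the R^2 scale: change = SSE_perturbed / SStot_reference
# = 1 - R^2 of the perturbed model against the reference data (0 for the
# unperturbed model, and strictly increasing in every residual).

#' Classify a parameter's sensitivity from its fit changes
#'
#' High if either +/-5% perturbation changes the fit by more than 25%;
#' otherwise Medium if either +/-50% perturbation does; otherwise Low.
#' "More than" is strict. `NA` entries (diverged perturbations) are ignored;
#' all-`NA` input classifies as `NA`.
#'
#' @param changes numeric, relative fit-change fractions in the order
#'   (+5%, -5%, +50%, -50%); all non-negative.
#' @return `"High"`, `"Medium"` or `"Low"`.
#' @export
#' @examples
#' classify_parameter(c(0.30, 0.01, 0.40, 0.02)) # "High"
#' classify_parameter(c(0.10, 0.10, 0.26, 0.05)) # "Medium"
classify_parameter <- function(changes) {
  if (length(changes) != 4L)
    stop("changes must have 4 entries: +5%, -5%, +50%, -50%")
  if (any(changes < 0, na.rm = TRUE)) stop("fit changes must be >= 0")
  if (all(is.na(changes))) return(NA_character_)
  d5 <- changes[1:2]
  d50 <- changes[3:4]
  if (any(d5 > 0.25, na.rm = TRUE)) return("High")
  if (any(d50 > 0.25, na.rm = TRUE)) return("Medium")
  "Low"
}

# 1 - R^2 of a perturbed simulation against a noise-free reference readout.
.fit_change <- function(params, protocol, ref, dt) {
  tr <- simulate_protocol(protocol, params, dt = dt,
                          t_end = max(protocol$duration, max(ref$time)))
  model <- normalized_translocation(tr, schedule = ref$time)$value
  ss_tot <- sum((ref$value - mean(ref$value))^2)
  sum((model - ref$value)^2) / ss_tot
}

#' Parameter-sensitivity table
#'
#' Perturbs each parameter by +/-5% and +/-50% (others fixed), re-simulates
#' the perturbed model under the massed and spaced reference protocols, and
#' classifies the change in fit per protocol (see [classify_parameter()]).
#' The reference data are the noise-free normalized readouts of the
#' unperturbed model, making the analysis self-contained and deterministic.
#' A diverging perturbed simulation is flagged (`NA` change) and the class
#' taken from the remaining perturbations.
#'
#' @param params a `model_parameters` object.
#' @param parameters names to analyze; default all published-table parameters.
#' @param massed,spaced reference protocols (objects or packaged names).
#' @param dt solver step size.
#' @return data.frame with one row per parameter: `parameter`, `value`,
#'   `class_spaced`, `class_massed` and the raw change fractions.
#' @export
sensitivity_table <- function(params = param_preset("table1_primary"),
                              parameters = table1_parameter_names(),
                              massed = "massed90", spaced = "spaced5x5_15",
                              dt = 0.01) {
  validate_parameters(params)
  if (is.character(massed)) massed <- paper_protocol(massed)
  if (is.character(spaced)) spaced <- paper_protocol(spaced)
  protos <- list(massed = massed, spaced = spaced)
  refs <- lapply(protos, function(pr) {
    tr <- simulate_protocol(pr, params, dt = dt)
    normalized_translocation(tr)
  })
  factors <- c(d5_plus = 1.05, d5_minus = 0.95, d50_plus = 1.5,
               d50_minus = 0.5)
  rows <- lapply(parameters, function(pn) {
    ch <- sapply(names(protos), function(cond) {
      sapply(factors, function(f) {
        pert <- unclass(params)
        pert[[pn]] <- pert[[pn]] * f
        pert <- structure(pert, class = "model_parameters")
        tryCatch(.fit_change(pert, protos[[cond]], refs[[cond]], dt),
                 error = function(e) NA_real_)
      })
    })
    data.frame(parameter = pn, value = as.numeric(params[[pn]]),
               class_spaced = classify_parameter(ch[, "spaced"]),
               class_massed = classify_parameter(ch[, "massed"]),
               spaced_d5_plus = ch[1, "spaced"], spaced_d5_minus = ch[2, "spaced"],
               spaced_d50_plus = ch[3, "spaced"], spaced_d50_minus = ch[4, "spaced"],
               massed_d5_plus = ch[1, "massed"], massed_d5_minus = ch[2, "massed"],
               massed_d50_plus = ch[3, "massed"], massed_d50_minus = ch[4, "massed"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' Names of the published-table parameters
#'
#' The 39 parameters of the published table (excludes the auxiliaries
#' `kcAMPd` and `stim_5HT`).
#'
#' @return character vector.
#' @export
table1_parameter_names <- function() {
  setdiff(.param_names, c("kcAMPd", "stim_5HT"))
}

#' Published sensitivity classes
#'
#' The printed per-parameter High/Medium/Low classes under the spaced and
#' massed reference protocols, shipped as package data.
#'
#' @return data.frame with columns `parameter`, `value`, `class_spaced`,
#'   `class_massed`.
#' @export
table1_classes <- function() {
  f <- system.file("extdata", "table1_sensitivity_classes.csv",
                   package = "pkcdesens", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Count parameters whose spaced and massed classes agree
#'
#' @param classes data.frame with `class_spaced` and `class_massed` columns,
#'   e.g. from [table1_classes()] or [sensitivity_table()].
#' @return named integer vector with components `High`, `Medium`, `Low`.
#' @export
class_agreement_counts <- function(classes = table1_classes()) {
  agree <- classes$class_spaced == classes$class_massed
  out <- c(High = 0L, Medium = 0L, Low = 0L)
  tab <- table(classes$class_spaced[agree & !is.na(agree)])
  out[names(tab)] <- as.integer(tab)
  out
}

#' Write a sensitivity report as CSV
#'
#' Columns mirror the published table: parameter, value, class under the
#' spaced protocol, class under the massed protocol (plus raw changes).
#'
#' @param report data.frame from [sensitivity_table()].
#' @param file CSV path.
#' @export
write_sensitivity <- function(report, file) {
  utils::write.csv(report, file, row.names = FALSE)
  invisible(file)
}
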