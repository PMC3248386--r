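# Model parameters: every rate constant, Hill pair and window length of the
# receptor-trafficking / PKA / protein-synthesis network, plus two auxiliaries
# (kcAMPd, stim_5HT) that the published table does not list.
#
# Concentration-bearing quantities (stim_5HT, K5HT) are in molar; 10 uM 5HT is
# 1e-5. All first-order rate constants are per minute; windows and delays are
# minutes; receptor fractions and the protein/second-messenger species are
# dimensionless.

.param_names <- c(
  "kA1", "kA2", "kA3", "kA4", "kA5",
  "kDAGp", "kDAGd",
  "kB1", "kB2", "kB2a", "kB2b",
  "kC1", "kC2", "kC2a", "kC2b",
  "kD1", "kD1a", "kD1b", "kD2a", "kD2b", "kD3", "kD3a", "kD3b",
  "kS1", "kS1a", "kS1b", "kS2", "kS3", "kS3a", "kS3b", "kS4",
  "Vm", "K5HT", "cAMP_basal", "Kfpka", "Kbpka", "kcAMPd",
  "delayD", "intPKA", "intPKC",
  "stim_5HT"
)

# Hill exponents must be strictly positive; half-saturations strictly positive
# (they sit in denominators of Hill forms); windows strictly positive.
.hill_coef_names <- c("kB2b", "kC2b", "kD1b", "kD2b", "kD3b", "kS1b", "kS3b")
.half_sat_names  <- c("kB2a", "kC2a", "kD1a", "kD2a", "kD3a", "kS1a", "kS3a",
                      "K5HT")
.window_names    <- c("delayD", "intPKA", "intPKC")

.table1_primary <- list(
  kA1 = 1e5, kA2 = 1, kA3 = 3, kA4 = 0.2371, kA5 = 0.003,
  kDAGp = 200, kDAGd = 100,
  kB1 = 0.1276, kB2 = 0.2, kB2a = 0.5, kB2b = 6,
  kC1 = 2, kC2 = 0.1, kC2a = 1, kC2b = 1,
  kD1 = 8.0441, kD1a = 5.33e-8, kD1b = 0.3372,
  kD2a = 53.1, kD2b = 0.4187,
  kD3 = 0.0764, kD3a = 1.6e4, kD3b = 0.1385,
  kS1 = 0.026, kS1a = 6, kS1b = 4, kS2 = 0.2,
  kS3 = 0.4483, kS3a = 6, kS3b = 4, kS4 = 0.2847,
  Vm = 3.6, K5HT = 1.4e-5, cAMP_basal = 0.005,
  Kfpka = 105, Kbpka = 3, kcAMPd = 1,
  delayD = 10, intPKA = 15, intPKC = 15,
  stim_5HT = 1e-5
)

# Alternate set for the core translocation component (starred rows); the rest
# of the network is unchanged.
.table1_alternate <- utils::modifyList(.table1_primary, list(
  kA2 = 2, kDAGp = 2, kDAGd = 200, kA1 = 2e5, kA3 = 2, kA4 = 0.08
))

#' Construct a validated model parameter set
#'
#' Builds the full parameter set of the desensitization model, starting from a
#' packaged preset and overriding individual values. Rate constants are per
#' minute, Hill half-saturations and coefficients dimensionless (except `K5HT`,
#' molar), integration windows and the delay in minutes, and `stim_5HT` (the
#' serotonin concentration applied during a pulse) molar, default 1e-5 (10 uM).
#'
#' @param ... named scalar overrides, e.g. `kA4 = 0.2`.
#' @param base parameter list to start from; default the primary published set.
#' @return an object of class `model_parameters` (a named list).
#' @seealso [param_preset()]
#' @export
#' @examples
#' p <- model_parameters(kA5 = 0.01)
#' p$kA5
model_parameters <- function(..., base = param_preset("table1_primary")) {
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), .param_names)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           "; valid names are: ", paste(.param_names, collapse = ", "))
    base <- utils::modifyList(unclass(base), over)
  } else {
    base <- unclass(base)
  }
  p <- structure(base[.param_names], class = "model_parameters")
  validate_parameters(p)
  p
}

#' Packaged parameter presets
#'
#' `"table1_primary"` is the published primary parameter set;
#' `"table1_alternate"` replaces the starred core-translocation rows
#' (kA1 = 2e5, kA2 = 2, kA3 = 2, kA4 = 0.08, kDAGp = 2, kDAGd = 200).
#'
#' @param name preset name.
#' @return a `model_parameters` object.
#' @export
param_preset <- function(name = c("table1_primary", "table1_alternate")) {
  name <- match.arg(name)
  p <- switch(name, table1_primary = .table1_primary,
              table1_alternate = .table1_alternate)
  structure(p[.param_names], class = "model_parameters")
}

#' Validate a parameter set
#'
#' Checks completeness, non-negativity of all rate constants and
#' half-saturations, strict positivity of Hill coefficients, half-saturations
#' and window/delay lengths. Called by [model_parameters()]; exported so that
#' deserialized sets can be re-checked.
#'
#' @param params a `model_parameters` object or named list.
#' @return the validated parameter set, invisibly.
#' @export
validate_parameters <- function(params) {
  missing <- setdiff(.param_names, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  v <- unlist(params[.param_names])
  if (any(!is.finite(v)))
    stop("non-finite parameter(s): ",
         paste(.param_names[!is.finite(v)], collapse = ", "))
  if (any(v < 0))
    stop("negative parameter(s): ", paste(.param_names[v < 0], collapse = ", "))
  strict <- c(.hill_coef_names, .half_sat_names, .window_names)
  zero <- strict[unlist(params[strict]) <= 0]
  if (length(zero))
    stop("parameter(s) must be strictly positive: ",
         paste(zero, collapse = ", "))
  invisible(params)
}

# Named numeric vector in canonical order, for the compiled core.
as_param_vector <- function(params) {
  v <- unlist(params[.param_names])
  names(v) <- .param_names
  v
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters> (", length(.param_names), " parameters)\n", sep = "")
  v <- as_param_vector(x)
  print(signif(v, 6))
  invisible(x)
}

#' Read or write a parameter set as flat YAML/JSON
#'
#' Keys are exactly the parameter names. The format is chosen by the file
#' extension (`.yaml`/`.yml` or `.json`).
#'
#' @param params a `model_parameters` object.
#' @param file path to write to / read from.
#' @return `read_parameters()` returns a validated `model_parameters` object.
#' @export
write_parameters <- function(params, file) {
  validate_parameters(params)
  vals <- lapply(unclass(params)[.param_names], as.numeric)
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(vals, file, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, file)
  }
  invisible(file)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(file) {
  vals <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  do.call(model_parameters, as.list(vals))
}
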