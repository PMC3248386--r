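# Core model surface: state layout, Hill kinetics, the right-hand side of the
# integro-differential system, and the basal PKA fixed point.

# Canonical state ordering shared with the compiled core.
.state_names <- c("S_OFF", "S_ON", "S_IN1", "S_IN2", "S_PKA", "S_AD", "S_ADON",
                  "DAG", "cAMP", "R", "C", "RC", "AD", "D")
.receptor_names  <- .state_names[1:7]
.signaling_names <- .state_names[8:14]

#' State component names
#'
#' The model state is a named numeric vector of 14 components: seven receptor
#' fractions (`S_OFF`, `S_ON`, `S_IN1`, `S_IN2`, `S_PKA`, `S_AD`, `S_ADON`),
#' the membrane diacylglycerol level `DAG` (the translocation readout), and the
#' PKA module species `cAMP`, `R`, `C`, `RC` plus the synthesized proteins
#' `AD` and `D`.
#'
#' @return character vector of component names.
#' @export
state_names <- function() .state_names

#' Extract the receptor-state or signaling-state part of a model state
#'
#' @param state named numeric state vector (see [state_names()]).
#' @return named numeric vector of the seven receptor fractions
#'   (`receptor_state`) or the seven continuous species (`signaling_state`).
#' @export
receptor_state <- function(state) state[.receptor_names]

#' @rdname receptor_state
#' @export
signaling_state <- function(state) state[.signaling_names]

#' Hill function
#'
#' Activating form `x^n / (K^n + x^n)`; inhibiting form `K^n / (K^n + x^n)`.
#' Vectorized over `x`.
#'
#' @param x non-negative input.
#' @param K half-saturation, strictly positive.
#' @param n Hill coefficient, strictly positive.
#' @param mode `"activating"` or `"inhibiting"`.
#' @return value(s) in \[0, 1\].
#' @export
#' @examples
#' hill(2, K = 1, n = 4)               # 16/17
#' hill(0, K = 1, n = 2, "inhibiting") # 1
hill <- function(x, K, n, mode = c("activating", "inhibiting")) {
  mode <- match.arg(mode)
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("invalid parameter: half-saturation K must be a positive scalar")
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("invalid parameter: Hill coefficient n must be a positive scalar")
  if (any(x < 0)) stop("hill() requires non-negative x")
  xn <- x^n
  Kn <- K^n
  if (mode == "activating") xn / (Kn + xn) else Kn / (Kn + xn)
}

#' Right-hand side of the desensitization model
#'
#' Evaluates the time-derivative of the full 14-component state given the
#' instantaneous inputs and the two precomputed windowed history integrals.
#' The receptor derivatives sum to exactly zero (total S is conserved by
#' construction). With `kt5720 = TRUE` every receptor/synthesis term that
#' contains PKA activity (the free catalytic subunit C) uses zero in its
#' place; with `anisomycin = TRUE` the synthesis terms of AD and D are zero
#' while their degradation is unaffected.
#'
#' @param t time in minutes (the system is autonomous given its inputs; `t` is
#'   accepted for interface completeness).
#' @param state named numeric state vector, see [state_names()].
#' @param inputs list with `fiveHT` (molar), `anisomycin`, `kt5720` (logical).
#' @param histories list with `intPKC_value` (integral of DAG over the PKC
#'   window) and `intPKA_delayed_value` (delayed integral of C over the PKA
#'   window), as computed by the integrator.
#' @param params a `model_parameters` object.
#' @return named derivative vector, same shape as `state` (units 1/min).
#' @export
model_rhs <- function(t, state, inputs, histories, params) {
  validate_parameters(params)
  state <- state[.state_names]
  if (any(is.na(state)))
    stop("state must contain all components: ",
         paste(.state_names, collapse = ", "))
  if (any(state < -1e-6))
    stop("invalid state: component(s) ",
         paste(.state_names[state < -1e-6], collapse = ", "),
         " negative beyond tolerance")
  .rhs_cpp(state,
           fiveHT = as.numeric(inputs$fiveHT),
           aniso = isTRUE(inputs$anisomycin),
           kt = isTRUE(inputs$kt5720),
           ipkc = as.numeric(histories$intPKC_value),
           ipka = as.numeric(histories$intPKA_delayed_value),
           params = as_param_vector(params))
}

#' PKA activity of a state
#'
#' PKA activity is identified with the amount of free catalytic subunit C.
#'
#' @param state named state vector (or any vector containing a `C` component).
#' @return non-negative scalar.
#' @export
pka_activity <- function(state) {
  if (!"C" %in% names(state)) stop("state has no catalytic-subunit component C")
  unname(state["C"])
}

#' Basal fixed point of the PKA subunit cycle
#'
#' At basal cAMP the dissociation flux `Kfpka * cAMP * RC` balances the
#' reassociation flux `Kbpka * R * C`. With total regulatory and catalytic
#' subunit pools both set to 1 (R + RC = C + RC = 1, so R = C), the balance is
#' a quadratic in RC solved in closed form; the root in \[0, 1\] is returned.
#'
#' @param params a `model_parameters` object.
#' @return named vector with components `R`, `C`, `RC`.
#' @export
basal_pka_state <- function(params) {
  kb <- params$Kbpka
  kf <- params$Kfpka
  cb <- params$cAMP_basal
  # kb*RC^2 - (2*kb + kf*cb)*RC + kb = 0
  b <- 2 * kb + kf * cb
  disc <- b^2 - 4 * kb^2
  if (disc < 0 || kb <= 0)
    stop("basal PKA fixed point does not exist for these parameters")
  rc <- (b - sqrt(disc)) / (2 * kb)
  if (rc < 0 || rc > 1)
    stop("basal PKA fixed-point solve failed to converge to a root in [0, 1]")
  c(R = 1 - rc, C = 1 - rc, RC = rc)
}
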