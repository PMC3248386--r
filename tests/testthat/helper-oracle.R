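# Independent flux-by-flux oracle for the model right-hand side. Written as an
# explicit edge list over the reaction network (from-state, to-state, rate),
# assembled by summation -- structurally unlike the packaged implementation,
# so agreement is a genuine cross-check.

oracle_hill_act <- function(x, K, n) {
  x <- max(x, 0)
  if (x == 0) return(0)
  1 / (1 + (K / x)^n)
}
oracle_hill_inh <- function(x, K, n) 1 - oracle_hill_act(x, K, n)

oracle_rhs <- function(state, fiveHT, aniso, kt, ipkc, ipka, p) {
  s <- as.list(state)
  C_eff <- if (kt) 0 else s$C
  AD <- max(s$AD, 0)
  D <- max(s$D, 0)

  # receptor network as an edge list: list(from, to, flux)
  edges <- list(
    list("S_OFF", "S_ON",  p$kA1 * fiveHT * s$S_OFF),
    list("S_ON",  "S_IN1", p$kA2 * s$S_ON),
    list("S_IN1", "S_OFF", p$kA3 * s$S_IN1),
    list("S_IN1", "S_IN2", p$kA4 * s$S_IN1),
    list("S_IN2", "S_OFF", p$kA5 * s$S_IN2),
    list("S_OFF", "S_PKA", (p$kB1 * C_eff + p$kD1 * D) *
           oracle_hill_inh(AD, p$kD1a, p$kD1b) * s$S_OFF),
    list("S_PKA", "S_OFF", p$kB2 * oracle_hill_inh(C_eff, p$kB2a, p$kB2b) *
           oracle_hill_inh(D, p$kD2a, p$kD2b) * s$S_PKA),
    list("S_PKA", "S_AD",  p$kD3 * oracle_hill_act(AD, p$kD3a, p$kD3b) *
           s$S_PKA),
    list("S_OFF", "S_AD",  p$kC1 * AD * s$S_OFF),
    list("S_AD",  "S_OFF", p$kC2 * oracle_hill_inh(AD, p$kC2a, p$kC2b) *
           s$S_AD),
    list("S_AD",  "S_ADON", p$kA1 * fiveHT * s$S_AD),
    list("S_ADON", "S_AD",  p$kA2 * s$S_ADON)
  )
  d <- setNames(numeric(length(state_names())), state_names())
  for (e in edges) {
    d[[e[[1]]]] <- d[[e[[1]]]] - e[[3]]
    d[[e[[2]]]] <- d[[e[[2]]]] + e[[3]]
  }

  d[["DAG"]] <- p$kDAGp * (s$S_ON + s$S_ADON) - p$kDAGd * s$DAG
  d[["cAMP"]] <- p$Vm * oracle_hill_act(fiveHT, p$K5HT, 1) -
    p$kcAMPd * (s$cAMP - p$cAMP_basal)
  diss <- p$Kfpka * s$cAMP * s$RC
  reas <- p$Kbpka * s$R * s$C
  d[["R"]] <- diss - reas
  d[["C"]] <- diss - reas
  d[["RC"]] <- reas - diss
  d[["AD"]] <- (if (aniso) 0 else
    p$kS1 * oracle_hill_act(ipkc, p$kS1a, p$kS1b)) - p$kS2 * s$AD
  d[["D"]] <- (if (aniso) 0 else
    p$kS3 * oracle_hill_act(ipka, p$kS3a, p$kS3b)) - p$kS4 * s$D
  d
}

# A random admissible model state (receptor fractions on the simplex,
# non-negative continuous species with conserved subunit totals).
random_state <- function() {
  r <- stats::runif(7)
  r <- r / sum(r)
  rc <- stats::runif(1)
  s <- c(r, stats::runif(1, 0, 2), stats::runif(1, 0, 2),
         1 - rc, 1 - rc, rc, stats::runif(1, 0, 0.3), stats::runif(1, 0, 2))
  setNames(s, state_names())
}

# A fake trace with a prescribed translocation series, for readout tests.
fake_trace <- function(protocol, time, translocation) {
  structure(list(time = time,
                 state = matrix(0, length(time), 14,
                                dimnames = list(NULL, state_names())),
                 translocation = translocation, protocol = protocol,
                 params = param_preset("table1_primary"),
                 dt = time[2] - time[1]),
            class = "translocation_trace")
}
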