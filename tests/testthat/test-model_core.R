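test_that("hill function matches its closed form and rejects bad parameters", {
  expect_equal(hill(1, K = 1, n = 3), 0.5)          # half-saturation
  expect_equal(hill(7, K = 7, n = 0.42), 0.5)
  expect_equal(hill(0, K = 2, n = 5, "inhibiting"), 1)
  expect_equal(hill(2, K = 1, n = 4), 16 / 17)
  expect_equal(hill(2, K = 1, n = 4, "inhibiting"), 1 / 17)
  x <- c(0, 0.3, 1, 4)
  expect_true(all(hill(x, 0.7, 2.3) >= 0 & hill(x, 0.7, 2.3) <= 1))
  expect_equal(hill(x, 0.7, 2.3) + hill(x, 0.7, 2.3, "inhibiting"),
               rep(1, 4))
  expect_error(hill(1, K = 0, n = 2), "invalid parameter")
  expect_error(hill(1, K = 1, n = -1), "invalid parameter")
  expect_error(hill(-1, K = 1, n = 2), "non-negative")
})

test_that("packaged presets reproduce the published parameter table", {
  p <- param_preset("table1_primary")
  expect_equal(p$kA4, 0.2371)
  expect_equal(p$kA5, 0.003)
  expect_equal(p$kD1a, 5.33e-8)
  expect_equal(p$kD2a, 53.1)
  expect_equal(p$K5HT, 1.4e-5)
  expect_equal(p$cAMP_basal, 0.005)
  a <- param_preset("table1_alternate")
  expect_equal(a[c("kA1", "kA2", "kA3", "kA4", "kDAGp", "kDAGd")],
               list(kA1 = 2e5, kA2 = 2, kA3 = 2, kA4 = 0.08, kDAGp = 2,
                    kDAGd = 200), ignore_attr = TRUE)
  # the alternate set only replaces the starred core rows
  same <- setdiff(names(unclass(p)),
                  c("kA1", "kA2", "kA3", "kA4", "kDAGp", "kDAGd"))
  expect_identical(unclass(p)[same], unclass(a)[same])
})

test_that("parameter validation enforces positivity constraints", {
  expect_error(model_parameters(kA1 = -1), "negative")
  expect_error(model_parameters(kS1b = 0), "strictly positive")
  expect_error(model_parameters(intPKC = 0), "strictly positive")
  expect_error(model_parameters(nonsense = 1), "unknown parameter")
  # round-trip through flat YAML and JSON
  p <- model_parameters(kA4 = 0.19)
  for (ext in c("yaml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_parameters(p, f)
    expect_equal(unclass(read_parameters(f)), unclass(p))
  }
})

test_that("rhs is zero for an unstimulated naive receptor with drugs on", {
  p <- param_preset("table1_primary")
  s <- setNames(numeric(14), state_names())
  s["S_OFF"] <- 1
  d <- model_rhs(0, s, inputs = list(fiveHT = 0, anisomycin = TRUE,
                                     kt5720 = TRUE),
                 histories = list(intPKC_value = 0, intPKA_delayed_value = 0),
                 params = p)
  expect_equal(unname(d[c(1:7, 13, 14)]), numeric(9))
})

test_that("S_IN2 recycling flux equals kA5 * S_IN2", {
  p <- param_preset("table1_primary")
  s <- setNames(numeric(14), state_names())
  s["S_IN2"] <- 0.5
  s["S_OFF"] <- 0.5
  d <- model_rhs(0, s, inputs = list(fiveHT = 0, anisomycin = TRUE,
                                     kt5720 = TRUE),
                 histories = list(intPKC_value = 0, intPKA_delayed_value = 0),
                 params = p)
  expect_equal(unname(d["S_IN2"]), -0.0015)
  expect_equal(unname(d["S_OFF"]), 0.0015)
})

test_that("rhs agrees with an independent flux-by-flux oracle", {
  p <- param_preset("table1_primary")
  set.seed(7)
  for (i in 1:40) {
    s <- random_state()
    fiveHT <- sample(c(0, 1e-5), 1)
    aniso <- runif(1) < 0.5
    kt <- runif(1) < 0.5
    ipkc <- runif(1, 0, 20)
    ipka <- runif(1, 0, 20)
    got <- model_rhs(0, s, list(fiveHT = fiveHT, anisomycin = aniso,
                                kt5720 = kt),
                     list(intPKC_value = ipkc, intPKA_delayed_value = ipka), p)
    want <- oracle_rhs(s, fiveHT, aniso, kt, ipkc, ipka, p)
    expect_lt(max(abs(got - want)), 1e-10)
    # conservation by construction: receptor derivatives sum to (exactly) zero
    expect_lt(abs(sum(got[1:7])), 1e-15)
    # subunit totals conserved: dR + dRC = dC + dRC = 0
    expect_equal(unname(got["R"] + got["RC"]), 0)
    expect_equal(unname(got["C"] + got["RC"]), 0)
  }
})

test_that("rhs rejects states that are negative beyond tolerance", {
  p <- param_preset("table1_primary")
  s <- setNames(numeric(14), state_names())
  s["S_OFF"] <- 1
  s["DAG"] <- -0.01
  expect_error(
    model_rhs(0, s, list(fiveHT = 0, anisomycin = FALSE, kt5720 = FALSE),
              list(intPKC_value = 0, intPKA_delayed_value = 0), p),
    "invalid state")
})

test_that("PKA activity is the free catalytic subunit", {
  s <- setNames(numeric(14), state_names())
  expect_equal(pka_activity(s), 0)
  s["C"] <- 0.3
  s["RC"] <- 0.7
  expect_equal(pka_activity(s), 0.3)
})

test_that("basal PKA state is the stationary point of the subunit cycle", {
  p <- param_preset("table1_primary")
  b <- basal_pka_state(p)
  # oracle: root of the balance found independently by uniroot
  bal <- function(rc) p$Kfpka * p$cAMP_basal * rc - p$Kbpka * (1 - rc)^2
  rc_star <- uniroot(bal, c(0, 1), tol = 1e-14)$root
  expect_equal(unname(b["RC"]), rc_star, tolerance = 1e-9)
  # residual of the stationarity equations at the returned point
  expect_lt(abs(p$Kfpka * p$cAMP_basal * b["RC"] -
                p$Kbpka * b["R"] * b["C"]), 1e-10)
  expect_equal(unname(b["R"] + b["RC"]), 1)
})

test_that("anisomycin leaves pure exponential decay of AD and D", {
  p <- param_preset("table1_primary")
  pr <- build_protocol(data.frame(start = 0, end = 60),
                       aniso_windows = data.frame(start = 30, end = 60),
                       duration = 60)
  tr <- simulate_protocol(pr, p)
  i30 <- which(abs(tr$time - 30) < 1e-9)
  ad30 <- tr$state[i30, "AD"]
  d30 <- tr$state[i30, "D"]
  expect_gt(ad30, 0)
  expect_gt(d30, 0)
  for (tt in c(35, 45, 60)) {
    it <- which(abs(tr$time - tt) < 1e-9)
    expect_equal(tr$state[it, "AD"], ad30 * exp(-p$kS2 * (tt - 30)),
                 tolerance = 1e-6)
    expect_equal(tr$state[it, "D"], d30 * exp(-p$kS4 * (tt - 30)),
                 tolerance = 1e-6)
  }
})

test_that("KT5720 is equivalent to deleting PKA activity from every term", {
  # clamping C should match a model in which the C-driven terms are removed:
  # kB1 = 0 (no C-driven sequestration), a huge kB2a (recycling Hill at 1),
  # kS3 = 0 (no D synthesis from the clamped activity integral)
  p <- param_preset("table1_primary")
  tr_kt <- simulate_protocol("massed90_kt", p, dt = 0.01)
  p0 <- model_parameters(kB1 = 0, kB2a = 1e12, kS3 = 0)
  pr <- build_protocol(data.frame(start = 0, end = 90), duration = 90)
  tr0 <- simulate_protocol(pr, p0, dt = 0.01)
  cols <- c("S_OFF", "S_ON", "S_IN1", "S_IN2", "S_PKA", "S_AD", "S_ADON",
            "DAG", "AD", "D")
  expect_lt(max(abs(tr_kt$state[, cols] - tr0$state[, cols])), 1e-9)
})
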