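p_primary <- param_preset("table1_primary")

test_that("windowed trapezoid integral is exact for constants and ramps", {
  tt <- seq(0, 20, by = 0.1)
  # constant series
  expect_equal(windowed_integral(tt, rep(3, length(tt)), t = 15, window = 4),
               12)
  # linear ramp: trapezoid is exact
  expect_equal(windowed_integral(tt, tt, t = 10, window = 10), 50)
  # delayed window of a ramp: integral of u over [4, 8]
  expect_equal(windowed_integral(tt, tt, t = 10, window = 4, delay = 2), 24)
  # window truncated at zero history
  expect_equal(windowed_integral(tt, rep(2, length(tt)), t = 3, window = 10),
               6)
  # zero when t <= delay
  expect_equal(windowed_integral(tt, tt, t = 5, window = 3, delay = 5), 0)
  # fractional (off-grid) endpoints still integrate a constant exactly
  expect_equal(windowed_integral(tt, rep(2, length(tt)), t = 10.07,
                                 window = 1.13, delay = 0.55), 2.26)
  expect_error(windowed_integral(tt, tt, t = 25, window = 1),
               "outside computed history")
})

test_that("windowed integral of sin matches its antiderivative at O(dt^2)", {
  err_at <- function(dt) {
    tt <- seq(0, 10, by = dt)
    got <- windowed_integral(tt, sin(tt), t = 10, window = pi, delay = 2)
    abs(got - (cos(8 - pi) - cos(8)))
  }
  e1 <- err_at(0.02)
  e2 <- err_at(0.005)
  expect_lt(e1, 1e-3)
  expect_gt(e1 / e2, 8)   # ~16 expected for a second-order rule
  expect_lt(e1 / e2, 32)
})

test_that("initial state is the naive neuron at the basal PKA fixed point", {
  s <- initial_state(p_primary)
  expect_equal(unname(s["S_OFF"]), 1)
  expect_equal(unname(s[c("S_ON", "S_IN1", "S_IN2", "S_PKA", "S_AD",
                          "S_ADON", "DAG", "AD", "D")]), numeric(9))
  expect_equal(unname(s["cAMP"]), 0.005)
  expect_lt(abs(p_primary$Kfpka * s["cAMP"] * s["RC"] -
                p_primary$Kbpka * s["R"] * s["C"]), 1e-10)
})

test_that("receptor conservation and positivity hold along trajectories", {
  for (nm in c("massed90", "spaced5x5_15",
               "massed90_then45wash_then5_aniso_kt", "kt25_then_ktaniso65")) {
    tr <- simulate_protocol(nm, p_primary)
    expect_lt(max(abs(rowSums(tr$state[, 1:7]) - 1)), 1e-8)
    expect_gt(min(tr$state), -1e-9)
    # PKA subunit totals constant
    expect_lt(max(abs(tr$state[, "R"] + tr$state[, "RC"] -
                      (tr$state[1, "R"] + tr$state[1, "RC"]))), 1e-8)
  }
})

test_that("translocation rises within a minute and clears within a minute", {
  pr <- build_protocol(data.frame(start = 0, end = 5), duration = 10)
  tr <- simulate_protocol(pr, p_primary)
  plateau <- trace_value(tr, 5)
  expect_gte(trace_value(tr, 1) / plateau, 0.9)
  expect_lt(trace_value(tr, 6) / plateau, 0.5)
})

test_that("the scheme self-converges at fourth order", {
  # smooth sub-problem: constant 5HT, protein synthesis off, no input events
  pr <- build_protocol(data.frame(start = 0, end = 10),
                       aniso_windows = data.frame(start = 0, end = 10),
                       duration = 10)
  ref <- simulate_protocol(pr, p_primary, dt = 0.01 / 16)
  end_state <- function(tr) tr$state[nrow(tr$state), ]
  e1 <- max(abs(end_state(simulate_protocol(pr, p_primary, dt = 0.01)) -
                end_state(ref)))
  e2 <- max(abs(end_state(simulate_protocol(pr, p_primary, dt = 0.005)) -
                end_state(ref)))
  expect_gt(e1 / e2, 8)
  expect_lt(e1 / e2, 32)
})

test_that("traces are step-size robust at the default resolution", {
  for (nm in protocol_names()) {
    a <- simulate_protocol(nm, p_primary, dt = 0.01)
    b <- simulate_protocol(nm, p_primary, dt = 0.005)
    idx <- seq(1, length(b$translocation), by = 2)
    rel <- max(abs(a$translocation - b$translocation[idx])) /
      max(a$translocation)
    expect_lt(rel, 1e-3)
  }
})

test_that("the receptor subsystem without PKA/AD/D matches its matrix exponential", {
  skip_if_not_installed("Matrix")
  p <- p_primary
  pr <- build_protocol(data.frame(start = 0, end = 20),
                       aniso_windows = data.frame(start = 0, end = 20),
                       kt_windows = data.frame(start = 0, end = 20),
                       duration = 20)
  tr <- simulate_protocol(pr, p, dt = 0.01)
  a <- p$kA1 * p$stim_5HT
  A <- rbind(c(-a,     0,       p$kA3,            p$kA5),
             c( a, -p$kA2,      0,                0),
             c( 0,  p$kA2, -(p$kA3 + p$kA4),     0),
             c( 0,      0,      p$kA4,       -p$kA5))
  for (tt in c(0.5, 2, 10, 20)) {
    y <- as.numeric(Matrix::expm(A * tt) %*% c(1, 0, 0, 0))
    got <- sapply(c("S_OFF", "S_ON", "S_IN1", "S_IN2"),
                  function(w) trace_value(tr, tt, what = w))
    expect_lt(max(abs(got - y)), 1e-6)
  }
})

test_that("grid and event-alignment preconditions are enforced", {
  pr <- build_protocol(data.frame(start = 0, end = 5), duration = 10)
  expect_error(simulate_protocol(pr, p_primary, dt = -0.01), "dt")
  expect_error(simulate_protocol(pr, p_primary, dt = 0.01, t_end = 4),
               "duration")
  pr2 <- build_protocol(data.frame(start = 0, end = 5.005), duration = 10)
  expect_error(simulate_protocol(pr2, p_primary, dt = 0.01),
               "does not divide")
})

test_that("a divergent integration is reported with the offending step", {
  # dt far outside the RK4 stability limit of the fast subunit dissociation
  pr <- build_protocol(data.frame(start = 0, end = 90), duration = 90)
  expect_error(simulate_protocol(pr, p_primary, dt = 0.1), "step")
})

test_that("trace export writes tidy CSV with a conservation column", {
  tr <- simulate_protocol("twopulse_5_5", p_primary, dt = 0.01)
  f <- withr::local_tempfile(fileext = ".csv")
  mf <- withr::local_tempfile(fileext = ".json")
  write_trace(tr, f, mf)
  df <- read.csv(f)
  expect_named(df, c("time", state_names(), "translocation", "sum_S"))
  expect_lt(max(abs(df$sum_S - 1)), 1e-8)
  meta <- jsonlite::read_json(mf)
  expect_equal(meta$protocol$name, "twopulse_5_5")
  expect_equal(meta$dt, 0.01)
  expect_equal(meta$params$kA4, 0.2371)
})
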