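# Fixed-step numerical solution of the delayed integro-differential system:
# classical RK4 for the differential part, trapezoid rule on the solver grid
# for the two history integrals. Integral values are refreshed at the start of
# each step and held over its stages (the windows intPKC/intPKA are three
# orders of magnitude longer than the default step).

#' Initial model state
#'
#' Pre-stimulus naive neuron: all signaling complex in `S_OFF`; no DAG, AD or
#' D; cAMP at its basal level; PKA subunits at the basal fixed point with
#' total regulatory and catalytic pools of 1 (see [basal_pka_state()]).
#' Histories before t = 0 are taken as zero (windowed integrals truncate at
#' t = 0).
#'
#' @param params a `model_parameters` object.
#' @return named numeric state vector, see [state_names()].
#' @export
initial_state <- function(params) {
  validate_parameters(params)
  pka <- basal_pka_state(params)
  s <- stats::setNames(numeric(length(.state_names)), .state_names)
  s["S_OFF"] <- 1
  s["cAMP"] <- params$cAMP_basal
  s["R"] <- pka["R"]
  s["C"] <- pka["C"]
  s["RC"] <- pka["RC"]
  s
}

#' Windowed trapezoid integral of a sampled series
#'
#' Trapezoid-rule approximation of the integral of `series` over
#' `[max(0, t - delay - window), max(0, t - delay)]`. The series is sampled on
#' a uniform grid; window endpoints that fall between grid nodes are handled
#' by linear interpolation of the cumulative integral. Exactly zero when
#' `t <= delay`.
#'
#' @param time uniform, strictly increasing sample times (minutes).
#' @param series sampled values, same length as `time`.
#' @param t evaluation time; must lie within the computed history.
#' @param window window length (minutes), non-negative.
#' @param delay delay (minutes), non-negative.
#' @return scalar integral value.
#' @export
#' @examples
#' tt <- seq(0, 10, by = 0.1)
#' windowed_integral(tt, tt, t = 10, window = 10) # 50, exact for a ramp
windowed_integral <- function(time, series, t, window, delay = 0) {
  if (length(time) != length(series) || length(time) < 2)
    stop("time and series must be equal-length vectors (>= 2 points)")
  if (t < 0 || window < 0 || delay < 0)
    stop("t, window and delay must be non-negative")
  if (t > time[length(time)] + 1e-9)
    stop("t = ", t, " outside computed history [", time[1], ", ",
         time[length(time)], "]")
  dt <- time[2] - time[1]
  q <- c(0, cumsum((series[-1] + series[-length(series)]) / 2 * dt))
  q_at <- function(tt) {
    tt <- min(max(tt, 0), time[length(time)])
    x <- (tt - time[1]) / dt
    i0 <- floor(x)
    fr <- x - i0
    i0 <- as.integer(i0) + 1L
    if (i0 >= length(q)) return(q[length(q)])
    q[i0] + fr * (q[i0 + 1L] - q[i0])
  }
  upper <- max(0, t - delay)
  lower <- max(0, t - delay - window)
  q_at(upper) - q_at(lower)
}

#' Simulate a protocol
#'
#' Advances the full model with a fixed-step fourth-order Runge-Kutta scheme,
#' recomputing the two windowed history integrals (PKC activity feeding AD
#' synthesis; delayed PKA activity feeding D synthesis) from the stored
#' trajectory at every step via the trapezoid rule. Protocol transitions must
#' fall on grid points (`dt` must divide all event times).
#'
#' @param protocol a `stimulus_protocol`, or the name of a packaged one.
#' @param params a `model_parameters` object.
#' @param dt step size in minutes (default 0.01).
#' @param t_end simulation end time; defaults to the protocol duration, may
#'   exceed it (inputs are all off past the end).
#' @return a `translocation_trace`: list with `time`, `state` (matrix, one row
#'   per grid point), `translocation` (the DAG series), `ipkc`/`ipka` (the
#'   history-integral series), `protocol`, `params`, `dt`.
#' @export
#' @examples
#' tr <- simulate_protocol(paper_protocol("massed90_aniso_kt"),
#'                         param_preset("table1_primary"), dt = 0.05,
#'                         t_end = 10)
#' max(abs(rowSums(tr$state[, 1:7]) - 1))
simulate_protocol <- function(protocol, params = param_preset("table1_primary"),
                              dt = 0.01, t_end = NULL) {
  if (is.character(protocol)) protocol <- paper_protocol(protocol)
  stopifnot(inherits(protocol, "stimulus_protocol"))
  validate_parameters(params)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  if (is.null(t_end)) t_end <- protocol$duration
  if (t_end < protocol$duration - 1e-9)
    stop("t_end must be at least the protocol duration (", protocol$duration,
         " min)")
  ev <- .event_times(protocol)
  off <- abs(ev / dt - round(ev / dt))
  if (any(off > 1e-6))
    stop("dt = ", dt, " does not divide protocol event time(s): ",
         paste(ev[off > 1e-6], collapse = ", "))
  n <- round(t_end / dt)
  if (abs(n * dt - t_end) > 1e-6 * max(1, t_end))
    stop("dt = ", dt, " does not divide t_end = ", t_end)
  gi <- .grid_inputs(protocol, dt, n)
  res <- .simulate_cpp(initial_state(params), as_param_vector(params),
                       gi$fiveHT, gi$aniso, gi$kt, dt, n)
  structure(list(time = seq(0, by = dt, length.out = n + 1L),
                 state = `colnames<-`(res$state, .state_names),
                 translocation = res$state[, 8L],
                 ipkc = res$ipkc, ipka = res$ipka,
                 protocol = protocol, params = params, dt = dt),
            class = "translocation_trace")
}

#' @export
print.translocation_trace <- function(x, ...) {
  cat("<translocation_trace> protocol '", x$protocol$name, "', dt = ", x$dt,
      " min, ", length(x$time), " points over [0, ",
      x$time[length(x$time)], "] min\n", sep = "")
  cons <- max(abs(rowSums(x$state[, 1:7]) - 1))
  cat("  max |sum(S) - 1| = ", format(cons, digits = 3),
      "; peak translocation = ", format(max(x$translocation), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.translocation_trace <- function(x, ...) {
  data.frame(time = x$time, x$state, translocation = x$translocation,
              check.names = FALSE)
}

#' Interpolate a trace at arbitrary times
#'
#' Linear interpolation on the solver grid.
#'
#' @param trace a `translocation_trace`.
#' @param times times in minutes, within the trace range.
#' @param what column of the state to interpolate, or `"translocation"`.
#' @return numeric vector of interpolated values.
#' @export
trace_value <- function(trace, times, what = "translocation") {
  y <- if (what == "translocation") trace$translocation
       else trace$state[, what]
  if (any(times < trace$time[1] - 1e-9 |
          times > trace$time[length(trace$time)] + 1e-9))
    stop("requested time(s) outside the computed trace")
  stats::approx(trace$time, y, xout = times, rule = 2)$y
}

#' Export a trace as tidy CSV (plus JSON metadata)
#'
#' The CSV holds time, every state component, the translocation readout and a
#' receptor-conservation column `sum_S`. The optional JSON sidecar records the
#' protocol, step size and full parameter set.
#'
#' @param trace a `translocation_trace`.
#' @param file CSV path.
#' @param metadata_file optional JSON path.
#' @export
write_trace <- function(trace, file, metadata_file = NULL) {
  df <- as.data.frame(trace)
  df$sum_S <- rowSums(trace$state[, 1:7])
  utils::write.csv(df, file, row.names = FALSE)
  if (!is.null(metadata_file)) {
    meta <- list(protocol = protocol_to_list(trace$protocol), dt = trace$dt,
                 n_points = length(trace$time),
                 params = lapply(unclass(trace$params)[.param_names],
                                 as.numeric),
                 max_conservation_deviation =
                   max(abs(rowSums(trace$state[, 1:7]) - 1)))
    jsonlite::write_json(meta, metadata_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}
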