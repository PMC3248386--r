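# Stimulation and drug schedules. A protocol is a set of half-open intervals
# [start, end) in minutes on three channels: 5HT pulses (with concentration),
# anisomycin windows and KT5720 windows. Times are minutes from first 5HT
# onset; drugs "present throughout" map to [0, duration].

.norm_windows <- function(w) {
  if (is.null(w) || (is.data.frame(w) && nrow(w) == 0)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  if (is.matrix(w)) w <- data.frame(start = w[, 1], end = w[, 2])
  if (!is.data.frame(w) || !all(c("start", "end") %in% names(w)))
    stop("windows must be a data.frame with columns 'start' and 'end'")
  w <- w[order(w$start), c("start", "end"), drop = FALSE]
  rownames(w) <- NULL
  w
}

.check_windows <- function(w, duration, channel) {
  bad <- character(0)
  if (nrow(w) == 0) return(invisible())
  if (any(w$end <= w$start))
    bad <- c(bad, paste0(channel, " interval(s) with end <= start: ",
                         paste(which(w$end <= w$start), collapse = ", ")))
  if (any(w$start < 0) || any(w$end > duration))
    bad <- c(bad, paste0(channel, " interval(s) outside [0, ", duration, "]: ",
                         paste(which(w$start < 0 | w$end > duration),
                               collapse = ", ")))
  if (nrow(w) > 1 && any(w$start[-1] < w$end[-nrow(w)]))
    bad <- c(bad, paste0(channel, " overlapping interval(s): ",
                         paste(which(w$start[-1] < w$end[-nrow(w)]) + 1L,
                               collapse = ", ")))
  if (length(bad)) stop("invalid protocol: ", paste(bad, collapse = "; "))
  invisible()
}

#' Build a stimulation/drug protocol
#'
#' @param pulses data.frame (or 2-column matrix) of 5HT pulse intervals with
#'   columns `start`, `end` (minutes); may be empty for a constant-zero
#'   stimulus.
#' @param fiveHT serotonin concentration during pulses, molar (default 1e-5,
#'   i.e. 10 uM).
#' @param aniso_windows,kt_windows drug windows, same format as `pulses`.
#' @param duration total duration in minutes; defaults to the latest interval
#'   end.
#' @param name protocol name.
#' @return a `stimulus_protocol` object.
#' @export
#' @examples
#' p <- build_protocol(data.frame(start = c(0, 20), end = c(5, 25)),
#'                     duration = 40)
#' inputs_at(p, 2)$fiveHT
build_protocol <- function(pulses, fiveHT = 1e-5, aniso_windows = NULL,
                           kt_windows = NULL, duration = NULL,
                           name = "custom") {
  pulses <- .norm_windows(pulses)
  aniso <- .norm_windows(aniso_windows)
  kt <- .norm_windows(kt_windows)
  if (!is.numeric(fiveHT) || length(fiveHT) != 1L || fiveHT < 0)
    stop("invalid protocol: fiveHT concentration must be a non-negative scalar")
  if (is.null(duration))
    duration <- max(0, pulses$end, aniso$end, kt$end)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("invalid protocol: duration must be a positive scalar")
  .check_windows(pulses, duration, "5HT pulse")
  .check_windows(aniso, duration, "anisomycin")
  .check_windows(kt, duration, "KT5720")
  structure(list(name = name, duration = duration, fiveHT = fiveHT,
                 pulses = pulses, aniso = aniso, kt = kt),
            class = "stimulus_protocol")
}

# Named library of the stimulation protocols used in the study. Spaced
# training: 5-min pulses at a 20-min intertrial interval (onset to onset),
# i.e. 15-min washes.
.protocol_specs <- function() {
  iv <- function(s, e) data.frame(start = s, end = e)
  p5x5 <- iv(c(0, 20, 40, 60, 80), c(5, 25, 45, 65, 85))
  full <- function(d) iv(0, d)
  specs <- list(
    massed90          = list(pulses = iv(0, 90), duration = 90),
    massed90_aniso    = list(pulses = iv(0, 90), aniso = full(90),
                             duration = 90),
    massed90_kt       = list(pulses = iv(0, 90), kt = full(90), duration = 90),
    massed90_aniso_kt = list(pulses = iv(0, 90), aniso = full(90),
                             kt = full(90), duration = 90),
    spaced5x5_15          = list(pulses = p5x5, duration = 100),
    spaced5x5_15_aniso    = list(pulses = p5x5, aniso = full(100),
                                 duration = 100),
    spaced5x5_15_kt       = list(pulses = p5x5, kt = full(100),
                                 duration = 100),
    spaced5x5_15_aniso_kt = list(pulses = p5x5, aniso = full(100),
                                 kt = full(100), duration = 100),
    massed90_then45wash_then5_aniso_kt =
      list(pulses = iv(c(0, 135), c(90, 140)), aniso = full(140),
           kt = full(140), duration = 140),
    massed90_then45wash_then5_aniso =
      list(pulses = iv(c(0, 135), c(90, 140)), aniso = full(140),
           duration = 140),
    kt25_then_ktaniso65 = list(pulses = iv(0, 90), kt = full(90),
                               aniso = iv(25, 90), duration = 90),
    threex15_wash15 = list(pulses = iv(c(0, 30, 60), c(15, 45, 75)),
                           duration = 80),
    threex15_wash25 = list(pulses = iv(c(0, 40, 80), c(15, 55, 95)),
                           duration = 100),
    twopulse_130wash_aniso_kt =
      list(pulses = iv(c(0, 135), c(5, 140)), aniso = full(140),
           kt = full(140), duration = 140)
  )
  for (w in c(5, 10, 15, 30, 45)) {
    specs[[paste0("twopulse_5_", w)]] <-
      list(pulses = iv(c(0, 5 + w), c(5, 10 + w)), duration = 15 + w)
  }
  specs
}

#' Names of the packaged protocols
#' @return character vector of protocol names accepted by [paper_protocol()].
#' @export
protocol_names <- function() names(.protocol_specs())

#' Retrieve a packaged protocol by name
#'
#' The library covers the massed (90-min continuous) and spaced (5 x 5 min,
#' 15-min washes) trainings with their anisomycin/KT5720 variants, the
#' 90-min + 45-min-wash + 5-min test-pulse recovery protocols, the
#' 25-min-KT5720-then-KT5720+anisomycin protocol probing AD decay, the
#' two-pulse protocols with 5/10/15/30/45-min washes, the 3 x 15-min protocols
#' with 15- or 25-min washes, and the two-pulse 130-min-wash control.
#'
#' @param name protocol name; see [protocol_names()].
#' @return a `stimulus_protocol` object.
#' @export
paper_protocol <- function(name) {
  specs <- .protocol_specs()
  if (!name %in% names(specs))
    stop("unknown protocol '", name, "'; available: ",
         paste(names(specs), collapse = ", "))
  s <- specs[[name]]
  build_protocol(pulses = s$pulses, aniso_windows = s$aniso,
                 kt_windows = s$kt, duration = s$duration, name = name)
}

#' Protocol inputs at a time point
#'
#' Piecewise-constant lookup under the half-open interval convention
#' `[start, end)`.
#'
#' @param protocol a `stimulus_protocol`.
#' @param t time in minutes, within `[0, duration]`.
#' @return list with `fiveHT` (molar), `anisomycin`, `kt5720` (logical).
#' @export
inputs_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (length(t) != 1L || t < 0 || t > protocol$duration)
    stop("t = ", t, " outside protocol range [0, ", protocol$duration, "]")
  inw <- function(w) nrow(w) > 0 && any(t >= w$start & t < w$end)
  list(fiveHT = if (inw(protocol$pulses)) protocol$fiveHT else 0,
       anisomycin = inw(protocol$aniso),
       kt5720 = inw(protocol$kt))
}

# Inputs sampled on the solver grid: element i holds the value on
# [t_i, t_{i+1}). Times beyond the protocol duration are silently "all off".
.grid_inputs <- function(protocol, dt, n) {
  t <- (seq_len(n) - 1L) * dt
  inw <- function(w) {
    out <- logical(n)
    for (i in seq_len(nrow(w)))
      out <- out | (t >= w$start[i] - 1e-9 & t < w$end[i] - 1e-9)
    out
  }
  list(fiveHT = ifelse(inw(protocol$pulses), protocol$fiveHT, 0),
       aniso = inw(protocol$aniso),
       kt = inw(protocol$kt))
}

# Event times that the solver grid must hit exactly.
.event_times <- function(protocol) {
  sort(unique(c(protocol$pulses$start, protocol$pulses$end,
                protocol$aniso$start, protocol$aniso$end,
                protocol$kt$start, protocol$kt$end)))
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol> ", x$name, " (", x$duration, " min)\n", sep = "")
  fmt <- function(w) if (nrow(w) == 0) "none" else
    paste(sprintf("[%g, %g)", w$start, w$end), collapse = " ")
  cat("  5HT ", format(x$fiveHT * 1e6), " uM: ", fmt(x$pulses), "\n", sep = "")
  cat("  anisomycin: ", fmt(x$aniso), "\n", sep = "")
  cat("  KT5720: ", fmt(x$kt), "\n", sep = "")
  invisible(x)
}

#' Serialize a protocol to a plain list / rebuild it
#'
#' `protocol_to_list()` produces a plain-list form suitable for YAML/JSON;
#' `protocol_from_list()` rebuilds (and re-validates) the protocol.
#' `write_protocol()`/`read_protocol()` round-trip through a YAML file.
#'
#' @param protocol a `stimulus_protocol`.
#' @param x plain list as produced by `protocol_to_list()`.
#' @param file YAML file path.
#' @export
protocol_to_list <- function(protocol) {
  w2l <- function(w) lapply(seq_len(nrow(w)),
                            function(i) list(start = w$start[i], end = w$end[i]))
  list(name = protocol$name, duration = protocol$duration,
       fiveHT = protocol$fiveHT, pulses = w2l(protocol$pulses),
       aniso = w2l(protocol$aniso), kt = w2l(protocol$kt))
}

#' @rdname protocol_to_list
#' @export
protocol_from_list <- function(x) {
  l2w <- function(l) {
    if (length(l) == 0) return(NULL)
    data.frame(start = vapply(l, function(e) as.numeric(e$start), 0),
               end = vapply(l, function(e) as.numeric(e$end), 0))
  }
  build_protocol(pulses = l2w(x$pulses), fiveHT = as.numeric(x$fiveHT),
                 aniso_windows = l2w(x$aniso), kt_windows = l2w(x$kt),
                 duration = as.numeric(x$duration), name = x$name)
}

#' @rdname protocol_to_list
#' @export
write_protocol <- function(protocol, file) {
  yaml::write_yaml(protocol_to_list(protocol), file)
  invisible(file)
}

#' @rdname protocol_to_list
#' @export
read_protocol <- function(file) protocol_from_list(yaml::read_yaml(file))
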