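# Translocation readouts: the measured quantity is the membrane/cytosol
# intensity ratio, normalized to the first post-5HT measurement ("post 5HT
# #1"), which in the model is the translocation signal (DAG) at the 5-min
# point of the first pulse.

#' Reference ("post 5HT #1") time of a protocol
#'
#' The end of the first 5-min exposure window: first pulse start + 5 min for
#' pulses of at least 5 min (the 5-min time point of a longer, e.g. 90-min,
#' pulse), or the pulse end for shorter pulses.
#'
#' @param protocol a `stimulus_protocol` with at least one pulse.
#' @return time in minutes.
#' @export
reference_time <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (nrow(protocol$pulses) == 0)
    stop("protocol '", protocol$name, "' has no 5HT pulses")
  s <- protocol$pulses$start[1]
  e <- protocol$pulses$end[1]
  s + min(5, e - s)
}

#' Default measurement schedule of a protocol
#'
#' Emulates the imaging cadence: samples every 5 min within each pulse
#' (counted from pulse onset), so 5-min pulses are sampled at their ends and
#' longer pulses at 5, 10, ... min. Short pulses (< 5 min) are sampled at
#' their end.
#'
#' @param protocol a `stimulus_protocol`.
#' @return increasing vector of sample times in minutes.
#' @export
default_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  out <- unlist(lapply(seq_len(nrow(protocol$pulses)), function(i) {
    s <- protocol$pulses$start[i]
    e <- protocol$pulses$end[i]
    if (e - s >= 5) seq(s + 5, e, by = 5) else e
  }))
  sort(unique(out))
}

#' Normalized translocation readout
#'
#' Samples the translocation signal at the scheduled times and divides by its
#' value at the protocol's reference time ([reference_time()]), so the
#' reference sample maps to exactly 1.
#'
#' @param trace a `translocation_trace`.
#' @param schedule sample times (minutes); defaults to
#'   [default_schedule()] of the trace's protocol.
#' @return data.frame with columns `time` and `value`.
#' @export
normalized_translocation <- function(trace, schedule = NULL) {
  stopifnot(inherits(trace, "translocation_trace"))
  if (is.null(schedule)) schedule <- default_schedule(trace$protocol)
  t_ref <- reference_time(trace$protocol)
  ref <- trace_value(trace, t_ref)
  if (!is.finite(ref) || ref <= 0)
    stop("normalization error: reference translocation at t = ", t_ref,
         " min is ", ref)
  data.frame(time = schedule,
             value = trace_value(trace, schedule) / ref)
}

#' Wash-desensitization ratio
#'
#' Translocation at the 5-min point of pulse `k + 1` divided by translocation
#' at the 15-min point of pulse `k`; quantifies the desensitization occurring
#' during the intervening wash. Requires pulse `k` of length >= 15 min and
#' pulse `k + 1` of length >= 5 min.
#'
#' @param trace a `translocation_trace`.
#' @param protocol protocol to take pulse times from; defaults to the trace's.
#' @param k index of the earlier pulse.
#' @return scalar ratio.
#' @export
wash_desens_ratio <- function(trace, protocol = trace$protocol, k) {
  stopifnot(inherits(trace, "translocation_trace"))
  p <- protocol$pulses
  if (k < 1 || k + 1 > nrow(p))
    stop("protocol '", protocol$name, "' has no pulse pair (", k, ", ",
         k + 1, ")")
  if (p$end[k] - p$start[k] < 15)
    stop("pulse ", k, " shorter than 15 min")
  if (p$end[k + 1] - p$start[k + 1] < 5)
    stop("pulse ", k + 1, " shorter than 5 min")
  trace_value(trace, p$start[k + 1] + 5) / trace_value(trace, p$start[k] + 15)
}

#' Write a normalized readout as CSV
#'
#' @param readout data.frame from [normalized_translocation()].
#' @param file CSV path.
#' @export
write_readout <- function(readout, file) {
  utils::write.csv(readout, file, row.names = FALSE)
  invisible(file)
}
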