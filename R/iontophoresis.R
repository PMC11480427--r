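#' Microiontophoretic ejection epoch
#'
#' One ejection window overlaid on a pyramidal-neuron recording: the agent
#' (5-HT, NE, or the background excitant quisqualate), the onset/offset of
#' the ejection current, and the current in nA (20 nA is the conventional
#' test current for 5-HT and NE).
#'
#' @param ejection_onset,ejection_offset Seconds; `offset > onset`.
#' @param current Ejection current in nA, positive.
#' @param agent `"5HT"`, `"NE"` or `"quisqualate"`.
#' @return A list of class `ionto_epoch`.
#' @export
ionto_epoch <- function(ejection_onset, ejection_offset, current = 20,
                        agent = c("5HT", "NE", "quisqualate")) {
  agent <- match.arg(agent)
  stopifnot(ejection_offset > ejection_onset, current > 0)
  structure(list(ejection_onset = as.numeric(ejection_onset),
                 ejection_offset = as.numeric(ejection_offset),
                 current = as.numeric(current), agent = agent),
            class = "ionto_epoch")
}

#' Binned firing-rate trace
#'
#' Histogram of spike times over uniform bins spanning the recording epoch;
#' a trailing partial bin is dropped. Returned rates are counts divided by
#' the bin width.
#'
#' @param train A [spike_train()].
#' @param bin_width Bin width in seconds.
#' @return A list of class `rate_trace`: `bin_edges`, `bin_centers`,
#'   `counts`, `rate` (Hz), `bin_width`.
#' @export
bin_rate <- function(train, bin_width) {
  stopifnot(inherits(train, "spike_train"), bin_width > 0)
  dur <- epoch_duration(train)
  if (bin_width >= dur) stop("bin_width must be smaller than the epoch", call. = FALSE)
  n_bins <- floor(dur / bin_width)
  edges <- train$epoch_start + bin_width * (0:n_bins)
  counts <- if (length(train$times)) {
    # right-open bins [e_i, e_{i+1}); spikes beyond the last full bin dropped
    tabulate(findInterval(train$times, edges, rightmost.closed = FALSE,
                          left.open = FALSE), nbins = n_bins + 1L)[seq_len(n_bins)]
  } else rep(0L, n_bins)
  structure(list(bin_edges = edges,
                 bin_centers = edges[-length(edges)] + bin_width / 2,
                 counts = as.integer(counts),
                 rate = counts / bin_width,
                 bin_width = bin_width),
            class = "rate_trace")
}

# 3-bin centered moving average (ends padded by replication)
smooth3 <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  xs <- as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2))
  xs[1] <- mean(x[1:2]); xs[n] <- mean(x[(n - 1):n])
  xs
}

# shared baseline machinery: mean rate over bins whose centers fall in the
# baseline window immediately preceding the ejection onset
ionto_baseline <- function(trace, epoch, baseline_window) {
  in_base <- trace$bin_centers >= epoch$ejection_onset - baseline_window &
    trace$bin_centers < epoch$ejection_onset
  if (!any(in_base)) stop("baseline window contains no complete bin", call. = FALSE)
  baseline <- mean(trace$rate[in_base])
  if (baseline <= 0) stop("baseline firing rate is zero; RT50/IT50 undefined", call. = FALSE)
  baseline
}

# first index where `cross(rate, thr)` is TRUE among bins with center >= t0;
# returns interpolated time (relative to t0) of the threshold crossing
first_crossing <- function(trace, rate, t0, thr, direction = c("up", "down")) {
  direction <- match.arg(direction)
  ok <- if (direction == "up") rate >= thr else rate <= thr
  cand <- which(ok & trace$bin_centers >= t0)
  if (!length(cand)) return(NA_real_)
  k <- cand[1]
  if (k == 1L || trace$bin_centers[k - 1L] < t0) {
    return(0)  # already past threshold in the first usable bin
  }
  r0 <- rate[k - 1L]; r1 <- rate[k]
  t_prev <- trace$bin_centers[k - 1L]; t_this <- trace$bin_centers[k]
  tcross <- if (r1 == r0) t_this else t_prev + (thr - r0) / (r1 - r0) * (t_this - t_prev)
  max(0, tcross - t0)
}

#' RT50: recovery time after iontophoretic ejection
#'
#' Time in seconds from the cessation of a microiontophoretic 5-HT or NE
#' ejection to 50% recovery of the pre-ejection firing rate — an in vivo
#' index of reuptake-transporter activity (slower recovery = less reuptake).
#' The binned rate is compared against half the baseline rate; the first
#' post-offset crossing is located with linear interpolation between the
#' bracketing bin centers. With `smooth = TRUE` a 3-bin moving average is
#' applied to the rate before the crossing search, which suppresses the
#' early-triggering that single noisy bins cause on slow recovery ramps (see
#' the methods vignette); the baseline is always computed from raw bins.
#'
#' @param train A pyramidal-neuron [spike_train()].
#' @param epoch An [ionto_epoch()].
#' @param baseline_window Seconds of pre-ejection baseline (default 60).
#' @param bin_width Bin width in seconds (default 2).
#' @param smooth Apply 3-bin moving-average smoothing before the crossing
#'   search (default `FALSE`).
#' @return Recovery time in seconds; 0 if the first post-offset bin is
#'   already at or above 50% of baseline; `NA` (with attribute
#'   `recovered = FALSE`) if 50% is never reached within the epoch.
#' @export
rt50 <- function(train, epoch, baseline_window = 60, bin_width = 2, smooth = FALSE) {
  stopifnot(inherits(epoch, "ionto_epoch"))
  if (epoch$ejection_onset - baseline_window < train$epoch_start) {
    stop("baseline window extends before the recording epoch", call. = FALSE)
  }
  trace <- bin_rate(train, bin_width)
  baseline <- ionto_baseline(trace, epoch, baseline_window)
  rate <- if (smooth) smooth3(trace$rate) else trace$rate
  t <- first_crossing(trace, rate, epoch$ejection_offset, 0.5 * baseline, "up")
  if (is.na(t)) {
    t <- NA_real_
    attr(t, "recovered") <- FALSE
  }
  t
}

#' IT50: charge to 50% inhibition
#'
#' The ejection current (nA) multiplied by the time (s) needed to reduce the
#' spontaneous firing of a pyramidal neuron to 50% of baseline, in
#' nanocoulombs — an index of postsynaptic receptor sensitivity (smaller =
#' more sensitive). Crossing detection mirrors [rt50()] but runs downward
#' from the ejection onset.
#'
#' @inheritParams rt50
#' @return Charge in nC; `NA` with attribute `reached = FALSE` if firing
#'   never falls to 50% of baseline during the ejection.
#' @export
it50 <- function(train, epoch, baseline_window = 60, bin_width = 2, smooth = FALSE) {
  stopifnot(inherits(epoch, "ionto_epoch"))
  trace <- bin_rate(train, bin_width)
  baseline <- ionto_baseline(trace, epoch, baseline_window)
  rate <- if (smooth) smooth3(trace$rate) else trace$rate
  # only crossings during the ejection window count
  t <- first_crossing(trace, rate, epoch$ejection_onset, 0.5 * baseline, "down")
  if (!is.na(t) &&
      epoch$ejection_onset + t > epoch$ejection_offset) t <- NA_real_
  if (is.na(t)) {
    out <- NA_real_
    attr(out, "reached") <- FALSE
    return(out)
  }
  epoch$current * t
}
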