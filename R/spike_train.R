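#' Spike train container
#'
#' A `spike_train` holds the ordered action-potential times of one neuron over
#' an explicit recording epoch, together with its cell-type label. Epoch
#' bounds are stored explicitly (never inferred from the spikes) so that
#' silent neurons remain representable — silence is informative when counting
#' spontaneously active cells. Times are snapped to microsecond resolution and
#' must be strictly increasing; coincident events are rejected.
#'
#' @param times Numeric vector of spike times in seconds, strictly increasing.
#' @param epoch_start,epoch_end Recording epoch bounds in seconds
#'   (`epoch_end > epoch_start`); all times must lie inside the closed epoch.
#' @param neuron_type One of `"DA"`, `"5HT"`, `"NE"`, `"PYR"` (ventral
#'   tegmental dopamine, dorsal raphe serotonin, locus coeruleus
#'   norepinephrine, hippocampal CA3 pyramidal).
#' @param neuron_id,rat_id Opaque identifiers (coerced to character).
#'
#' @return An object of class `spike_train`.
#' @examples
#' st <- spike_train(c(0.1, 0.5, 1.2), 0, 2, "DA", "n1", "r1")
#' n_spikes(st)
#' @export
spike_train <- function(times, epoch_start, epoch_end,
                        neuron_type = c("DA", "5HT", "NE", "PYR"),
                        neuron_id = "n1", rat_id = "r1") {
  neuron_type <- match.arg(neuron_type)
  stopifnot(is.numeric(times), length(epoch_start) == 1L, length(epoch_end) == 1L)
  if (!is.finite(epoch_start) || !is.finite(epoch_end) || epoch_end <= epoch_start) {
    stop("epoch_end must be greater than epoch_start", call. = FALSE)
  }
  times <- round(as.numeric(times), 6)  # microsecond resolution
  if (anyNA(times)) stop("spike times must be finite", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("spike times must be strictly increasing (duplicate or unsorted events)",
         call. = FALSE)
  }
  if (length(times) && (times[1] < epoch_start || times[length(times)] > epoch_end)) {
    stop("spike times must lie within [epoch_start, epoch_end]", call. = FALSE)
  }
  structure(
    list(times = times,
         epoch_start = as.numeric(epoch_start),
         epoch_end = as.numeric(epoch_end),
         neuron_type = neuron_type,
         neuron_id = as.character(neuron_id),
         rat_id = as.character(rat_id)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s neuron %s (rat %s): %d spikes over [%g, %g] s (%.2f Hz)\n",
              x$neuron_type, x$neuron_id, x$rat_id, length(x$times),
              x$epoch_start, x$epoch_end, mean_firing_rate(x)))
  invisible(x)
}

#' Number of spikes in a train
#' @param train A [spike_train()].
#' @return Integer spike count.
#' @export
n_spikes <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  length(train$times)
}

#' Epoch duration in seconds
#' @param train A [spike_train()].
#' @return Numeric scalar, `epoch_end - epoch_start`.
#' @export
epoch_duration <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  train$epoch_end - train$epoch_start
}

#' Interspike intervals
#'
#' Consecutive differences of the spike times, in seconds. A train with fewer
#' than two spikes has no intervals and yields a zero-length vector (this is
#' the empty-result signal, not an error).
#'
#' @param train A [spike_train()].
#' @return Numeric vector of length `n_spikes(train) - 1` (or 0).
#' @examples
#' interspike_intervals(spike_train(c(0, 0.5, 1), 0, 2, "DA"))
#' @export
interspike_intervals <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$times) < 2L) return(numeric(0))
  diff(train$times)
}

#' Mean firing rate over the recording epoch
#'
#' Spike count divided by the full epoch duration. The full epoch (not the
#' first-to-last spike span) is used so that leading/trailing silence lowers
#' the rate, consistent with how spontaneous activity is assessed.
#'
#' @param train A [spike_train()].
#' @return Firing rate in Hz; 0 for an empty train.
#' @export
mean_firing_rate <- function(train) {
  dur <- epoch_duration(train)
  if (dur <= 0) stop("epoch has zero duration", call. = FALSE)
  n_spikes(train) / dur
}

#' Cell-type analysis parameters
#'
#' Two-threshold ISI burst criteria and the physiological firing-rate window
#' used to classify a unit as spontaneously active. Defaults follow the
#' standard in vivo identification criteria: burst onset at ISI < 0.08 s and
#' termination at ISI > 0.16 s for DA and NE neurons, onset = termination =
#' 0.01 s for 5-HT neurons; rate windows 2-10 Hz (DA), 0.5-2.5 Hz (5-HT),
#' 0.5-5 Hz (NE) and 10-15 Hz for quisqualate-driven CA3 pyramidal cells.
#' Pyramidal neurons are not subjected to burst analysis (thresholds `NA`).
#'
#' @param neuron_type One of `"DA"`, `"5HT"`, `"NE"`, `"PYR"`.
#' @param burst_onset_isi,burst_termination_isi Override thresholds (seconds);
#'   `burst_onset_isi <= burst_termination_isi` is enforced.
#' @param physiological_rate_range Length-2 numeric, Hz, closed interval.
#' @return A list of class `neuron_type_params`.
#' @examples
#' neuron_type_params("DA")
#' @export
neuron_type_params <- function(neuron_type = c("DA", "5HT", "NE", "PYR"),
                               burst_onset_isi = NULL,
                               burst_termination_isi = NULL,
                               physiological_rate_range = NULL) {
  neuron_type <- match.arg(neuron_type)
  defaults <- list(
    DA   = list(onset = 0.08, term = 0.16, range = c(2, 10)),
    `5HT` = list(onset = 0.01, term = 0.01, range = c(0.5, 2.5)),
    NE   = list(onset = 0.08, term = 0.16, range = c(0.5, 5)),
    PYR  = list(onset = NA_real_, term = NA_real_, range = c(10, 15))
  )[[neuron_type]]
  onset <- if (is.null(burst_onset_isi)) defaults$onset else burst_onset_isi
  term <- if (is.null(burst_termination_isi)) defaults$term else burst_termination_isi
  rng <- if (is.null(physiological_rate_range)) defaults$range else physiological_rate_range
  if (!anyNA(c(onset, term)) && onset > term) {
    stop("burst_onset_isi must not exceed burst_termination_isi", call. = FALSE)
  }
  stopifnot(length(rng) == 2L, rng[1] <= rng[2])
  structure(
    list(neuron_type = neuron_type,
         burst_onset_isi = onset,
         burst_termination_isi = term,
         physiological_rate_range = as.numeric(rng)),
    class = "neuron_type_params"
  )
}
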