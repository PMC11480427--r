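#' Electrode-track grid of spontaneously active neuron counts
#'
#' One stereotaxic grid per rat: the number of spontaneously active neurons
#' encountered on each electrode descent (track). The standard protocol uses
#' 6-9 tracks per rat; counts outside that range are accepted with a warning.
#' Tracks are treated as exchangeable counts (no electrode geometry).
#'
#' @param rat_id Identifier.
#' @param neurons_per_track Non-negative integer vector, one entry per track.
#' @return A list of class `track_grid`.
#' @export
track_grid <- function(rat_id, neurons_per_track) {
  stopifnot(is.numeric(neurons_per_track), length(neurons_per_track) >= 1L)
  if (any(neurons_per_track < 0) || any(neurons_per_track != round(neurons_per_track))) {
    stop("neurons_per_track must be non-negative integers", call. = FALSE)
  }
  k <- length(neurons_per_track)
  if (k < 6 || k > 9) {
    warning(sprintf("rat %s: %d tracks is outside the usual 6-9 track grid", rat_id, k))
  }
  structure(list(rat_id = as.character(rat_id),
                 track_count = k,
                 neurons_per_track = as.integer(neurons_per_track)),
            class = "track_grid")
}

#' Population activity: spontaneously active neurons per track
#'
#' The arithmetic mean of the per-track counts of one rat's grid — the
#' standard index of how many cells of a population are spontaneously firing.
#'
#' @param grid A [track_grid()].
#' @return Mean neurons per track (numeric scalar).
#' @examples
#' population_activity(track_grid("r1", c(3, 4, 5, 4, 4, 4)))  # 4
#' @export
population_activity <- function(grid) {
  stopifnot(inherits(grid, "track_grid"))
  if (grid$track_count < 1L) stop("grid has no tracks", call. = FALSE)
  mean(grid$neurons_per_track)
}

#' Is a unit spontaneously active?
#'
#' Rate criterion only: the mean firing rate must fall inside the cell type's
#' physiological window (closed interval, so boundary rates count). Waveform
#' criteria used for online identification are outside the scope of this
#' package.
#'
#' @param train A [spike_train()].
#' @param params A [neuron_type_params()]; defaults to the train's type.
#' @return Logical scalar.
#' @export
classify_spontaneously_active <- function(train,
                                          params = neuron_type_params(train$neuron_type)) {
  stopifnot(inherits(params, "neuron_type_params"))
  r <- mean_firing_rate(train)
  rng <- params$physiological_rate_range
  r >= rng[1] && r <= rng[2]
}
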