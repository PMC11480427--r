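#' Two-threshold ISI burst detection
#'
#' Scans the interspike intervals left to right. A burst opens at the first
#' ISI strictly below the onset threshold (the pair of spikes bounding that
#' ISI are the first two burst spikes); while open, each subsequent spike
#' joins the burst as long as its ISI is at or below the termination
#' threshold; the first ISI strictly above the termination threshold closes
#' the burst, after which scanning for a new onset resumes. A burst still
#' open at the last spike closes there. ISIs in the half-open band
#' `[onset, termination]` therefore extend but never start a burst. For 5-HT
#' neurons onset and termination coincide at 0.01 s, so the band is empty and
#' a burst is simply a maximal run of ISIs below 0.01 s.
#'
#' @param train A [spike_train()].
#' @param params A [neuron_type_params()] for the train's cell type; defaults
#'   to `neuron_type_params(train$neuron_type)`.
#' @return A list of class `burst_result` with elements `bursts` (data frame
#'   with columns `start_index`, `end_index`, `n_spikes`; 1-based spike
#'   indices), `pct_spikes_in_burst`, `has_burst`, `bursts_per_minute`,
#'   and `n_spikes_total`.
#' @examples
#' st <- spike_train(c(0, 0.05, 0.10, 0.50, 1.00), 0, 2, "DA")
#' detect_bursts(st)$pct_spikes_in_burst  # 60
#' @export
detect_bursts <- function(train, params = neuron_type_params(train$neuron_type)) {
  stopifnot(inherits(train, "spike_train"), inherits(params, "neuron_type_params"))
  onset <- params$burst_onset_isi
  term <- params$burst_termination_isi
  if (anyNA(c(onset, term))) {
    stop(sprintf("burst thresholds undefined for neuron type %s", params$neuron_type),
         call. = FALSE)
  }
  isi <- interspike_intervals(train)
  n <- length(train$times)
  starts <- integer(0); ends <- integer(0)
  i <- 1L
  while (i <= length(isi)) {
    if (isi[i] < onset) {
      s <- i            # burst spikes s .. e+1 (spike indices s, ..., e + 1)
      e <- i
      while (e + 1L <= length(isi) && isi[e + 1L] <= term) e <- e + 1L
      starts <- c(starts, s)
      ends <- c(ends, e + 1L)  # spike index of last burst spike
      i <- e + 2L       # ISI e+1 closed the burst (or run out); resume after
    } else {
      i <- i + 1L
    }
  }
  bursts <- data.frame(start_index = starts, end_index = ends,
                       n_spikes = ends - starts + 1L)
  dur_min <- epoch_duration(train) / 60
  structure(
    list(bursts = bursts,
         pct_spikes_in_burst = if (n == 0L) 0 else 100 * sum(bursts$n_spikes) / n,
         has_burst = nrow(bursts) > 0L,
         bursts_per_minute = nrow(bursts) / dur_min,
         n_spikes_total = n),
    class = "burst_result"
  )
}

#' @export
print.burst_result <- function(x, ...) {
  cat(sprintf("<burst_result> %d bursts; %.1f%% of %d spikes in bursts\n",
              nrow(x$bursts), x$pct_spikes_in_burst, x$n_spikes_total))
  invisible(x)
}

#' Per-rat burst summaries
#'
#' Burst statistics are computed per neuron and then averaged within each rat
#' (never pooled across neurons), so each rat contributes one value to group
#' statistics. `pct_neurons_with_burst` is the percentage of a rat's neurons
#' showing at least one burst.
#'
#' @param results A list of `burst_result` objects, one per neuron.
#' @param rat_ids Character vector of the same length assigning each neuron
#'   to a rat.
#' @return A tibble with columns `rat_id`, `n_neurons`,
#'   `pct_spikes_in_burst` (mean over neurons) and `pct_neurons_with_burst`.
#' @export
burst_summary_by_rat <- function(results, rat_ids) {
  stopifnot(length(results) == length(rat_ids),
            all(vapply(results, inherits, logical(1), "burst_result")))
  if (!length(results)) {
    warning("no neurons supplied; returning empty summary")
    return(tibble::tibble(rat_id = character(), n_neurons = integer(),
                          pct_spikes_in_burst = numeric(),
                          pct_neurons_with_burst = numeric()))
  }
  df <- tibble::tibble(
    rat_id = as.character(rat_ids),
    pct = vapply(results, function(r) r$pct_spikes_in_burst, numeric(1)),
    has = vapply(results, function(r) r$has_burst, logical(1))
  )
  dplyr::summarise(
    dplyr::group_by(df, .data$rat_id),
    n_neurons = dplyr::n(),
    pct_spikes_in_burst = mean(.data$pct),
    pct_neurons_with_burst = 100 * mean(.data$has),
    .groups = "drop"
  )
}
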