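#' Intravenous antagonist dose event
#'
#' One systemic injection overlaid on a pyramidal-neuron recording, used for
#' tonic-activation (antagonist-disinhibition) analysis: WAY 100635
#' (5-HT1A antagonist, cumulative 25-100 ug/kg), prazosin (alpha-1
#' antagonist, 0.1 mg/kg), idazoxan (alpha-2 antagonist, 1 mg/kg), or a
#' saline control injection.
#'
#' @param time Injection time in seconds.
#' @param drug `"WAY100635"`, `"prazosin"`, `"idazoxan"` or `"saline"`.
#' @param dose Positive dose in the drug's units (`ug/kg` for WAY 100635,
#'   `mg/kg` otherwise); saline takes a nominal dose of 0 allowed.
#' @param cumulative_index Position within a cumulative dosing sequence
#'   (1-based; default 1).
#' @return A list of class `dose_event`.
#' @export
dose_event <- function(time, drug = c("WAY100635", "prazosin", "idazoxan", "saline"),
                       dose = 1, cumulative_index = 1L) {
  drug <- match.arg(drug)
  if (drug != "saline" && dose <= 0) stop("dose must be positive", call. = FALSE)
  structure(list(time = as.numeric(time), drug = drug, dose = as.numeric(dose),
                 cumulative_index = as.integer(cumulative_index)),
            class = "dose_event")
}

rate_in_window <- function(train, from, to) {
  stopifnot(to > from)
  sum(train$times >= from & train$times < to) / (to - from)
}

#' Percent change in firing after an antagonist dose
#'
#' `100 * (rate_response - rate_baseline) / rate_baseline`, where the
#' baseline rate is measured over `baseline_window` seconds ending at the
#' injection and the response rate over `response_window` seconds starting
#' `response_delay` seconds after it (the delay skips the injection
#' artifact and circulation time). A positive value is disinhibition — the
#' signature of tonic receptor activation by endogenous transmitter.
#'
#' @param train A pyramidal-neuron [spike_train()].
#' @param dose A [dose_event()].
#' @param baseline_window,response_window Seconds (defaults 60 and 60).
#' @param response_delay Seconds between injection and response window
#'   (default 30).
#' @param other_doses Optional list of other [dose_event()]s on the same
#'   record; windows overlapping any of them raise an error.
#' @return Percent change (numeric scalar).
#' @examples
#' # +40% disinhibition: 10 Hz baseline, 14 Hz response
#' @export
percent_change_after_dose <- function(train, dose, baseline_window = 60,
                                      response_window = 60, response_delay = 30,
                                      other_doses = list()) {
  stopifnot(inherits(train, "spike_train"), inherits(dose, "dose_event"))
  b0 <- dose$time - baseline_window
  r0 <- dose$time + response_delay
  r1 <- r0 + response_window
  if (b0 < train$epoch_start || r1 > train$epoch_end) {
    stop("analysis windows extend beyond the recording epoch", call. = FALSE)
  }
  for (d in other_doses) {
    if (d$time > b0 && d$time < r1 && d$time != dose$time) {
      stop(sprintf("analysis windows overlap another dose at t = %g s", d$time),
           call. = FALSE)
    }
  }
  baseline <- rate_in_window(train, b0, dose$time)
  if (baseline <= 0) stop("baseline firing rate is zero; percent change undefined",
                          call. = FALSE)
  response <- rate_in_window(train, r0, r1)
  100 * (response - baseline) / baseline
}

#' Cumulative dose-response curve of firing disinhibition
#'
#' Percent change in firing after each dose of a cumulative intravenous
#' regimen, every value referenced to the single pre-first-dose baseline
#' (not to the preceding dose's plateau), matching the "overall change"
#' semantics of cumulative antagonist challenges.
#'
#' @param train A pyramidal-neuron [spike_train()].
#' @param doses List of [dose_event()]s in increasing time order.
#' @param baseline_window Seconds of baseline before the first dose.
#' @param response_window,response_delay Per-dose response timing, seconds;
#'   `response_delay + response_window` must fit within each inter-dose
#'   interval.
#' @return A tibble with columns `cumulative_index`, `drug`, `dose`,
#'   `time`, `pct_change`.
#' @export
cumulative_dose_curve <- function(train, doses, baseline_window = 60,
                                  response_window = 60, response_delay = 30) {
  stopifnot(length(doses) >= 1L,
            all(vapply(doses, inherits, logical(1), "dose_event")))
  times <- vapply(doses, function(d) d$time, numeric(1))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("doses must be in strictly increasing time order", call. = FALSE)
  }
  b0 <- times[1] - baseline_window
  if (b0 < train$epoch_start) {
    stop("baseline window extends before the recording epoch", call. = FALSE)
  }
  baseline <- rate_in_window(train, b0, times[1])
  if (baseline <= 0) stop("baseline firing rate is zero; percent change undefined",
                          call. = FALSE)
  pct <- vapply(seq_along(doses), function(i) {
    r0 <- times[i] + response_delay
    r1 <- r0 + response_window
    if (i < length(doses) && r1 > times[i + 1]) {
      stop(sprintf("response window of dose %d overlaps the next dose", i),
           call. = FALSE)
    }
    if (r1 > train$epoch_end) {
      stop(sprintf("response window of dose %d extends beyond the epoch", i),
           call. = FALSE)
    }
    100 * (rate_in_window(train, r0, r1) - baseline) / baseline
  }, numeric(1))
  tibble::tibble(
    cumulative_index = vapply(doses, function(d) d$cumulative_index, integer(1)),
    drug = vapply(doses, function(d) d$drug, character(1)),
    dose = vapply(doses, function(d) d$dose, numeric(1)),
    time = times,
    pct_change = pct
  )
}
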