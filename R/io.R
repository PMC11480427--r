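#' Read spike trains from a fixture file
#'
#' Two plain-text dialects are supported. Format `"csv"` has one row per
#' spike with columns `rat_id, neuron_id, neuron_type, epoch_start,
#' epoch_end, spike_time` (header required); an empty train is encoded by a
#' single row with an empty `spike_time` field. Format `"json"` is an array
#' of per-train objects with a `times` array, used for nested experiment
#' bundles. Round-trips are lossless to microsecond precision.
#'
#' Validation failures (unsorted, duplicate, or out-of-epoch times) raise an
#' error naming the offending neuron.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @return A named list of [spike_train()] objects (names = neuron ids).
#' @seealso [write_spiketrains()]
#' @export
read_spiketrains <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    recs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    trains <- lapply(recs, function(r) {
      tr <- try(spike_train(unlist(r$times, use.names = FALSE) %||% numeric(0),
                            r$epoch_start, r$epoch_end, r$neuron_type,
                            r$neuron_id, r$rat_id), silent = TRUE)
      if (inherits(tr, "try-error")) {
        stop(sprintf("invalid spike train '%s': %s", r$neuron_id,
                     attr(tr, "condition")$message), call. = FALSE)
      }
      tr
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    needed <- c("rat_id", "neuron_id", "neuron_type", "epoch_start", "epoch_end", "spike_time")
    missing <- setdiff(needed, names(df))
    if (length(missing)) {
      stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    trains <- lapply(split(df, df$neuron_id), function(d) {
      times <- d$spike_time[!is.na(d$spike_time)]
      tr <- try(spike_train(times, d$epoch_start[1], d$epoch_end[1],
                            d$neuron_type[1], d$neuron_id[1], d$rat_id[1]),
                silent = TRUE)
      if (inherits(tr, "try-error")) {
        stop(sprintf("invalid spike train '%s': %s", d$neuron_id[1],
                     attr(tr, "condition")$message), call. = FALSE)
      }
      tr
    })
    # preserve file order of first appearance rather than split()'s sort
    trains <- trains[unique(df$neuron_id)]
  }
  names(trains) <- vapply(trains, function(t) t$neuron_id, character(1))
  trains
}

#' Write spike trains to a fixture file
#'
#' @param trains A list of [spike_train()] objects.
#' @inheritParams read_spiketrains
#' @return `path`, invisibly.
#' @export
write_spiketrains <- function(trains, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  stopifnot(all(vapply(trains, inherits, logical(1), "spike_train")))
  if (format == "json") {
    recs <- lapply(trains, function(t) {
      list(rat_id = t$rat_id, neuron_id = t$neuron_id, neuron_type = t$neuron_type,
           epoch_start = t$epoch_start, epoch_end = t$epoch_end,
           times = as.numeric(t$times))
    })
    jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- lapply(trains, function(t) {
      data.frame(rat_id = t$rat_id, neuron_id = t$neuron_id,
                 neuron_type = t$neuron_type,
                 epoch_start = t$epoch_start, epoch_end = t$epoch_end,
                 spike_time = if (length(t$times)) t$times else NA_real_)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
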