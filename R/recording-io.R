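#' @keywords internal
new_recording <- function(spikes, trials, units, config = NULL) {
  rec <- list(spikes = spikes, trials = trials, units = units)
  attr(rec, "config") <- config
  class(rec) <- "population_recording"
  rec
}

#' @export
print.population_recording <- function(x, ...) {
  cat("population_recording:",
      nrow(x$units), "units,",
      nrow(x$trials), "trials,",
      nrow(x$spikes), "spikes\n")
  cat("orientations:", paste(sort(unique(x$trials$orientation)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Write a population recording to CSV files
#'
#' Writes \code{spikes.csv}, \code{trials.csv} and \code{units.csv} under
#' \code{dir}, plus \code{config.json} when the recording carries a
#' generator configuration.
#'
#' @param rec a \code{population_recording}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "population_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(rec$spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(rec$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(rec$units, file.path(dir, "units.csv"), row.names = FALSE)
  cfg <- attr(rec, "config")
  if (!is.null(cfg)) {
    cfg$units <- NULL
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a population recording from CSV files
#'
#' Reads and validates the three-table CSV layout written by
#' [write_recording()].  Duplicate (trial, unit, time) rows are collapsed;
#' schema violations (orientation outside [0, 180), spike times outside the
#' half-open trial interval, unknown trial ids) abort with the offending row
#' index.
#'
#' @param dir directory holding \code{spikes.csv}, \code{trials.csv},
#'   \code{units.csv}.
#' @return a validated \code{population_recording}; the number of rows read
#'   and collapsed is attached as attribute \code{"load_report"}.
#' @export
load_recording <- function(dir) {
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"))
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  units <- utils::read.csv(file.path(dir, "units.csv"))
  need_s <- c("trial_id", "unit_id", "t_ms")
  need_t <- c("trial_id", "orientation", "stim_onset", "stim_duration",
              "trial_length")
  if (!all(need_s %in% names(spikes)))
    stop("spikes.csv: schema mismatch, need columns ",
         paste(need_s, collapse = ", "))
  if (!all(need_t %in% names(trials)))
    stop("trials.csv: schema mismatch, need columns ",
         paste(need_t, collapse = ", "))
  bad <- which(trials$orientation < 0 | trials$orientation >= 180)
  if (length(bad))
    stop("trials.csv row ", bad[1], ": orientation outside [0, 180)")
  n_raw <- nrow(spikes)
  if (n_raw) {
    m <- match(spikes$trial_id, trials$trial_id)
    if (anyNA(m))
      stop("spikes.csv row ", which(is.na(m))[1], ": unknown trial_id")
    len <- trials$trial_length[m]
    bad <- which(spikes$t_ms < 0 | spikes$t_ms >= len)
    if (length(bad))
      stop("spikes.csv row ", bad[1],
           ": spike time outside [0, trial_length)")
    dup <- duplicated(spikes[, need_s])
    spikes <- spikes[!dup, , drop = FALSE]
    o <- order(spikes$trial_id, spikes$unit_id, spikes$t_ms)
    spikes <- spikes[o, , drop = FALSE]
    rownames(spikes) <- NULL
  }
  rec <- new_recording(spikes, trials, units)
  attr(rec, "load_report") <- list(spike_rows = n_raw,
                                   collapsed = n_raw - nrow(spikes),
                                   trials = nrow(trials),
                                   units = nrow(units))
  rec
}

#' Per-trial spike times for one unit
#'
#' Extracts the ordered spike times of a unit on every trial of the given
#' orientation(s), optionally relative to a reference signal.  When a
#' reference is applied, spikes before it are excluded (spikes exactly at
#' the reference are kept); times stay in the trial clock.
#'
#' @param rec a \code{population_recording}.
#' @param unit_id the unit.
#' @param orientation orientation(s) to select; \code{NULL} for all trials.
#' @param reference \code{NULL} (no filtering), a scalar time, or a vector
#'   named by trial id / of length \code{nrow(rec$trials)} giving a per-trial
#'   reference; \code{NA} references drop the trial (no detected onset).
#' @return a list of sorted numeric vectors, one per trial, with attributes
#'   \code{trial_id} and \code{reference} (per retained trial).
#' @export
spike_view <- function(rec, unit_id, orientation = NULL, reference = NULL) {
  tr <- rec$trials
  if (!is.null(orientation)) tr <- tr[tr$orientation %in% orientation, ]
  ids <- tr$trial_id
  sp <- rec$spikes[rec$spikes$unit_id == unit_id &
                     rec$spikes$trial_id %in% ids, ]
  byt <- split(sp$t_ms, factor(sp$trial_id, levels = ids))
  byt <- lapply(byt, sort)
  ref <- rep(0, length(ids))
  if (!is.null(reference)) {
    if (length(reference) == 1L && is.null(names(reference))) {
      ref <- rep(reference, length(ids))
    } else {
      if (!is.null(names(reference))) {
        ref <- unname(reference[as.character(ids)])
      } else {
        stopifnot(length(reference) == nrow(rec$trials))
        ref <- reference[match(ids, rec$trials$trial_id)]
      }
    }
    keep <- !is.na(ref)
    byt <- byt[keep]; ids <- ids[keep]; ref <- ref[keep]
    byt <- mapply(function(v, r) v[v >= r], byt, ref, SIMPLIFY = FALSE)
  }
  structure(byt, trial_id = ids, reference = ref, class = "spike_view")
}

#' Time of the nth spike on every trial
#'
#' For each trial of a [spike_view()], the time of the nth spike after the
#' view's reference, or \code{NA} when fewer than \code{n} spikes occur.
#' Times are reported in the trial clock (not relative to the reference).
#'
#' @param view a \code{spike_view}.
#' @param n spike index, >= 1.
#' @return numeric vector, one entry per trial.
#' @export
nth_spike_times <- function(view, n) {
  stopifnot(n >= 1)
  vapply(view, function(v) if (length(v) >= n) v[n] else NA_real_,
         numeric(1))
}
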