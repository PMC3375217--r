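#' Two-group race to threshold (n-tWTA)
#'
#' Races two spike pools after a reference signal: the winner is the group
#' that fires its nth post-reference spike first.  If both nth spikes fall
#' at the same time, the group with more spikes in the time bin holding
#' that spike wins; a remaining tie is resolved uniformly at random.  If
#' neither group accumulates n spikes there is no decision (flagged;
#' callers score it as chance).
#'
#' @param spikes_a,spikes_b spike times of the two groups (trial clock).
#' @param reference reference time; spikes before it are ignored (spikes
#'   exactly at the reference are kept).
#' @param n decision threshold (spike count), >= 1.
#' @param bin_ms bin width used for tie evaluation (default 10, the
#'   estimation grid).
#' @return list with \code{winner} (1, 2 or NA), \code{time} (decision time
#'   in ms after the reference, NA if no decision), \code{tie} and
#'   \code{tie_path} ("bin_count", "random" or "none"),
#'   \code{no_decision}.
#' @export
race_two_groups <- function(spikes_a, spikes_b, reference = 0, n = 1,
                            bin_ms = 10) {
  stopifnot(n >= 1)
  a <- sort(spikes_a[spikes_a >= reference]) - reference
  b <- sort(spikes_b[spikes_b >= reference]) - reference
  ta <- if (length(a) >= n) a[n] else NA_real_
  tb <- if (length(b) >= n) b[n] else NA_real_
  if (is.na(ta) && is.na(tb))
    return(list(winner = NA_integer_, time = NA_real_, tie = FALSE,
                tie_path = "none", no_decision = TRUE))
  if (is.na(tb) || (!is.na(ta) && ta < tb))
    return(list(winner = 1L, time = ta, tie = FALSE, tie_path = "none",
                no_decision = FALSE))
  if (is.na(ta) || tb < ta)
    return(list(winner = 2L, time = tb, tie = FALSE, tie_path = "none",
                no_decision = FALSE))
  # identical nth-spike times: compare spike counts inside that bin
  bin <- ta %/% bin_ms
  ca <- sum(a %/% bin_ms == bin)
  cb <- sum(b %/% bin_ms == bin)
  if (ca != cb) {
    w <- if (ca > cb) 1L else 2L
    return(list(winner = w, time = if (w == 1L) ta else tb, tie = TRUE,
                tie_path = "bin_count", no_decision = FALSE))
  }
  w <- if (stats::runif(1) < 0.5) 1L else 2L
  list(winner = w, time = if (w == 1L) ta else tb, tie = TRUE,
       tie_path = "random", no_decision = FALSE)
}

#' Multi-group race to threshold
#'
#' Generalises the race to M labelled groups: the winner is the first group
#' to fire its nth spike after the reference.  Groups whose nth spikes fall
#' in the same (earliest) bin are resolved uniformly at random -- no
#' bin-count sub-rule, unlike the two-group race.  If no group reaches n
#' spikes, a uniformly random winner is returned and flagged.
#'
#' @param groups named list of spike-time vectors.
#' @param reference reference time (spikes before it ignored).
#' @param n decision threshold, >= 1.
#' @param bin_ms bin width defining "same time" (default 10).
#' @return list with \code{winner} (name), \code{time} (ms after reference,
#'   NA if no decision), \code{tie}, \code{no_decision}.
#' @export
race_multi <- function(groups, reference = 0, n = 1, bin_ms = 10) {
  stopifnot(length(groups) >= 2, n >= 1)
  labs <- names(groups)
  if (is.null(labs)) labs <- as.character(seq_along(groups))
  tn <- vapply(groups, function(s) {
    v <- s[s >= reference]
    if (length(v) < n) NA_real_ else sort(v)[n] - reference
  }, numeric(1))
  if (all(is.na(tn))) {
    w <- sample.int(length(groups), 1)
    return(list(winner = labs[w], time = NA_real_, tie = FALSE,
                no_decision = TRUE))
  }
  bins <- tn %/% bin_ms
  lead <- which(bins == min(bins, na.rm = TRUE))
  w <- if (length(lead) == 1L) lead else lead[sample.int(length(lead), 1)]
  list(winner = labs[w], time = unname(tn[w]), tie = length(lead) > 1L,
       no_decision = FALSE)
}

# fast vectorised two-group race over several n at once; returns winners
# (1/2/NA for no decision) and decision times. u is a vector of pre-drawn
# uniforms for random tie-breaks (one per n).
race_two_all_n <- function(rel_a, rel_b, n_vec, bin_ms, u) {
  ba <- rel_a %/% bin_ms
  bb <- rel_b %/% bin_ms
  winners <- rep(NA_integer_, length(n_vec))
  times <- rep(NA_real_, length(n_vec))
  for (j in seq_along(n_vec)) {
    n <- n_vec[j]
    ta <- if (length(rel_a) >= n) rel_a[n] else NA_real_
    tb <- if (length(rel_b) >= n) rel_b[n] else NA_real_
    if (is.na(ta) && is.na(tb)) next
    if (is.na(tb) || (!is.na(ta) && ta < tb)) {
      winners[j] <- 1L; times[j] <- ta
    } else if (is.na(ta) || tb < ta) {
      winners[j] <- 2L; times[j] <- tb
    } else {
      ca <- sum(ba == ba[n]); cb <- sum(bb == ba[n])
      w <- if (ca > cb) 1L else if (cb > ca) 2L else
        if (u[j] < 0.5) 1L else 2L
      winners[j] <- w; times[j] <- if (w == 1L) ta else tb
    }
  }
  list(winner = winners, time = times)
}
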