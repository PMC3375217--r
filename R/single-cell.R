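# restrict a recording to a set of trials
subset_trials <- function(rec, trial_ids) {
  new_recording(rec$spikes[rec$spikes$trial_id %in% trial_ids, ],
                rec$trials[rec$trials$trial_id %in% trial_ids, ],
                rec$units, config = attr(rec, "config"))
}

#' Build the per-stimulus inputs of the analytic race formulas
#'
#' From per-trial spike times (relative to a reference), estimates on a
#' fixed bin grid ending at \code{t_max}: the nth-spike density \code{f}
#' (mass per bin), and the truncation-state probabilities \code{pm[m+1] =
#' P(exactly m spikes in [0, t_max))} for m = 0..n-1.  By construction
#' \code{sum(f) + sum(pm) = 1}.
#'
#' @param rel_trials list of numeric vectors: spike times relative to the
#'   reference, one vector per trial (negatives are dropped).
#' @param n spike index.
#' @param t_max end of the grid (T0), ms.
#' @param bin_ms bin width, ms.
#' @return list of class \code{race_input}: \code{f}, \code{pm},
#'   \code{edges}, \code{n}, \code{bin_ms}, \code{t_max}, \code{K}.
#' @export
nth_spike_inputs <- function(rel_trials, n, t_max, bin_ms = 10) {
  stopifnot(n >= 1, t_max > 0)
  edges <- seq(0, t_max, by = bin_ms)
  nb <- length(edges) - 1L
  K <- length(rel_trials)
  tn <- rep(NA_real_, K)
  cnt <- integer(K)
  for (i in seq_len(K)) {
    v <- rel_trials[[i]]
    v <- sort(v[v >= 0 & v < t_max])
    cnt[i] <- length(v)
    if (length(v) >= n) tn[i] <- v[n]
  }
  f <- tabulate(findInterval(tn[!is.na(tn)], edges), nbins = nb) / K
  pm <- vapply(0:(n - 1L), function(m) mean(cnt == m), numeric(1))
  structure(list(f = f, pm = pm, edges = edges, n = n, bin_ms = bin_ms,
                 t_max = t_max, K = K), class = "race_input")
}

# P(Gamma(a, rate) < Gamma(b, rate)) for independent gammas with a common
# rate: merge the two Poisson processes; each event belongs to the first
# process with probability 1/2, and the first process finishes first iff at
# least a of the first a+b-1 merged events are its own.
gamma_race_prob <- function(a, b) {
  stats::pbinom(a - 1, a + b - 1, 0.5, lower.tail = FALSE)
}

#' Probability of correct 2AFC discrimination from nth-spike distributions
#'
#' Analytic probability that the response to the preferred stimulus wins
#' the race to the nth spike: the nth-spike density of the preferred
#' stimulus is multiplied by the probability that the other response has
#' not yet reached its nth spike, summed over bins; nth spikes landing in
#' the same bin are credited at chance (1/2); and the probability mass of
#' trials in which a response has not reached n spikes by \code{t_max}
#' is completed by spontaneous Poisson firing at rate \code{lambda}, so a
#' state pair (m1, m2) races Gamma(n-m1) against Gamma(n-m2) with the same
#' rate (which therefore cancels).  With \code{lambda = 0} the residual
#' mass cannot race and is resolved at chance; the result is then flagged
#' with attribute \code{"chance_tail"}.
#'
#' @param pref,other [nth_spike_inputs()] objects on a common grid (for the
#'   preferred and the other stimulus), or bare density vectors for n = 1.
#' @param lambda spontaneous rate, spikes/s.
#' @return probability of correct response.
#' @export
pc_nth_spike <- function(pref, other, lambda = 0) {
  if (!inherits(pref, "race_input"))
    pref <- structure(list(f = pref, pm = 1 - sum(pref), n = 1L),
                      class = "race_input")
  if (!inherits(other, "race_input"))
    other <- structure(list(f = other, pm = 1 - sum(other), n = 1L),
                       class = "race_input")
  stopifnot(pref$n == other$n, length(pref$f) == length(other$f))
  n <- pref$n
  f1 <- pref$f; f2 <- other$f
  F2 <- cumsum(f2)
  pc <- sum(f1 * (1 - F2)) + 0.5 * sum(f1 * f2)
  chance_tail <- FALSE
  s1 <- sum(pref$pm); s2 <- sum(other$pm)
  if (s1 > 0 && s2 > 0) {
    if (lambda > 0) {
      for (m1 in 0:(n - 1L)) for (m2 in 0:(n - 1L))
        pc <- pc + pref$pm[m1 + 1L] * other$pm[m2 + 1L] *
          gamma_race_prob(n - m1, n - m2)
    } else {
      pc <- pc + 0.5 * s1 * s2
      chance_tail <- TRUE
    }
  } else {
    # only one side can still complete: it always loses the tail race
    pc <- pc + 0
  }
  attr(pc, "chance_tail") <- chance_tail
  pc
}

#' @rdname pc_nth_spike
#' @export
pc_first_spike <- function(pref, other, lambda = 0) {
  if (inherits(pref, "race_input")) stopifnot(pref$n == 1L)
  pc_nth_spike(pref, other, lambda)
}

#' Probability of correct 2AFC discrimination from spike counts
#'
#' The standard all-pairs (area-under-ROC) estimator: the probability that
#' a count drawn from the preferred stimulus exceeds an independent count
#' drawn from the other stimulus, with half credit for equal counts.
#'
#' @param counts_pref,counts_other per-trial spike counts.
#' @return probability of correct response.
#' @export
pc_rate_code <- function(counts_pref, counts_other) {
  g <- outer(counts_pref, counts_other, ">")
  e <- outer(counts_pref, counts_other, "==")
  mean(g) + 0.5 * mean(e)
}

# E[min(Gamma(a, rate), Gamma(b, rate))], rate per ms
gamma_min_mean <- function(a, b, rate_ms) {
  f <- function(t) stats::pgamma(t, a, rate = rate_ms, lower.tail = FALSE) *
    stats::pgamma(t, b, rate = rate_ms, lower.tail = FALSE)
  stats::integrate(f, 0, Inf, rel.tol = 1e-8)$value
}

#' Mean decision time of the two-stimulus race
#'
#' Expectation of the earlier of the two nth-spike times under the same
#' binned-plus-Poisson-tail model as [pc_nth_spike()], using left bin
#' edges.  With \code{lambda = 0} the undecided tail mass is dropped and
#' the mean is conditional on a decision.
#'
#' @param pref,other [nth_spike_inputs()] objects on a common grid.
#' @param lambda spontaneous rate, spikes/s.
#' @return mean decision time, ms.
#' @export
mean_decision_time <- function(pref, other, lambda = 0) {
  stopifnot(inherits(pref, "race_input"), pref$n == other$n)
  f1 <- pref$f; f2 <- other$f
  F1 <- cumsum(f1); F2 <- cumsum(f2)
  p_bin <- f1 * (1 - F2) + f2 * (1 - F1) + f1 * f2
  lefts <- pref$edges[-length(pref$edges)]
  num <- sum(lefts * p_bin)
  mass <- sum(p_bin)
  n <- pref$n
  if (lambda > 0) {
    rate_ms <- lambda / 1000
    for (m1 in 0:(n - 1L)) for (m2 in 0:(n - 1L)) {
      w <- pref$pm[m1 + 1L] * other$pm[m2 + 1L]
      if (w > 0) {
        num <- num + w * (pref$t_max +
                            gamma_min_mean(n - m1, n - m2, rate_ms))
        mass <- mass + w
      }
    }
  }
  num / mass
}

#' Per-trial spike times relative to a reference
#'
#' Convenience extraction for the race formulas: one vector of
#' reference-relative spike times per trial of the requested orientation.
#' Trials with an undefined (NA) reference are dropped.
#'
#' @param rec a \code{population_recording}.
#' @param unit_id the unit.
#' @param orientation orientation(s); NULL for all trials.
#' @param reference as in [spike_view()]; default stimulus onset.
#' @return list of numeric vectors (times >= 0, ms after the reference).
#' @export
relative_spike_trials <- function(rec, unit_id, orientation = NULL,
                                  reference = NULL) {
  if (is.null(reference))
    reference <- stats::setNames(rec$trials$stim_onset,
                                 rec$trials$trial_id)
  v <- spike_view(rec, unit_id, orientation, reference)
  mapply(function(s, r) s - r, v, attr(v, "reference"), SIMPLIFY = FALSE)
}

#' Trial-resampled estimate of race accuracy
#'
#' Monte-Carlo companion of [pc_nth_spike()]: draws random trial pairs
#' (one response to each stimulus) and races them with
#' [race_two_groups()]; no-decision races score 1/2.
#'
#' @param rel_pref,rel_other lists of reference-relative spike-time
#'   vectors (one per trial), as from [relative_spike_trials()].
#' @param n decision threshold.
#' @param n_draws number of resampled trial pairs.
#' @param bin_ms race bin, ms.
#' @param seed seed.
#' @return fraction of races won by the preferred response.
#' @export
pc_race_replay <- function(rel_pref, rel_other, n = 1, n_draws = 20000,
                           bin_ms = 10, seed = 1L) {
  set.seed(seed)
  i <- sample.int(length(rel_pref), n_draws, replace = TRUE)
  j <- sample.int(length(rel_other), n_draws, replace = TRUE)
  correct <- numeric(n_draws)
  for (k in seq_len(n_draws)) {
    rr <- race_two_groups(rel_pref[[i[k]]], rel_other[[j[k]]],
                          reference = 0, n = n, bin_ms = bin_ms)
    correct[k] <- if (rr$no_decision) 0.5 else as.numeric(rr$winner == 1L)
  }
  mean(correct)
}

# nearest protocol orientation to phi (circular, period 180)
nearest_orientation <- function(phi, orients) {
  d <- abs(((orients - phi + 90) %% 180) - 90)
  orients[which.min(d)]
}

#' Single-cell neurometric curve
#'
#' Splits the trials of each orientation into a training and a test half
#' (seeded, stratified).  The training half fixes the latency-based
#' preferred orientation via the cosine fit; the test half yields, for each
#' orientation difference on the protocol grid, the probability of correct
#' 2AFC discrimination for the nth-spike readouts and the rate-code
#' comparator, together with mean decision times.  SEM is
#' sqrt(Pc(1-Pc)/K) with K the number of test trials.
#'
#' @param rec a \code{population_recording}.
#' @param unit_id the unit (must be latency-tuned).
#' @param n_values spike-readout thresholds (default 1:3).
#' @param include_rate include the spike-count comparator (default TRUE).
#' @param split_seed seed of the train/test partition.
#' @param bin_ms estimation bin, ms.
#' @param b_threshold_ms tuning threshold below which the unit is refused.
#' @return data frame with \code{delta_theta}, \code{readout}, \code{pc},
#'   \code{sem}, \code{decision_time}; the estimated preferred orientation
#'   is attached as attribute \code{"pref"}.
#' @export
neurometric_curve <- function(rec, unit_id, n_values = 1:3,
                              include_rate = TRUE, split_seed = 1L,
                              bin_ms = 10, b_threshold_ms = 15) {
  orients <- sort(unique(rec$trials$orientation))
  step <- min(diff(orients))
  t0 <- rec$trials$stim_duration[1] + 300
  set.seed(split_seed)
  train_ids <- unlist(lapply(orients, function(o) {
    ids <- rec$trials$trial_id[rec$trials$orientation == o]
    sample(ids, floor(length(ids) / 2))
  }))
  test_rec <- subset_trials(rec, setdiff(rec$trials$trial_id, train_ids))
  d_train <- estimate_nth_spike_distribution(subset_trials(rec, train_ids),
                                             unit_id, 1, bin_ms, t0)
  fit <- fit_cosine(d_train$orientations, level_curve(d_train))
  if (!fit$ok || is.na(fit$B) || fit$B <= b_threshold_ms)
    stop("unit ", unit_id, " is not latency-tuned (B = ",
         round(fit$B, 1), " ms); neurometric curve refused")
  pref <- nearest_orientation(fit$phi, orients)
  lambda <- unname(spontaneous_rate(rec, unit_id))

  rel_trials <- function(orientation)
    relative_spike_trials(test_rec, unit_id, orientation)
  counts_in <- function(rel) vapply(rel, function(v)
    sum(v >= 0 & v < t0), numeric(1))

  dgrid <- seq(0, 90, by = step)
  rel_pref <- rel_trials(pref)
  out <- list()
  for (dth in dgrid) {
    other_or <- (pref + dth) %% 180
    rel_other <- rel_trials(other_or)
    K <- min(length(rel_pref), length(rel_other))
    for (n in n_values) {
      ip <- nth_spike_inputs(rel_pref, n, t0, bin_ms)
      io <- nth_spike_inputs(rel_other, n, t0, bin_ms)
      pc <- as.numeric(pc_nth_spike(ip, io, lambda))
      out[[length(out) + 1L]] <- data.frame(
        delta_theta = dth, readout = paste0("n", n), pc = pc,
        sem = sqrt(pc * (1 - pc) / K),
        decision_time = mean_decision_time(ip, io, lambda))
    }
    if (include_rate) {
      pc <- pc_rate_code(counts_in(rel_pref), counts_in(rel_other))
      out[[length(out) + 1L]] <- data.frame(
        delta_theta = dth, readout = "rate", pc = pc,
        sem = sqrt(pc * (1 - pc) / K), decision_time = t0)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "pref") <- pref
  res
}
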