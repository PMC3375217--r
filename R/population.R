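#' Partition tuned units into orientation columns
#'
#' Divides units into M groups of equal orientation width 180/M degrees,
#' assigning each unit to the group whose centre is circularly nearest to
#' its latency-based preferred orientation (period 180).  Units exactly on
#' a boundary go to the lower-index group.  Empty groups are permitted.
#'
#' @param phi named vector of preferred orientations (degrees), names =
#'   unit ids; NA entries (untuned) are skipped.
#' @param M number of groups (>= 2).
#' @param anchor orientation of the first group centre (default 0); set to
#'   the stimulus orientation to centre one group on it.
#' @return list of class \code{column_partition}: \code{M}, \code{width},
#'   \code{centers}, and \code{assignment} (data frame unit_id, phi,
#'   column, center).
#' @export
build_columns <- function(phi, M = NULL, width = NULL, anchor = 0) {
  if (is.null(M)) {
    stopifnot(!is.null(width))
    M <- round(180 / width)
  }
  if (M < 2) stop("M must be >= 2")
  width <- 180 / M
  centers <- (anchor + (seq_len(M) - 1L) * width) %% 180
  keep <- !is.na(phi)
  p <- phi[keep]
  d <- abs(((outer(p, centers, "-") + 90) %% 180) - 90)
  col <- apply(d, 1, function(r) which(r <= min(r) + 1e-9)[1])
  structure(list(M = M, width = width, centers = centers,
                 assignment = data.frame(
                   unit_id = as.integer(names(p)), phi = unname(p),
                   column = col, center = centers[col])),
            class = "column_partition")
}

# per-(trial, unit) post-reference relative spike times for fast pooling:
# a list indexed [[trial]][[unit]] of sorted relative times
index_spikes <- function(rec, trial_ids, unit_ids, reference) {
  sp <- rec$spikes[rec$spikes$trial_id %in% trial_ids &
                     rec$spikes$unit_id %in% unit_ids, ]
  ref <- reference[as.character(sp$trial_id)]
  rel <- sp$t_ms - ref
  keep <- !is.na(rel) & rel >= 0
  sp <- sp[keep, ]; rel <- rel[keep]
  out <- vector("list", length(trial_ids))
  names(out) <- trial_ids
  byt <- split(data.frame(u = sp$unit_id, rel = rel),
               factor(sp$trial_id, levels = trial_ids))
  for (i in seq_along(out)) {
    d <- byt[[i]]
    l <- split(d$rel, factor(d$u, levels = unit_ids))
    out[[i]] <- lapply(l, sort)
  }
  out
}

pool_sorted <- function(lst, units) sort(unlist(lst[as.character(units)],
                                                use.names = FALSE))

#' Population neurometric: Pc as a function of column size and threshold
#'
#' For two columns of tuned units with preferred orientations matching two
#' stimulus orientations, replays every trial of those orientations: the
#' pooled spikes of an N-unit subset of each column race to n spikes after
#' the per-trial reference (normally the detected onset).  Correctness is
#' averaged over trials, then over random subset realizations (uniform
#' without replacement within a realization).  No-decision races score
#' chance (1/2); trials without a detected onset are excluded and counted.
#'
#' @param rec a \code{population_recording}.
#' @param units1,units2 unit ids of the two columns.
#' @param orient1,orient2 the two stimulus orientations (column centres).
#' @param N_grid subset sizes; entries exceeding a column size are skipped
#'   with a warning.
#' @param n_grid decision thresholds.
#' @param realizations subset realizations per N (default 1000).
#' @param reference per-trial reference times named by trial id (trial
#'   clock), e.g. from [detect_trial_onsets()]; NA = excluded trial.
#' @param bin_ms race bin, ms.
#' @param seed seed for subset sampling and tie-breaking.
#' @return data frame of class \code{population_neurometric} with columns
#'   \code{N}, \code{n}, \code{pc}, \code{sem}, \code{dt_mean},
#'   \code{dt_sem}; the excluded-trial fraction is attribute
#'   \code{"excluded_frac"}.
#' @export
population_neurometric <- function(rec, units1, units2, orient1, orient2,
                                   N_grid, n_grid = 1, realizations = 1000,
                                   reference, bin_ms = 10, seed = 1L) {
  stopifnot(length(units1) >= 1, length(units2) >= 1)
  tr <- rec$trials
  t1 <- tr$trial_id[tr$orientation == orient1]
  t2 <- tr$trial_id[tr$orientation == orient2]
  n_all <- length(t1) + length(t2)
  ok <- !is.na(reference[as.character(c(t1, t2))])
  excluded <- 1 - mean(ok)
  t1 <- t1[!is.na(reference[as.character(t1)])]
  t2 <- t2[!is.na(reference[as.character(t2)])]
  all_units <- c(units1, units2)
  idx <- index_spikes(rec, c(t1, t2), all_units, reference)
  trials <- c(t1, t2)
  pref_col <- rep(c(1L, 2L), c(length(t1), length(t2)))
  N_grid <- N_grid[N_grid >= 1]
  skip <- N_grid > min(length(units1), length(units2))
  if (any(skip)) {
    warning("skipping N > column size: ",
            paste(N_grid[skip], collapse = ", "))
    N_grid <- N_grid[!skip]
  }
  set.seed(seed)
  out <- expand.grid(N = N_grid, n = n_grid)
  acc <- matrix(0, nrow(out), realizations)
  dts <- vector("list", nrow(out))
  for (r in seq_len(realizations)) {
    # a permutation per column; prefixes give nested uniform subsets
    p1 <- units1[sample.int(length(units1))]
    p2 <- units2[sample.int(length(units2))]
    for (gi in seq_along(N_grid)) {
      N <- N_grid[gi]
      s1 <- p1[seq_len(N)]; s2 <- p2[seq_len(N)]
      correct <- matrix(NA_real_, length(trials), length(n_grid))
      dt <- matrix(NA_real_, length(trials), length(n_grid))
      for (ti in seq_along(trials)) {
        rel_a <- pool_sorted(idx[[ti]], s1)
        rel_b <- pool_sorted(idx[[ti]], s2)
        u <- stats::runif(length(n_grid))
        rr <- race_two_all_n(rel_a, rel_b, n_grid, bin_ms, u)
        w <- rr$winner
        correct[ti, ] <- ifelse(is.na(w), 0.5, as.numeric(w == pref_col[ti]))
        dt[ti, ] <- rr$time
      }
      for (ni in seq_along(n_grid)) {
        row <- which(out$N == N & out$n == n_grid[ni])
        acc[row, r] <- mean(correct[, ni])
        dts[[row]] <- c(dts[[row]], dt[, ni])
      }
    }
  }
  out$pc <- rowMeans(acc)
  out$sem <- sqrt(out$pc * (1 - out$pc) / length(trials))
  out$dt_mean <- vapply(dts, function(v) mean(v, na.rm = TRUE), numeric(1))
  out$dt_sem <- vapply(dts, function(v)
    stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))), numeric(1))
  attr(out, "excluded_frac") <- excluded
  class(out) <- c("population_neurometric", class(out))
  out
}

#' Optimal decision threshold per population size
#'
#' For each N, the n maximising Pc on the tested grid (ties to smaller n).
#'
#' @param pop a [population_neurometric()] result.
#' @return data frame with \code{N}, \code{n_opt}, \code{pc_opt}.
#' @export
optimal_n <- function(pop) {
  Ns <- sort(unique(pop$N))
  res <- data.frame(N = Ns, n_opt = NA_real_, pc_opt = NA_real_)
  for (i in seq_along(Ns)) {
    sub <- pop[pop$N == Ns[i], ]
    sub <- sub[order(sub$n), ]
    j <- which.max(sub$pc)  # first maximum: ties go to smaller n
    res$n_opt[i] <- sub$n[j]
    res$pc_opt[i] <- sub$pc[j]
  }
  res
}

#' Accuracy as a function of an artificial reference time
#'
#' Sweeps an imposed reference signal over a grid of times after stimulus
#' onset (spikes before the reference are ignored) and measures first-spike
#' tWTA accuracy for each population size, for comparison with the
#' internally detected onset.
#'
#' @param rec a \code{population_recording}.
#' @param units1,units2,orient1,orient2 as in [population_neurometric()].
#' @param N_grid subset sizes.
#' @param ref_times reference times, ms after stimulus onset (default
#'   0..120 in steps of 10).
#' @param realizations subset realizations (default 100).
#' @param n decision threshold (default 1).
#' @param detected optional per-trial detected onsets (trial clock) whose
#'   mean and SD are reported for overlay.
#' @param seed seed.
#' @return data frame with \code{t_ref}, \code{N}, \code{pc}, \code{sem};
#'   attributes \code{"onset_mean"} and \code{"onset_sd"} when
#'   \code{detected} is given.
#' @export
reference_sweep <- function(rec, units1, units2, orient1, orient2,
                            N_grid, ref_times = seq(0, 120, by = 10),
                            realizations = 100, n = 1, detected = NULL,
                            seed = 1L) {
  res <- list()
  for (t_ref in ref_times) {
    ref <- stats::setNames(rec$trials$stim_onset + t_ref,
                           rec$trials$trial_id)
    pop <- population_neurometric(rec, units1, units2, orient1, orient2,
                                  N_grid, n_grid = n,
                                  realizations = realizations,
                                  reference = ref, seed = seed)
    pop$t_ref <- t_ref
    res[[length(res) + 1L]] <- as.data.frame(pop)
  }
  out <- do.call(rbind, res)[, c("t_ref", "N", "pc", "sem")]
  if (!is.null(detected)) {
    rel <- detected - rec$trials$stim_onset[
      match(names(detected), rec$trials$trial_id)]
    attr(out, "onset_mean") <- mean(rel, na.rm = TRUE)
    attr(out, "onset_sd") <- stats::sd(rel, na.rm = TRUE)
  }
  out
}

# shuffle trial assignments independently per unit (within orientation),
# destroying inter-unit correlations; optionally shuffles a per-trial
# onset signal the same way (as its own "unit")
shuffle_recording <- function(rec, reference = NULL) {
  sp <- rec$spikes
  tr <- rec$trials
  new_ref <- reference
  for (o in unique(tr$orientation)) {
    ids <- tr$trial_id[tr$orientation == o]
    if (length(ids) < 2) next
    for (u in unique(sp$unit_id)) {
      rows <- which(sp$unit_id == u & sp$trial_id %in% ids)
      if (!length(rows)) next
      perm <- stats::setNames(ids[sample.int(length(ids))], ids)
      sp$trial_id[rows] <- unname(perm[as.character(sp$trial_id[rows])])
    }
    if (!is.null(reference)) {
      perm <- ids[sample.int(length(ids))]
      new_ref[as.character(ids)] <- reference[as.character(perm)]
    }
  }
  list(rec = new_recording(sp, tr, rec$units, config = attr(rec, "config")),
       reference = new_ref)
}

#' Shuffle analysis of latency correlations
#'
#' Measures the contribution of trial-to-trial inter-unit correlations to
#' decoding accuracy: Pc on the original simultaneous data minus the mean
#' Pc over datasets in which each unit's trials (and the onset signal) are
#' independently permuted within orientation.
#'
#' @inheritParams population_neurometric
#' @param n decision threshold (default 1).
#' @param n_shuffles number of shuffled replicates (default 50).
#' @return data frame with \code{N}, \code{pc_original},
#'   \code{pc_shuffled}, \code{delta_pc}, \code{se_shuffle} (SE of the
#'   shuffled mean).
#' @export
shuffle_analysis <- function(rec, units1, units2, orient1, orient2,
                             N_grid, n = 1, realizations = 100,
                             n_shuffles = 50, reference, seed = 1L) {
  orig <- population_neurometric(rec, units1, units2, orient1, orient2,
                                 N_grid, n_grid = n,
                                 realizations = realizations,
                                 reference = reference, seed = seed)
  shuf <- matrix(NA_real_, n_shuffles, length(orig$N))
  for (s in seq_len(n_shuffles)) {
    set.seed(seed + 1000L + s)
    sh <- shuffle_recording(rec, reference)
    # common random numbers: same subset realizations as the original
    ps <- population_neurometric(sh$rec, units1, units2, orient1, orient2,
                                 N_grid, n_grid = n,
                                 realizations = realizations,
                                 reference = sh$reference, seed = seed)
    shuf[s, ] <- ps$pc
  }
  data.frame(N = orig$N, pc_original = orig$pc,
             pc_shuffled = colMeans(shuf),
             delta_pc = orig$pc - colMeans(shuf),
             se_shuffle = apply(shuf, 2, stats::sd) / sqrt(n_shuffles))
}

#' Multi-alternative discrimination with the n-tWTA
#'
#' For every trial, all M orientation columns race to n spikes after the
#' per-trial reference; the decision is the centre of the winning column.
#' For each trial the partition is anchored so that one column is centred
#' on the stimulus orientation.  Reports the probability that the
#' stimulus-centred column wins and the distribution of signed circular
#' errors (winner centre minus stimulus, wrapped to (-90, 90]).
#'
#' @param rec a \code{population_recording}.
#' @param phi named vector of latency preferred orientations of the tuned
#'   units (names = unit ids).
#' @param M number of columns.
#' @param n decision threshold.
#' @param reference per-trial reference times named by trial id; NA trials
#'   are excluded.
#' @param bin_ms race bin, ms.
#' @param seed seed for random tie resolution.
#' @return list with \code{pc}, \code{errors} (signed degrees, one per
#'   trial), \code{n_trials}, \code{excluded_frac}, \code{chance} (1/M).
#' @export
multi_alternative <- function(rec, phi, M, n = 1, reference, bin_ms = 10,
                              seed = 1L) {
  tr <- rec$trials
  ref <- reference[as.character(tr$trial_id)]
  keep <- !is.na(ref)
  excluded <- 1 - mean(keep)
  trials <- tr$trial_id[keep]
  orients_by_trial <- tr$orientation[keep]
  ref <- ref[keep]
  unit_ids <- as.integer(names(phi)[!is.na(phi)])
  idx <- index_spikes(rec, trials,
                      unit_ids, stats::setNames(ref, trials))
  set.seed(seed)
  # partitions are anchored per distinct stimulus orientation
  parts <- list()
  for (o in unique(orients_by_trial)) {
    anchor <- o %% (180 / M)
    parts[[as.character(o)]] <- build_columns(phi, M, anchor = anchor)
  }
  err <- numeric(length(trials))
  correct <- logical(length(trials))
  for (i in seq_along(trials)) {
    o <- orients_by_trial[i]
    part <- parts[[as.character(o)]]
    asn <- part$assignment
    groups <- lapply(seq_len(part$M), function(ci)
      pool_sorted(idx[[i]], asn$unit_id[asn$column == ci]))
    names(groups) <- as.character(seq_len(part$M))
    rr <- race_multi(groups, reference = 0, n = n, bin_ms = bin_ms)
    win_center <- part$centers[as.integer(rr$winner)]
    e <- ((win_center - o + 90) %% 180) - 90
    if (e <= -90) e <- e + 180
    err[i] <- e
    target <- which.min(abs(((part$centers - o + 90) %% 180) - 90))
    correct[i] <- as.integer(rr$winner) == target
  }
  list(pc = mean(correct), errors = err, n_trials = length(trials),
       excluded_frac = excluded, chance = 1 / M)
}
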