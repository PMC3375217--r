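#' Normalized first-spike latencies
#'
#' Per-trial z-scores of a unit's first-spike latency for one orientation:
#' (t1 - mean)/SD over the trials where the unit fired at least one spike
#' inside the analysis window.  Undefined (all NA) when fewer than two
#' defined trials exist or the latencies are constant.
#'
#' @param rec a \code{population_recording}.
#' @param unit_id the unit.
#' @param orientation stimulus orientation.
#' @param t_max analysis window end, ms after stimulus onset (default
#'   stimulus duration + 300).
#' @return numeric vector of z-scores named by trial id (NA where no first
#'   spike).
#' @export
normalized_latencies <- function(rec, unit_id, orientation, t_max = NULL) {
  if (is.null(t_max)) t_max <- rec$trials$stim_duration[1] + 300
  v <- spike_view(rec, unit_id, orientation,
                  reference = stats::setNames(rec$trials$stim_onset,
                                              rec$trials$trial_id))
  t1 <- nth_spike_times(v, 1) - attr(v, "reference")
  t1[!is.na(t1) & t1 >= t_max] <- NA
  mu <- mean(t1, na.rm = TRUE)
  sdv <- stats::sd(t1, na.rm = TRUE)
  z <- if (sum(!is.na(t1)) < 2 || is.na(sdv) || sdv == 0)
    rep(NA_real_, length(t1)) else (t1 - mu) / sdv
  stats::setNames(z, attr(v, "trial_id"))
}

#' Pairwise first-spike latency correlations
#'
#' Pearson correlation of the trial-to-trial first-spike latencies of every
#' unit pair, computed separately for each stimulus orientation over the
#' trials in which both units fired.  The difference between the pair's
#' preferred orientations (circular, period 180) is attached when
#' \code{phi} is given.
#'
#' @param rec a \code{population_recording}.
#' @param unit_ids units to correlate (typically the tuned units).
#' @param phi optional named vector of preferred orientations.
#' @param min_trials minimum joint defined trials per coefficient
#'   (default 10).
#' @param t_max analysis window end, ms.
#' @return data frame with \code{unit_a}, \code{unit_b},
#'   \code{orientation}, \code{r}, \code{n_trials}, \code{dpo}.
#' @export
latency_correlations <- function(rec, unit_ids, phi = NULL,
                                 min_trials = 10, t_max = NULL) {
  orients <- sort(unique(rec$trials$orientation))
  z <- list()
  for (u in unit_ids)
    for (o in orients)
      z[[paste(u, o)]] <- normalized_latencies(rec, u, o, t_max)
  out <- list()
  for (i in seq_along(unit_ids)) for (j in seq_along(unit_ids)) {
    if (j <= i) next
    a <- unit_ids[i]; b <- unit_ids[j]
    dpo <- if (is.null(phi)) NA_real_ else {
      d <- abs(phi[as.character(a)] - phi[as.character(b)]) %% 180
      min(d, 180 - d)
    }
    for (o in orients) {
      za <- z[[paste(a, o)]]; zb <- z[[paste(b, o)]]
      ok <- !is.na(za) & !is.na(zb)
      if (sum(ok) < min_trials) next
      out[[length(out) + 1L]] <- data.frame(
        unit_a = a, unit_b = b, orientation = o,
        r = stats::cor(za[ok], zb[ok]), n_trials = sum(ok),
        dpo = unname(dpo))
    }
  }
  if (!length(out))
    return(data.frame(unit_a = integer(), unit_b = integer(),
                      orientation = numeric(), r = numeric(),
                      n_trials = integer(), dpo = numeric()))
  do.call(rbind, out)
}

#' Latency correlation versus preferred-orientation difference
#'
#' Bins the per-(pair, orientation) correlation coefficients into six equal
#' bins of preferred-orientation difference over [0, 90] degrees and fits
#' an ordinary least-squares slope of correlation on the difference.
#'
#' @param tbl a [latency_correlations()] table with \code{dpo} defined.
#' @param n_bins number of bins (default 6).
#' @return list with \code{bins} (data frame: dpo_mid, mean_r, sem_r,
#'   n) and \code{slope}, \code{slope_se}, \code{slope_p} (NA when fewer
#'   than two distinct pairs).
#' @export
correlation_vs_dpo <- function(tbl, n_bins = 6) {
  tbl <- tbl[!is.na(tbl$dpo), ]
  edges <- seq(0, 90, length.out = n_bins + 1)
  idx <- pmin(findInterval(tbl$dpo, edges, rightmost.closed = TRUE), n_bins)
  bins <- data.frame(dpo_mid = (edges[-1] + edges[-length(edges)]) / 2,
                     mean_r = NA_real_, sem_r = NA_real_, n = 0L)
  for (b in seq_len(n_bins)) {
    rr <- tbl$r[idx == b]
    bins$n[b] <- length(rr)
    if (length(rr)) {
      bins$mean_r[b] <- mean(rr)
      bins$sem_r[b] <- stats::sd(rr) / sqrt(length(rr))
    }
  }
  n_pairs <- nrow(unique(tbl[, c("unit_a", "unit_b")]))
  if (n_pairs < 2)
    return(list(bins = bins, slope = NA_real_, slope_se = NA_real_,
                slope_p = NA_real_))
  fit <- stats::lm(r ~ dpo, data = tbl)
  cf <- summary(fit)$coefficients
  list(bins = bins, slope = cf["dpo", "Estimate"],
       slope_se = cf["dpo", "Std. Error"],
       slope_p = cf["dpo", "Pr(>|t|)"])
}
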