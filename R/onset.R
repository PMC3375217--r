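#' Calibrate the coincidence-detector threshold
#'
#' Estimates the mean and standard deviation of the number of spikes the
#' pooled onset units fire in non-overlapping windows of \code{window_ms}
#' tiling the spontaneous epochs (inter-stimulus intervals minus their first
#' 300 ms), and sets the spike-count threshold to the smallest integer at
#' least \code{n_sd} standard deviations above the mean (never below 1).
#'
#' @param rec a \code{population_recording}.
#' @param onset_units unit ids whose pooled activity signals onset.
#' @param window_ms running-window length T, ms (default 20).
#' @param n_sd criterion in standard deviations above baseline (default 4).
#' @param settle_ms dead time after stimulus offset (default 300).
#' @return list of class \code{onset_config}: \code{window_ms}, \code{n_sd},
#'   \code{mu0}, \code{sigma0}, \code{m}.
#' @export
calibrate_onset_threshold <- function(rec, onset_units, window_ms = 20,
                                      n_sd = 4, settle_ms = 300) {
  stopifnot(length(onset_units) >= 1)
  tr <- rec$trials
  ep0 <- tr$stim_onset + tr$stim_duration + settle_ms
  ep1 <- tr$trial_length
  if (sum(pmax(0, ep1 - ep0)) <= 0)
    stop("zero spontaneous time: cannot calibrate onset threshold")
  sp <- rec$spikes[rec$spikes$unit_id %in% onset_units, ]
  m <- match(sp$trial_id, tr$trial_id)
  counts <- integer(0)
  for (i in seq_len(nrow(tr))) {
    nwin <- floor((ep1[i] - ep0[i]) / window_ms)
    if (nwin < 1) next
    t <- sp$t_ms[m == i]
    t <- t[t >= ep0[i] & t < ep0[i] + nwin * window_ms]
    idx <- floor((t - ep0[i]) / window_ms) + 1L
    counts <- c(counts, tabulate(idx, nbins = nwin))
  }
  mu0 <- mean(counts)
  sigma0 <- stats::sd(counts)
  if (is.na(sigma0)) sigma0 <- 0
  structure(list(window_ms = window_ms, n_sd = n_sd, mu0 = mu0,
                 sigma0 = sigma0, m = max(1L, ceiling(mu0 + n_sd * sigma0))),
            class = "onset_config")
}

#' Running-window coincidence onset detector
#'
#' Finds the smallest time t such that at least \code{m} spikes fall in the
#' left-open window (t - T, t]; the onset is the window end.  Because a
#' crossing can only first occur at a spike time, candidate times are the
#' spike times themselves (equivalent to continuous sliding).
#'
#' @param spikes spike times (pooled over onset units), any order.
#' @param window_ms window length T, ms.
#' @param m spike-count threshold, >= 1.
#' @return onset time, or NA if the threshold is never reached.
#' @export
detect_onset <- function(spikes, window_ms, m) {
  s <- sort(spikes)
  k <- length(s)
  if (k < m) return(NA_real_)
  if (m == 1L) return(s[1])
  span <- s[m:k] - s[1:(k - m + 1L)]
  hit <- which(span < window_ms)
  if (!length(hit)) NA_real_ else s[hit[1] + m - 1L]
}

# count disjoint threshold crossings (used for false-alarm rates): after a
# detection the scan restarts with the spikes after the detected onset
count_detections <- function(spikes, window_ms, m) {
  s <- sort(spikes)
  k <- 0L
  repeat {
    t <- detect_onset(s, window_ms, m)
    if (is.na(t)) return(k)
    k <- k + 1L
    s <- s[s > t]
  }
}

#' Detect stimulus onset on every trial
#'
#' Runs the coincidence detector on the pooled onset-unit spikes of each
#' trial, using spikes from stimulus onset to the end of the trial.
#'
#' @param rec a \code{population_recording}.
#' @param onset_units unit ids of the onset detectors.
#' @param cfg an [calibrate_onset_threshold()] result (or a list with
#'   \code{window_ms} and \code{m}).
#' @return numeric vector named by trial id: detected onset time in the
#'   trial clock, NA for misses.
#' @export
detect_trial_onsets <- function(rec, onset_units, cfg) {
  tr <- rec$trials
  sp <- rec$spikes[rec$spikes$unit_id %in% onset_units, ]
  byt <- split(sp$t_ms, factor(sp$trial_id, levels = tr$trial_id))
  out <- stats::setNames(rep(NA_real_, nrow(tr)), tr$trial_id)
  for (i in seq_len(nrow(tr))) {
    t <- byt[[i]]
    t <- t[t >= tr$stim_onset[i]]
    out[i] <- detect_onset(t, cfg$window_ms, cfg$m)
  }
  out
}

#' ROC characterisation of the onset detector
#'
#' For each criterion on a grid of \code{n_sd} values: the hit probability
#' is the fraction of trials with a detection inside the stimulus window,
#' and the false-alarm rate is the number of disjoint detections during the
#' spontaneous-only epochs divided by the total spontaneous time (a rate in
#' events per second, not a probability, since "no stimulus" spans
#' arbitrary durations).
#'
#' @param rec a \code{population_recording}.
#' @param onset_units onset-unit ids.
#' @param window_ms window length T, ms.
#' @param n_sd_grid criteria, in standard deviations above baseline.
#' @param settle_ms dead time after stimulus offset (default 300).
#' @return data frame with \code{n_sd}, \code{m}, \code{hit_prob},
#'   \code{fa_rate} (per second) and \code{mean_onset} (ms after stimulus
#'   onset, over hit trials).
#' @export
onset_roc <- function(rec, onset_units, window_ms = 20,
                      n_sd_grid = 0:8, settle_ms = 300) {
  tr <- rec$trials
  sp <- rec$spikes[rec$spikes$unit_id %in% onset_units, ]
  byt <- split(sp$t_ms, factor(sp$trial_id, levels = tr$trial_id))
  base <- calibrate_onset_threshold(rec, onset_units, window_ms, 0,
                                    settle_ms)
  ep0 <- tr$stim_onset + tr$stim_duration + settle_ms
  ep1 <- tr$trial_length
  total_s <- sum(pmax(0, ep1 - ep0)) / 1000
  out <- data.frame(n_sd = n_sd_grid, m = NA_integer_, hit_prob = NA_real_,
                    fa_rate = NA_real_, mean_onset = NA_real_)
  for (j in seq_along(n_sd_grid)) {
    m <- max(1L, ceiling(base$mu0 + n_sd_grid[j] * base$sigma0))
    out$m[j] <- m
    hits <- onsets <- numeric(nrow(tr))
    fa <- 0L
    for (i in seq_len(nrow(tr))) {
      t <- byt[[i]]
      tin <- t[t >= tr$stim_onset[i] &
                 t <= tr$stim_onset[i] + tr$stim_duration[i]]
      d <- detect_onset(tin, window_ms, m)
      hits[i] <- !is.na(d)
      onsets[i] <- if (is.na(d)) NA else d - tr$stim_onset[i]
      fa <- fa + count_detections(t[t >= ep0[i] & t < ep1[i]], window_ms, m)
    }
    out$hit_prob[j] <- mean(hits)
    out$fa_rate[j] <- fa / total_s
    out$mean_onset[j] <- mean(onsets, na.rm = TRUE)
  }
  out
}

#' Leaky integrate-and-fire onset detector
#'
#' Each spike increments the membrane potential by one unit; between spikes
#' the potential decays exponentially with time constant \code{tau_ms}.
#' The onset is the first spike time at which the post-jump potential
#' reaches \code{threshold}.
#'
#' @param spikes pooled spike times, any order.
#' @param tau_ms decay time constant, ms (default 20).
#' @param threshold firing threshold, > 0 (in spike units).
#' @return onset time, or NA.
#' @export
lif_onset <- function(spikes, tau_ms = 20, threshold) {
  stopifnot(threshold > 0)
  s <- sort(spikes)
  v <- 0
  t_prev <- -Inf
  for (t in s) {
    v <- v * exp(-(t - t_prev) / tau_ms) + 1
    if (v >= threshold) return(t)
    t_prev <- t
  }
  NA_real_
}
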