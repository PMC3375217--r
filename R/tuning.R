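#' Estimate the nth-spike latency distribution of a unit
#'
#' For each stimulus orientation, forms the histogram of the trial-wise time
#' of the nth spike after the reference (default: stimulus onset) on a fixed
#' bin grid, normalised by the number of trials.  Trials with no nth spike
#' inside the grid contribute no mass, so the density may sum to less than 1;
#' the cumulative distribution is obtained by summation.
#'
#' @param rec a \code{population_recording}.
#' @param unit_id the unit.
#' @param n spike index (1 = first spike).
#' @param bin_ms histogram bin width, ms (default 10).
#' @param t_max end of the grid, ms after the reference; defaults to stimulus
#'   duration + 300 ms.
#' @param reference per-trial reference times (trial clock); defaults to each
#'   trial's stimulus onset.
#' @return an object of class \code{nth_spike_distribution}: list with
#'   \code{n}, \code{edges} (bin edges), \code{orientations}, matrices
#'   \code{f} and \code{F} (orientation x bin), and \code{K} (trials per
#'   orientation).
#' @export
estimate_nth_spike_distribution <- function(rec, unit_id, n = 1, bin_ms = 10,
                                            t_max = NULL, reference = NULL) {
  stopifnot(n >= 1)
  if (is.null(t_max))
    t_max <- rec$trials$stim_duration[1] + 300
  if (is.null(reference))
    reference <- stats::setNames(rec$trials$stim_onset,
                                 rec$trials$trial_id)
  orients <- sort(unique(rec$trials$orientation))
  edges <- seq(0, t_max, by = bin_ms)
  nb <- length(edges) - 1L
  f <- matrix(0, length(orients), nb,
              dimnames = list(orients, NULL))
  K <- integer(length(orients))
  for (i in seq_along(orients)) {
    v <- spike_view(rec, unit_id, orientation = orients[i],
                    reference = reference)
    tn <- nth_spike_times(v, n) - attr(v, "reference")
    K[i] <- length(tn)
    tn <- tn[!is.na(tn) & tn >= 0 & tn < t_max]
    if (length(tn))
      f[i, ] <- tabulate(findInterval(tn, edges), nbins = nb) / K[i]
  }
  structure(list(n = n, bin_ms = bin_ms, edges = edges,
                 orientations = orients, f = f,
                 F = t(apply(f, 1, cumsum)), K = K),
            class = "nth_spike_distribution")
}

# first crossing of `level` by cumulative curve Fv (values at right bin
# edges), linearly interpolated inside the crossing bin
level_cross <- function(Fv, edges, level) {
  hit <- which(Fv >= level)
  if (!length(hit)) return(NA_real_)
  b <- hit[1]
  F_prev <- if (b == 1L) 0 else Fv[b - 1L]
  edges[b] + (edges[b + 1L] - edges[b]) * (level - F_prev) / (Fv[b] - F_prev)
}

#' Level-curve latency per orientation
#'
#' The latency tuning curve: for each orientation, the earliest time at
#' which the cumulative nth-spike distribution reaches \code{level}
#' (default 0.5), linearly interpolated within the crossing bin.  \code{NA}
#' where the cumulative never reaches the level.
#'
#' @param dist an [estimate_nth_spike_distribution()] result.
#' @param level probability level in (0, 1).
#' @return named numeric vector of latencies (ms), one per orientation.
#' @export
level_curve <- function(dist, level = 0.5) {
  stopifnot(level > 0, level < 1)
  out <- apply(dist$F, 1, level_cross, edges = dist$edges, level = level)
  stats::setNames(out, rownames(dist$f))
}

#' Standard-error bounds for a level curve
#'
#' The cumulative distribution at each bin is the mean of a Bernoulli
#' variable over K trials, so SEM(F) = sqrt(F(1-F)/K).  The lower latency
#' bound is the level curve of F + SEM (which crosses earlier) and the upper
#' bound that of F - SEM.
#'
#' @param dist an [estimate_nth_spike_distribution()] result.
#' @param level probability level.
#' @return data frame with \code{orientation}, \code{latency},
#'   \code{lower}, \code{upper}.
#' @export
latency_sem_bounds <- function(dist, level = 0.5) {
  Fm <- dist$F
  sem <- sqrt(Fm * (1 - Fm) / dist$K)
  lo <- hi <- pt <- numeric(nrow(Fm))
  for (i in seq_len(nrow(Fm))) {
    pt[i] <- level_cross(Fm[i, ], dist$edges, level)
    lo[i] <- level_cross(pmin(Fm[i, ] + sem[i, ], 1), dist$edges, level)
    hi[i] <- level_cross(pmax(Fm[i, ] - sem[i, ], 0), dist$edges, level)
  }
  data.frame(orientation = dist$orientations, latency = pt,
             lower = lo, upper = hi)
}

#' Cosine fit of a latency tuning curve
#'
#' Least-squares fit of \eqn{L(\theta) = A - B \cos(2(\theta - \phi))} via
#' linear regression on \eqn{\{1, \cos 2\theta, \sin 2\theta\}}.  \code{B}
#' is reported as a non-negative amplitude and \code{phi} (degrees, in
#' [0, 180)) as the orientation minimising the fitted curve.  Orientations
#' with undefined latency are dropped; fewer than 3 defined points yield an
#' unavailable fit.
#'
#' @param theta orientations, degrees.
#' @param latency latencies, ms (NA allowed).
#' @return list with \code{A}, \code{B}, \code{phi}, standard errors
#'   \code{se_A}, \code{se_B}, \code{se_phi} (delta method, degrees),
#'   residual SD \code{sigma} and \code{ok}.  \code{phi} is \code{NA} when
#'   \code{B} is exactly 0 (untuned by convention).
#' @export
fit_cosine <- function(theta, latency) {
  keep <- !is.na(latency) & !is.na(theta)
  if (sum(keep) < 3)
    return(list(A = NA_real_, B = NA_real_, phi = NA_real_,
                se_A = NA_real_, se_B = NA_real_, se_phi = NA_real_,
                sigma = NA_real_, ok = FALSE))
  th <- theta[keep] * pi / 180
  y <- latency[keep]
  x1 <- cos(2 * th); x2 <- sin(2 * th)
  fit <- stats::lm(y ~ x1 + x2)
  cf <- stats::coef(fit)
  A <- unname(cf[1])
  c1 <- unname(cf[2]); c2 <- unname(cf[3])
  B <- sqrt(c1^2 + c2^2)
  # L = A + c1 cos2t + c2 sin2t = A - B cos(2(t - phi)) with
  # c1 = -B cos(2 phi), c2 = -B sin(2 phi); numerically-zero modulation
  # leaves the preferred orientation undefined
  phi <- if (B < 1e-8) NA_real_ else
    (atan2(-c2, -c1) / 2 * 180 / pi) %% 180
  sm <- suppressWarnings(summary(fit))
  se <- sm$coefficients[, "Std. Error"]
  se_B <- if (B > 0) sqrt((c1 * se[2])^2 + (c2 * se[3])^2) / B else
    sqrt(mean(se[2:3]^2))
  se_phi <- if (B > 0)
    0.5 * sqrt((c2 * se[2])^2 + (c1 * se[3])^2) / B^2 * 180 / pi
  else NA_real_
  list(A = A, B = B, phi = phi,
       se_A = unname(se[1]), se_B = unname(se_B), se_phi = unname(se_phi),
       sigma = sm$sigma, ok = TRUE)
}

#' Mean firing-rate tuning curve
#'
#' Mean rate per orientation over the window from stimulus onset to 300 ms
#' after stimulus offset.
#'
#' @param rec a \code{population_recording}.
#' @param unit_id the unit.
#' @param window_end_ms end of the counting window, ms after stimulus
#'   offset (default 300).
#' @return data frame with \code{orientation} and \code{rate} (spikes/s).
#' @export
rate_tuning <- function(rec, unit_id, window_end_ms = 300) {
  orients <- sort(unique(rec$trials$orientation))
  rate <- numeric(length(orients))
  for (i in seq_along(orients)) {
    tr <- rec$trials[rec$trials$orientation == orients[i], ]
    v <- spike_view(rec, unit_id, orientation = orients[i])
    w0 <- tr$stim_onset
    w1 <- tr$stim_onset + tr$stim_duration + window_end_ms
    counts <- mapply(function(s, a, b) sum(s >= a & s < b), v, w0, w1)
    rate[i] <- mean(counts) / mean(w1 - w0) * 1000
  }
  data.frame(orientation = orients, rate = rate)
}

#' Von-Mises fit of a rate tuning curve
#'
#' Nonlinear least-squares fit of
#' \deqn{R(\theta) = base + amp\,\exp(\kappa(\cos 2(\theta-\phi) - 1))}
#' with a multistart over a grid of preferred orientations.  Flat curves
#' yield a degenerate fit (kappa ~ 0) which is flagged.
#'
#' @param theta orientations, degrees.
#' @param rate mean rates, spikes/s.
#' @return list with \code{base}, \code{amp}, \code{kappa}, \code{phi},
#'   \code{rss}, \code{converged} and \code{degenerate}.
#' @export
fit_von_mises <- function(theta, rate) {
  stopifnot(length(theta) >= 4)
  th <- theta * pi / 180
  obj <- function(p) {
    mu <- p[1] + p[2] * exp(p[3] * (cos(2 * (th - p[4])) - 1))
    sum((rate - mu)^2)
  }
  best <- NULL
  for (phi0 in seq(0, pi * 7 / 8, by = pi / 8)) {
    p0 <- c(min(rate), max(rate) - min(rate) + 1e-6, 1.5, phi0)
    fit <- try(stats::optim(p0, obj, method = "L-BFGS-B",
                            lower = c(0, 0, 0, -pi),
                            upper = c(Inf, Inf, 50, 2 * pi)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    # fallback: cosine moments on the rates
    cs <- fit_cosine(theta, rate)
    return(list(base = cs$A, amp = cs$B, kappa = NA_real_, phi = cs$phi,
                rss = NA_real_, converged = FALSE, degenerate = TRUE))
  }
  p <- best$par
  degenerate <- p[3] < 1e-3 || p[2] < 1e-6
  list(base = p[1], amp = p[2], kappa = p[3],
       phi = if (degenerate) NA_real_ else (p[4] * 180 / pi) %% 180,
       rss = best$value, converged = best$convergence == 0,
       degenerate = degenerate)
}

#' Peristimulus time histogram
#'
#' Trial-averaged firing rate in fixed bins after stimulus onset.
#'
#' @param view a [spike_view()] (typically one unit, one orientation, no
#'   reference filtering).
#' @param bin_ms bin width, ms.
#' @param t_max length of the histogram, ms after stimulus onset.
#' @param stim_onset stimulus onset in the trial clock.
#' @return data frame with bin \code{time} (centre, ms) and \code{rate}
#'   (spikes/s).
#' @export
psth <- function(view, bin_ms = 10, t_max = 400, stim_onset = 0) {
  edges <- seq(0, t_max, by = bin_ms)
  nb <- length(edges) - 1L
  cnt <- numeric(nb)
  for (v in view) {
    rel <- v - stim_onset
    rel <- rel[rel >= 0 & rel < t_max]
    if (length(rel)) cnt <- cnt + tabulate(findInterval(rel, edges), nb)
  }
  K <- length(view)
  data.frame(time = edges[-length(edges)] + bin_ms / 2,
             rate = cnt / K / (bin_ms / 1000))
}

#' Half-maximum latency of a PSTH
#'
#' The earliest time at which the PSTH reaches half of its peak, linearly
#' interpolated between bin centres.  Undefined (NA) when the peak is less
#' than twice the spontaneous rate.
#'
#' @param psth_df a [psth()] result.
#' @param spont_rate the unit's spontaneous rate, spikes/s.
#' @return time in ms, or NA.
#' @export
halfmax_latency <- function(psth_df, spont_rate) {
  r <- psth_df$rate
  pk <- max(r)
  if (pk < 2 * spont_rate) return(NA_real_)
  half <- pk / 2
  b <- which(r >= half)[1]
  if (b == 1L)  # already above half-peak in the first bin: its left edge
    return(psth_df$time[1] - (psth_df$time[2] - psth_df$time[1]) / 2)
  t0 <- psth_df$time[b - 1L]; t1 <- psth_df$time[b]
  t0 + (t1 - t0) * (half - r[b - 1L]) / (r[b] - r[b - 1L])
}

#' Spontaneous firing rate from inter-stimulus intervals
#'
#' Pools, per unit, all spikes in the epochs from 300 ms after stimulus
#' offset to the end of each trial and divides by the total epoch time.
#'
#' @param rec a \code{population_recording}.
#' @param unit_ids units to measure (default all).
#' @param settle_ms dead time after stimulus offset excluded from the
#'   spontaneous epoch (default 300).
#' @return named numeric vector of rates, spikes/s (NA when no epoch time).
#' @export
spontaneous_rate <- function(rec, unit_ids = rec$units$unit_id,
                             settle_ms = 300) {
  tr <- rec$trials
  ep0 <- tr$stim_onset + tr$stim_duration + settle_ms
  ep1 <- tr$trial_length
  total_s <- sum(pmax(0, ep1 - ep0)) / 1000
  sp <- rec$spikes
  m <- match(sp$trial_id, tr$trial_id)
  inside <- sp$t_ms >= ep0[m] & sp$t_ms < ep1[m]
  out <- stats::setNames(numeric(length(unit_ids)), unit_ids)
  if (total_s <= 0) return(out * NA_real_)
  cnt <- table(factor(sp$unit_id[inside], levels = unit_ids))
  out[] <- as.numeric(cnt) / total_s
  out
}

#' Classify units as tuned, onset detectors, or other
#'
#' A unit is \emph{tuned} when the modulation amplitude B of the cosine fit
#' to its first-spike latency tuning curve exceeds 15 ms, and an \emph{onset
#' detector} when B < 15 ms and its spontaneous rate (from inter-stimulus
#' epochs, first 300 ms removed) is below 5 spikes/s.  Everything else --
#' including B exactly 15 ms or an unavailable fit -- is \emph{other}.
#'
#' @param rec a \code{population_recording}.
#' @param b_threshold_ms tuning-modulation threshold, ms (default 15).
#' @param spont_threshold spontaneous-rate threshold, spikes/s (default 5).
#' @param bin_ms histogram bin for the latency distributions.
#' @return data frame with \code{unit_id}, \code{spont_rate}, \code{A},
#'   \code{B}, \code{phi} and \code{label}.
#' @export
classify_units <- function(rec, b_threshold_ms = 15, spont_threshold = 5,
                           bin_ms = 10) {
  ids <- rec$units$unit_id
  spont <- spontaneous_rate(rec, ids)
  if (all(is.na(spont)))
    warning("no inter-stimulus epochs: spontaneous rate unavailable")
  res <- data.frame(unit_id = ids, spont_rate = as.numeric(spont),
                    A = NA_real_, B = NA_real_, phi = NA_real_,
                    label = "other", stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    d <- estimate_nth_spike_distribution(rec, ids[i], n = 1, bin_ms = bin_ms)
    fit <- fit_cosine(d$orientations, level_curve(d, 0.5))
    res$A[i] <- fit$A; res$B[i] <- fit$B; res$phi[i] <- fit$phi
    if (!fit$ok || is.na(res$spont_rate[i])) next
    if (fit$B > b_threshold_ms) {
      res$label[i] <- "tuned"
    } else if (fit$B < b_threshold_ms &&
               res$spont_rate[i] < spont_threshold) {
      res$label[i] <- "onset_detector"
    }
  }
  res
}
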