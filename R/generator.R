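#' Configuration for the synthetic population generator
#'
#' Builds the full parameter set used by [generate_population()].  The
#' defaults emulate a trial-aligned multi-electrode recording from primary
#' visual cortex: ~100 units, 8 orientations spanning 180 degrees, a few
#' hundred repetitions of a 300 ms drifting-grating stimulus separated by a
#' 500 ms inter-stimulus interval, orientation-tuned response latency and
#' rate, spontaneous firing, a subpopulation of untuned low-spontaneous
#' "onset" units, and weak positive shared trial-to-trial latency shifts.
#'
#' Tuned units respond with an evoked inhomogeneous Poisson segment whose
#' rate follows a von-Mises tuning curve
#' \deqn{R(\theta) = R_{max} \exp(\kappa(\cos 2(\theta-\phi) - 1))}
#' starting at the latency
#' \deqn{L(\theta) = A - B \cos 2(\theta-\phi) + s_{trial} + \epsilon}
#' where \code{s_trial ~ N(0, shared_shift_sd^2)} is common to all tuned
#' units in a trial and \code{epsilon ~ N(0, onset_jitter_sd^2)} is private.
#' Spontaneous Poisson firing at each unit's rate \code{lambda} is superposed
#' throughout the trial.  Onset units have \code{B = 0}, an untuned evoked
#' rate (\code{kappa = 0}) and a low spontaneous-rate ceiling.
#'
#' Per-unit parameters may be supplied as a data frame via \code{units};
#' otherwise they are drawn from population distributions under the root
#' seed.  The modulation \code{B} and mean latency \code{A} are drawn so that
#' the fitted latency at the preferred orientation, \code{A - B}, is
#' approximately constant across units.
#'
#' @param n_units number of units.
#' @param orientations stimulus orientations in degrees, unique modulo 180.
#' @param repetitions trials per orientation (K).
#' @param stim_duration,isi_duration stimulus and inter-stimulus durations, ms.
#' @param onset_fraction fraction of units designated untuned onset units.
#' @param shared_shift_sd SD (ms) of the trial-wise latency shift shared by
#'   all tuned units.
#' @param onset_jitter_sd SD (ms) of each unit's private latency jitter.
#' @param latency_A,latency_A_sd mean latency (ms) population mean and SD.
#' @param latency_B,latency_B_sd latency modulation (ms) population mean / SD.
#' @param evoked_rate_max peak evoked rate, spikes/s (population median).
#' @param rate_kappa von-Mises concentration of the evoked-rate tuning.
#' @param spont_rate mean spontaneous rate of tuned units, spikes/s.
#' @param onset_spont_max spontaneous-rate ceiling for onset units, spikes/s.
#' @param phase_freq optional temporal frequency (cycles/s) of a sinusoidal
#'   modulation of the evoked rate, emulating phase locking to a drifting
#'   grating; 0 (default) disables it.
#' @param units optional data frame of per-unit parameters with columns
#'   \code{unit_id, latency_A, latency_B, pref_phi, evoked_rate_max,
#'   rate_kappa, spont_rate, is_onset}; overrides the population draws.
#' @param seed integer root seed.
#' @return a list of class \code{"generator_config"}.
#' @export
generator_config <- function(n_units = 120,
                             orientations = seq(0, 157.5, by = 22.5),
                             repetitions = 300,
                             stim_duration = 300,
                             isi_duration = 500,
                             onset_fraction = 0.15,
                             shared_shift_sd = 2.7,
                             onset_jitter_sd = 10,
                             latency_A = 80, latency_A_sd = 8,
                             latency_B = 25, latency_B_sd = 5,
                             evoked_rate_max = 40,
                             rate_kappa = 1.5,
                             spont_rate = 5,
                             onset_spont_max = 2,
                             phase_freq = 0,
                             units = NULL,
                             seed = 1L) {
  if (stim_duration <= 0 || isi_duration < 0)
    stop("non-physical config: durations must be positive")
  if (n_units < 1) stop("n_units must be >= 1")
  if (any(orientations < 0 | orientations >= 180))
    stop("orientations must lie in [0, 180)")
  if (anyDuplicated(orientations %% 180))
    stop("orientations must be unique modulo 180")
  if (any(c(evoked_rate_max, spont_rate, onset_spont_max) < 0))
    stop("rates must be >= 0")
  if (latency_A < latency_B || latency_B < 0)
    stop("need latency_A >= latency_B >= 0")
  cfg <- list(n_units = as.integer(n_units),
              orientations = as.numeric(orientations),
              repetitions = as.integer(repetitions),
              stim_duration = as.numeric(stim_duration),
              isi_duration = as.numeric(isi_duration),
              onset_fraction = onset_fraction,
              shared_shift_sd = shared_shift_sd,
              onset_jitter_sd = onset_jitter_sd,
              latency_A = latency_A, latency_A_sd = latency_A_sd,
              latency_B = latency_B, latency_B_sd = latency_B_sd,
              evoked_rate_max = evoked_rate_max,
              rate_kappa = rate_kappa,
              spont_rate = spont_rate,
              onset_spont_max = onset_spont_max,
              phase_freq = phase_freq,
              units = units,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

## Draw the per-unit parameter table under the root seed.  Done before the
## trial loop so that growing K never changes unit identities.
draw_unit_table <- function(cfg) {
  if (!is.null(cfg$units)) {
    u <- cfg$units
    need <- c("unit_id", "latency_A", "latency_B", "pref_phi",
              "evoked_rate_max", "rate_kappa", "spont_rate", "is_onset")
    if (!all(need %in% names(u)))
      stop("units table missing columns: ",
           paste(setdiff(need, names(u)), collapse = ", "))
    if (any(u$latency_A < u$latency_B) || any(u$latency_B < 0))
      stop("need latency_A >= latency_B >= 0 for every unit")
    return(u)
  }
  n <- cfg$n_units
  n_onset <- round(cfg$onset_fraction * n)
  is_onset <- rep(FALSE, n)
  if (n_onset > 0) is_onset[seq_len(n_onset)] <- TRUE
  B <- pmax(0, stats::rnorm(n, cfg$latency_B, cfg$latency_B_sd))
  # A - B approximately constant across units (latency at preferred
  # orientation), so A and B come out positively correlated.
  A_at_pref <- pmax(20, stats::rnorm(n, cfg$latency_A - cfg$latency_B,
                                     cfg$latency_A_sd))
  A <- A_at_pref + B
  phi <- stats::runif(n, 0, 180)
  rmax <- cfg$evoked_rate_max * exp(stats::rnorm(n, 0, 0.25))
  kappa <- rep(cfg$rate_kappa, n)
  lam <- stats::rgamma(n, shape = 2, scale = cfg$spont_rate / 2)
  # onset units: untuned latency and rate, earlier latency, low background
  B[is_onset] <- 0
  A[is_onset] <- pmax(20, stats::rnorm(sum(is_onset), 55, 5))
  phi[is_onset] <- NA_real_
  kappa[is_onset] <- 0
  lam[is_onset] <- stats::runif(sum(is_onset), 0, cfg$onset_spont_max)
  data.frame(unit_id = seq_len(n),
             latency_A = A, latency_B = B, pref_phi = phi,
             evoked_rate_max = rmax, rate_kappa = kappa,
             spont_rate = lam, is_onset = is_onset)
}

# per-trial substream seed, derived from the root seed and the trial index
trial_seed <- function(seed, trial) {
  as.integer((as.numeric(seed) + 48271 * as.numeric(trial)) %% 2147483647L)
}

#' Generate a synthetic trial-aligned population recording
#'
#' Draws seeded spike trains for every (trial, unit) pair under the model
#' described in [generator_config()].  Spontaneous firing is a homogeneous
#' Poisson process over the whole trial; the evoked response is an
#' inhomogeneous Poisson segment starting at the unit's (noisy) latency and
#' ending at stimulus offset, superposed on the spontaneous process.
#' Negative latencies are clipped to stimulus onset.  Trials are enumerated
#' repetition-major (all orientations at repetition 1, then repetition 2,
#' ...), each with its own substream seed, so increasing \code{repetitions}
#' appends trials without altering earlier ones.
#'
#' @param cfg a [generator_config()].
#' @return a \code{population_recording}: list with data frames
#'   \code{spikes} (trial_id, unit_id, t_ms), \code{trials} (trial_id,
#'   orientation, stim_onset, stim_duration, trial_length) and \code{units}
#'   (ground-truth parameters), plus the config as an attribute.
#' @export
generate_population <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  units <- draw_unit_table(cfg)
  n_units <- nrow(units)
  orient <- cfg$orientations
  K <- cfg$repetitions
  stim_on <- 0
  stim_off <- stim_on + cfg$stim_duration
  trial_len <- cfg$stim_duration + cfg$isi_duration

  n_trials <- length(orient) * K
  trials <- data.frame(trial_id = seq_len(n_trials),
                       orientation = rep(orient, times = K),
                       stim_onset = stim_on,
                       stim_duration = cfg$stim_duration,
                       trial_length = trial_len)

  # rate tuning (spikes/ms) and latency per unit for each orientation
  dphi <- outer(units$pref_phi, orient, function(p, o) (o - p) * pi / 180)
  cos2 <- cos(2 * dphi)
  cos2[is.na(cos2)] <- 1  # untuned units: flat at peak rate
  rate_ms <- units$evoked_rate_max / 1000 *
    exp(units$rate_kappa * (cos2 - 1))      # n_units x n_orient
  lat0 <- units$latency_A - units$latency_B * cos2

  res <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    set.seed(trial_seed(cfg$seed, tr))
    oi <- ((tr - 1L) %% length(orient)) + 1L
    s_trial <- stats::rnorm(1, 0, cfg$shared_shift_sd)
    eps <- stats::rnorm(n_units, 0, cfg$onset_jitter_sd)
    L <- pmax(stim_on, stim_on + lat0[, oi] + s_trial + eps)
    dur <- pmax(0, stim_off - L)
    n_ev <- stats::rpois(n_units, rate_ms[, oi] * dur)
    n_sp <- stats::rpois(n_units, units$spont_rate / 1000 * trial_len)
    tot <- n_ev + n_sp
    if (sum(tot) == 0L) next
    ev_u <- rep.int(seq_len(n_units), n_ev)
    t_ev <- L[ev_u] + stats::runif(sum(n_ev)) * dur[ev_u]
    if (cfg$phase_freq > 0 && length(t_ev)) {
      # thin the evoked process with a sinusoidal envelope (phase locking)
      keep <- stats::runif(length(t_ev)) <
        0.5 * (1 + sin(2 * pi * cfg$phase_freq * (t_ev - stim_on) / 1000))
      t_ev <- t_ev[keep]
      ev_u <- ev_u[keep]
    }
    sp_u <- rep.int(seq_len(n_units), n_sp)
    t_sp <- stats::runif(sum(n_sp)) * trial_len
    u_all <- c(units$unit_id[ev_u], units$unit_id[sp_u])
    t_all <- c(t_ev, t_sp)
    o <- order(u_all, t_all)  # stable: ties keep input row order
    res[[tr]] <- data.frame(trial_id = tr, unit_id = u_all[o], t_ms = t_all[o])
  }
  spikes <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(spikes))
    spikes <- data.frame(trial_id = integer(), unit_id = integer(),
                         t_ms = numeric())
  rownames(spikes) <- NULL
  new_recording(spikes, trials, units, config = cfg)
}

#' Two-column race model
#'
#' A minimal stand-in model of two competing orientation columns used to
#' study how shared trial-to-trial latency fluctuations affect the temporal
#' winner-take-all race.  Each column holds \code{n_per_column} units.  On a
#' trial with "stimulus A" every unit in column A has latency
#' \code{base_latency + s + eps} and every unit in column B
#' \code{base_latency + delta_latency + s + eps}, with \code{s} shared by
#' all units in the trial and \code{eps} private; stimulus-B trials mirror
#' this.  Each unit emits one spike exactly at its latency (the latency
#' marker), optional further evoked Poisson spikes, and spontaneous Poisson
#' spikes throughout the trial.
#'
#' @param n_per_column units per column (N).
#' @param delta_latency deterministic latency offset of the losing column, ms.
#' @param shared_sd,private_sd SDs (ms) of shared / private latency noise.
#' @param spont_rate spontaneous rate, spikes/s.
#' @param evoked_rate rate of additional evoked spikes after the latency
#'   marker, spikes/s.
#' @param n_trials trials per stimulus.
#' @param base_latency mean latency of the favoured column, ms.
#' @param stim_duration,isi_duration trial structure, ms.
#' @param seed integer seed.
#' @return a \code{population_recording}; columns are labelled by pseudo
#'   preferred orientations 0 (column A) and 90 (column B), and trials carry
#'   the corresponding stimulus orientation.
#' @export
generate_two_column_race <- function(n_per_column, delta_latency = 10,
                                     shared_sd = 3, private_sd = 10,
                                     spont_rate = 5, evoked_rate = 40,
                                     n_trials = 200, base_latency = 60,
                                     stim_duration = 300, isi_duration = 500,
                                     seed = 1L) {
  if (n_per_column < 1) stop("n_per_column must be >= 1")
  if (base_latency + delta_latency < 0)
    stop("delta_latency drives latencies negative")
  N <- as.integer(n_per_column)
  trial_len <- stim_duration + isi_duration
  n_tot <- 2L * as.integer(n_trials)
  trials <- data.frame(trial_id = seq_len(n_tot),
                       orientation = rep(c(0, 90), each = n_trials),
                       stim_onset = 0, stim_duration = stim_duration,
                       trial_length = trial_len)
  units <- data.frame(unit_id = seq_len(2L * N),
                      column = rep(c("A", "B"), each = N),
                      pref_phi = rep(c(0, 90), each = N),
                      spont_rate = spont_rate)
  res <- vector("list", n_tot)
  for (tr in seq_len(n_tot)) {
    set.seed(trial_seed(seed, tr))
    s <- stats::rnorm(1, 0, shared_sd)
    eps <- stats::rnorm(2L * N, 0, private_sd)
    # favoured column = the one matching the stimulus
    offs <- if (trials$orientation[tr] == 0)
      rep(c(0, delta_latency), each = N) else rep(c(delta_latency, 0), each = N)
    L <- pmax(0, base_latency + offs + s + eps)
    dur <- pmax(0, stim_duration - L)
    n_ev <- stats::rpois(2L * N, evoked_rate / 1000 * dur)
    n_sp <- stats::rpois(2L * N, spont_rate / 1000 * trial_len)
    uid <- c(rep.int(seq_len(2L * N), 1L),           # latency markers
             rep.int(seq_len(2L * N), n_ev),
             rep.int(seq_len(2L * N), n_sp))
    tms <- c(L,
             L[rep.int(seq_len(2L * N), n_ev)] +
               stats::runif(sum(n_ev)) * dur[rep.int(seq_len(2L * N), n_ev)],
             stats::runif(sum(n_sp)) * trial_len)
    keep <- tms < trial_len
    uid <- uid[keep]; tms <- tms[keep]
    o <- order(uid, tms)
    res[[tr]] <- data.frame(trial_id = tr, unit_id = uid[o], t_ms = tms[o])
  }
  spikes <- do.call(rbind, res)
  rownames(spikes) <- NULL
  new_recording(spikes, trials, units)
}
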