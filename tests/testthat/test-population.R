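make_decoding_recording <- function(n_tuned_per_col = 5, n_onset = 4,
                                    repetitions = 80, spont = 6,
                                    shared_sd = 2.7, private_sd = 10,
                                    rmax = 45, seed = 33) {
  rows <- list()
  id <- 1
  for (c in 1:2) {
    for (k in seq_len(n_tuned_per_col)) {
      rows[[id]] <- unit_row(id, A = 85, B = 28,
                             phi = if (c == 1) 0 else 90,
                             rmax = rmax, kappa = 1.5, lam = spont)
      id <- id + 1
    }
  }
  for (k in seq_len(n_onset)) {
    rows[[id]] <- unit_row(id, A = 55, B = 0, phi = NA, rmax = 60,
                           kappa = 0, lam = 0.5, is_onset = TRUE)
    id <- id + 1
  }
  units <- do.call(rbind, rows)
  generate_population(generator_config(
    n_units = nrow(units), orientations = c(0, 90),
    repetitions = repetitions, shared_shift_sd = shared_sd,
    onset_jitter_sd = private_sd, units = units, seed = seed))
}

test_that("column construction assigns nearest centres with the declared
           boundary rule", {
  phi <- setNames(c(0, 22, 45), 1:3)
  part <- build_columns(phi, M = 8)
  expect_equal(part$width, 22.5)
  expect_equal(part$assignment$center, c(0, 22.5, 45))
  # exactly on a boundary: lower-index group
  part2 <- build_columns(setNames(11.25, 1), M = 8)
  expect_equal(part2$assignment$column, 1)
  expect_error(build_columns(phi, M = 1), "M must be >= 2")
  # pigeonhole: 69 units cannot fill 180 one-degree groups
  set.seed(1)
  phi69 <- setNames(runif(69, 0, 180), 1:69)
  p180 <- build_columns(phi69, M = 180)
  n_empty <- sum(!(seq_len(180) %in% p180$assignment$column))
  expect_gte(n_empty, 111)
})

test_that("population race is perfect without noise and matches the
           single-unit replay for one-unit columns", {
  # near-instantaneous evoked response: first spike sits at the latency
  rec <- make_decoding_recording(n_tuned_per_col = 1, n_onset = 3,
                                 repetitions = 60, spont = 0,
                                 shared_sd = 0, private_sd = 0,
                                 rmax = 2000)
  ref <- setNames(rec$trials$stim_onset, rec$trials$trial_id)
  pop <- population_neurometric(rec, 1, 2, 0, 90, N_grid = 1, n_grid = 1,
                                realizations = 3, reference = ref,
                                seed = 4)
  expect_equal(pop$pc, 1)
})

test_that("no-decision trials are scored at chance and exclusions are
           reported", {
  rec <- make_decoding_recording(n_tuned_per_col = 1, n_onset = 2,
                                 repetitions = 30, spont = 0)
  # silence both tuned units entirely
  rec$spikes <- rec$spikes[!(rec$spikes$unit_id %in% 1:2), ]
  ref <- setNames(rec$trials$stim_onset, rec$trials$trial_id)
  ref[1:5] <- NA  # pretend five onsets were missed
  pop <- population_neurometric(rec, 1, 2, 0, 90, N_grid = 1,
                                realizations = 2, reference = ref,
                                seed = 5)
  expect_equal(pop$pc, 0.5)
  expect_equal(attr(pop, "excluded_frac"), 5 / 60)
})

test_that("accuracy grows with column size and the optimal threshold
           picks the uppermost curve", {
  rec <- make_decoding_recording(n_tuned_per_col = 6, repetitions = 60)
  ids <- rec$units$unit_id[rec$units$is_onset]
  ons <- detect_trial_onsets(rec, ids,
                             calibrate_onset_threshold(rec, ids))
  pop <- population_neurometric(rec, 1:6, 7:12, 0, 90,
                                N_grid = c(1, 4), n_grid = c(1, 2),
                                realizations = 30, reference = ons,
                                seed = 6)
  pc14 <- pop$pc[pop$N == 4 & pop$n == 1]
  pc11 <- pop$pc[pop$N == 1 & pop$n == 1]
  expect_gt(pc14, pc11 - 0.05)
  opt <- optimal_n(pop)
  for (i in seq_len(nrow(opt)))
    expect_equal(opt$pc_opt[i], max(pop$pc[pop$N == opt$N[i]]))
  # decision time shrinks with N for fixed n
  dt <- pop[pop$n == 1, ]
  expect_lt(dt$dt_mean[dt$N == 4], dt$dt_mean[dt$N == 1])
})

test_that("requesting more units than a column holds skips that size", {
  rec <- make_decoding_recording(n_tuned_per_col = 2, repetitions = 20)
  ref <- setNames(rec$trials$stim_onset, rec$trials$trial_id)
  expect_warning(
    pop <- population_neurometric(rec, 1:2, 3:4, 0, 90,
                                  N_grid = c(1, 5), realizations = 2,
                                  reference = ref, seed = 7),
    "skipping N")
  expect_equal(sort(unique(pop$N)), 1)
})

test_that("an artificial reference far past the response leaves only
           chance accuracy", {
  rec <- make_decoding_recording(n_tuned_per_col = 3, repetitions = 50)
  sw <- reference_sweep(rec, 1:3, 4:6, 0, 90, N_grid = 2,
                        ref_times = c(60, 700), realizations = 20,
                        seed = 8)
  late <- sw$pc[sw$t_ref == 700]
  expect_lt(abs(late - 0.5), 3 * sqrt(0.25 / 100) + 0.05)
  expect_gt(sw$pc[sw$t_ref == 60], late + 0.2)
})

test_that("shuffling uncorrelated data leaves accuracy unchanged", {
  rec <- make_decoding_recording(n_tuned_per_col = 3, n_onset = 3,
                                 repetitions = 50, shared_sd = 0)
  ids <- rec$units$unit_id[rec$units$is_onset]
  ons <- detect_trial_onsets(rec, ids,
                             calibrate_onset_threshold(rec, ids))
  sh <- shuffle_analysis(rec, 1:3, 4:6, 0, 90, N_grid = 2, n = 1,
                         realizations = 20, n_shuffles = 6,
                         reference = ons, seed = 9)
  expect_lt(abs(sh$delta_pc),
            3 * sqrt(sh$se_shuffle^2 + 0.25 / 100))
})

test_that("the race at N = n is about as fast as a single unit's first
           spike, and the detected onset performs comparably to the best
           fixed reference", {
  rec <- make_decoding_recording(n_tuned_per_col = 5, n_onset = 3,
                                 repetitions = 60, spont = 6,
                                 rmax = 18, seed = 44)
  ids <- rec$units$unit_id[rec$units$is_onset]
  ons <- detect_trial_onsets(rec, ids,
                             calibrate_onset_threshold(rec, ids))
  pop <- population_neurometric(rec, 1:5, 6:10, 0, 90, N_grid = 3,
                                n_grid = 3, realizations = 20,
                                reference = ons, seed = 45)
  t1 <- unlist(lapply(1:5, function(u) {
    rel <- relative_spike_trials(rec, u, 0, reference = ons)
    vapply(rel, function(v) if (length(v)) v[1] else NA_real_, numeric(1))
  }))
  m1 <- mean(t1, na.rm = TRUE)
  expect_lt(abs(pop$dt_mean - m1), 0.25 * m1)
  popd <- population_neurometric(rec, 1:5, 6:10, 0, 90, N_grid = 4,
                                 n_grid = 1, realizations = 20,
                                 reference = ons, seed = 46)
  sw <- reference_sweep(rec, 1:5, 6:10, 0, 90, N_grid = 4,
                        ref_times = seq(0, 120, by = 20),
                        realizations = 20, seed = 47)
  expect_lt(max(sw$pc) - popd$pc, 3 * sqrt(2) * popd$sem)
})

test_that("multi-alternative discrimination is at chance for untuned
           populations and errors live in (-90, 90]", {
  # untuned "tuned" units: identical latency stats for every orientation
  rows <- lapply(1:6, function(i)
    unit_row(i, A = 70, B = 0, phi = (i - 1) * 30, rmax = 40, kappa = 0,
             lam = 4))
  units <- do.call(rbind, rows)
  rec <- generate_population(generator_config(
    n_units = 6, orientations = seq(0, 157.5, 22.5), repetitions = 30,
    units = units, seed = 10))
  ref <- setNames(rec$trials$stim_onset, rec$trials$trial_id)
  phi <- setNames(units$pref_phi, units$unit_id)
  ma <- multi_alternative(rec, phi, M = 6, n = 1, reference = ref,
                          seed = 11)
  expect_lt(abs(ma$pc - 1 / 6), 3 * sqrt((1 / 6) * (5 / 6) / ma$n_trials))
  expect_true(all(ma$errors > -90 & ma$errors <= 90))
})

test_that("a tuned population discriminates multiple alternatives above
           chance and better with a higher threshold", {
  rows <- lapply(1:8, function(i)
    unit_row(i, A = 85, B = 28, phi = (i - 1) * 22.5, rmax = 45,
             kappa = 1.5, lam = 6))
  units <- do.call(rbind, rows)
  rec <- generate_population(generator_config(
    n_units = 8, orientations = seq(0, 157.5, 22.5), repetitions = 40,
    shared_shift_sd = 0, onset_jitter_sd = 8, units = units, seed = 12))
  ref <- setNames(rec$trials$stim_onset + 60, rec$trials$trial_id)
  phi <- setNames(units$pref_phi, units$unit_id)
  ma1 <- multi_alternative(rec, phi, M = 8, n = 1, reference = ref,
                           seed = 13)
  ma2 <- multi_alternative(rec, phi, M = 8, n = 2, reference = ref,
                           seed = 13)
  expect_gt(ma1$pc, 1 / 8 + 0.1)
  expect_gt(ma2$pc, ma1$pc - 0.05)
})
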