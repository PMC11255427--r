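# Generators: determinism, structural invariants, and recovery of the
# closed-form semi-Markov occupancy.

test_that("generators are pure functions of (parameters, seed)", {
  m <- hypnogram_model()
  expect_identical(as.character(simulate_hypnogram(m, 2, seed = 5)),
                   as.character(simulate_hypnogram(m, 2, seed = 5)))
  tr1 <- make_dose_train(seed = 6)
  tr2 <- make_dose_train(seed = 6)
  expect_identical(tr1$times_s, tr2$times_s)
  expect_false(identical(tr1$times_s, make_dose_train(seed = 7)$times_s))
  pm <- pk_model(cv = 0.2)
  expect_identical(simulate_pk(pm, seed = 3)$conc_ng_per_ml,
                   simulate_pk(pm, seed = 3)$conc_ng_per_ml)
  expect_identical(simulate_qpcr(1, seed = 8)$ct,
                   simulate_qpcr(1, seed = 8)$ct)
})

test_that("hypnogram with zero probability into REM contains no REM", {
  tl <- matrix(c(0, 1, 0, 1, 0, 0, 1, 0, 0), 3, 3, byrow = TRUE)
  m <- hypnogram_model(light = list(mean_bout_min = c(WAKE = 1, NREM = 1,
                                                      REM = 1), trans = tl),
                       dark = list(mean_bout_min = c(WAKE = 1, NREM = 1,
                                                     REM = 1), trans = tl))
  h <- simulate_hypnogram(m, 24, seed = 21)
  expect_false("REM" %in% as.character(h))
})

test_that("time-in-state matches the semi-Markov stationary occupancy", {
  # 200 independent 24 h realizations with identical light/dark
  # parameters; compare mean occupancy to the embedded-chain closed form
  ph <- list(mean_bout_min = c(WAKE = 1.25, NREM = 1.15, REM = 0.5),
             trans = matrix(c(0, 0.95, 0.05,
                              0.62, 0, 0.38,
                              0.90, 0.10, 0), 3, 3, byrow = TRUE,
                            dimnames = list(c("WAKE", "NREM", "REM"),
                                            c("WAKE", "NREM", "REM"))))
  m <- hypnogram_model(light = ph, dark = ph)
  occ <- t(vapply(1:200, function(s) {
    h <- simulate_hypnogram(m, 24, seed = 3000 + s)
    as.numeric(table(factor(as.character(h),
                            c("WAKE", "NREM", "REM")))) / length(h)
  }, numeric(3)))
  target <- stationary_occupancy(m, "light")
  se <- apply(occ, 2, sd) / sqrt(nrow(occ))
  expect_true(all(abs(colMeans(occ) - target) < 3 * se + 1e-12))
})

test_that("synthesized EMG separates states and EEG bands follow weights", {
  m <- hypnogram_model()
  h <- simulate_hypnogram(m, 1, seed = 31)
  rec <- synthesize_signals(h, signal_spec(fs = 128), seed = 32)
  ft <- compute_epoch_features(rec)
  st <- as.character(h)
  expect_gt(min(table(st)), 3)   # all three states present in the hour
  expect_lt(max(ft$emg_rms[st == "REM"]), min(ft$emg_rms[st == "WAKE"]))
  # delta-dominant NREM vs theta-dominant REM, via the spectral module
  sp <- epoch_psd(rec, max_hz = 64)
  rb <- relative_band_power(sp)
  d <- rb$relative_power_pct[rb$band == "delta"]
  expect_gt(mean(d[st == "NREM"]), mean(d[st == "REM"]))
  th <- rb$relative_power_pct[rb$band == "theta"]
  expect_gt(mean(th[st == "REM"]), mean(th[st == "NREM"]))
})

test_that("spike trains respect the refractory floor and burst geometry", {
  for (s in 1:25) {
    tr <- make_dose_train(seed = 400 + s, tonic = 5,
                          mult = c(1, 0.9, 0.7, 0.5, 0.3))
    expect_true(all(diff(tr$times_s) >= 0.001 - 1e-12))
    expect_true(all(tr$times_s >= 0 & tr$times_s < tr$duration_s))
  }
})

test_that("chance sub-80 ms ISI count matches the exponential closed form", {
  # with no injected bursts, at 1 Hz over 300 s the expected number of
  # ISIs below 80 ms is ~ n_isi * (1 - exp(-rate * 0.08)) ~ 23
  counts <- vapply(1:80, function(s) {
    tr <- simulate_spike_train(
      spike_model(tonic_rate_hz = 1, burst_rate_hz = 0),
      data.frame(label = "vehicle", start_s = 0, end_s = 300,
                 dose_mg_per_kg = NA),
      seed = 7000 + s)
    sum(diff(tr$times_s) < 0.08)
  }, 0)
  expected <- 300 * 1 * (1 - exp(-1 * 0.08))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.5)
})

test_that("noise-free PK curve recovers the analytic half-life", {
  pm <- pk_model(scale = 100, ka = 0.5, ke = 0.00693, cv = 0)
  prof <- simulate_pk(pm, times_min = c(120, 240, 480, 720))
  r <- nca(prof)
  expect_equal(r$t_half, log(2) / 0.00693, tolerance = 1e-4)
  # all-zero scale must fail loudly downstream
  prof0 <- simulate_pk(pk_model(scale = 0, ka = 0.5, ke = 0.00693),
                       times_min = c(60, 120, 240))
  expect_error(nca(prof0), "non-positive concentrations")
})

test_that("qPCR generator recovers its ground-truth fold change", {
  # noiseless identities
  expect_equal(ddct(simulate_qpcr(0, noise_sd = 0,
                                  seed = 1))$group_means$mean_fold_change,
               c(1, 1), tolerance = 1e-12)
  # noisy Monte-Carlo recovery of 2^-shift
  shift <- 1
  folds <- vapply(1:300, function(s) {
    d <- ddct(simulate_qpcr(shift, n_per_group = 5, noise_sd = 0.2,
                            seed = 10000 + s))
    d$group_means$mean_fold_change[d$group_means$group == "test"]
  }, 0)
  se <- sd(folds) / sqrt(length(folds))
  # lognormal noise inflates the mean fold slightly; stay within 2 SE
  # of the analytic mean E[2^-(ddCt)] for gaussian ddCt noise
  var_ddct <- 0.2^2 * (1 + 1 / 2) * (1 + 1 / 5)  # target + ref means, calibrator
  expected <- 2^(-shift) * exp((log(2))^2 * var_ddct / 2)
  expect_lt(abs(mean(folds) - expected), 2 * se)
})
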