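# Block firing rates, baseline normalization, two-threshold burst
# detection against the brute-force oracle, and the five burst metrics.

test_that("block rates use half-open membership", {
  blocks <- data.frame(label = c("vehicle", "dose_7"),
                       start_s = c(0, 300), end_s = c(300, 600),
                       dose_mg_per_kg = c(NA, 7))
  tr <- spike_train(seq(0, 299.5, by = 0.5), 600, blocks = blocks)
  r <- block_firing_rate(tr)
  expect_equal(r$rate_hz, c(2, 0))
  # spike exactly at a block end counts in the next block
  tr2 <- spike_train(c(1, 300), 600, blocks = blocks)
  expect_equal(block_firing_rate(tr2)$rate_hz * 300, c(1, 1))
  expect_error(block_firing_rate(
    tr, data.frame(label = "z", start_s = 1, end_s = 1)), "zero-duration")
})

test_that("baseline normalization is exact and guards silent baselines", {
  r <- data.frame(label = c("vehicle", "d1"), dose_mg_per_kg = c(NA, 3.5),
                  rate_hz = c(2, 1))
  n <- normalize_to_baseline(r)
  expect_equal(n$pct_of_baseline, c(100, 50))
  r0 <- r; r0$rate_hz[1] <- 0
  expect_error(normalize_to_baseline(r0), "silent baseline")
})

test_that("detect_bursts resolves the worked ISI examples", {
  b <- detect_bursts(spike_train(c(0, 0.05, 0.10, 0.30), 1))
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_spikes, 3L)
  expect_equal(b$length_s, 0.10)
  expect_equal(b$mean_isi_s, 0.05)
  # threshold edges: 100 ms does not open; exactly 80 ms does not open;
  # exactly 160 ms continues
  expect_equal(nrow(detect_bursts(spike_train(c(0, 0.10), 1))), 0L)
  expect_equal(nrow(detect_bursts(spike_train(c(0, 0.08), 1))), 0L)
  b2 <- detect_bursts(spike_train(c(0, 0.05, 0.21), 1))
  expect_equal(b2$n_spikes, 3L)
  expect_equal(nrow(detect_bursts(spike_train(numeric(0), 1))), 0L)
})

test_that("greedy detector matches the brute-force oracle across rates", {
  # random Poisson trains spanning the LC tonic range, plus trains with
  # injected bursts
  n_mismatch <- 0L
  for (s in 1:150) {
    rate <- 0.5 + 7 * (s %% 30) / 29
    tr <- random_poisson_train(rate, 300, seed = 5000 + s)
    got <- detect_bursts(tr)
    ora <- oracle_bursts(tr$times_s)
    same <- nrow(got) == nrow(ora) &&
      all(got$first_spike == ora$first_spike) &&
      all(got$first_spike + got$n_spikes - 1L == ora$last_spike)
    if (!same) n_mismatch <- n_mismatch + 1L
  }
  for (s in 1:50) {
    tr <- make_dose_train(seed = 6000 + s, tonic = 4)
    got <- detect_bursts(tr)
    ora <- oracle_bursts(tr$times_s)
    if (!(nrow(got) == nrow(ora) &&
          all(got$first_spike == ora$first_spike))) {
      n_mismatch <- n_mismatch + 1L
    }
  }
  expect_identical(n_mismatch, 0L)
})

test_that("burst invariants: disjoint, >= 2 spikes, ISI bounds, shift-free", {
  for (s in 1:30) {
    tr <- make_dose_train(seed = 6500 + s, tonic = 6)
    b <- detect_bursts(tr)
    if (!nrow(b)) next
    expect_true(all(b$n_spikes >= 2))
    last <- b$first_spike + b$n_spikes - 1L
    expect_true(all(b$first_spike[-1] > last[-nrow(b)]))
    for (i in seq_len(nrow(b))) {
      isis <- diff(tr$times_s[b$first_spike[i]:last[i]])
      expect_lt(isis[1], 0.080)
      expect_true(all(isis <= 0.160 + 1e-12))
    }
    # metrics invariant under global time shift
    m1 <- burst_metrics(b, tr)
    sh <- spike_train(tr$times_s + 0, tr$duration_s)
    expect_equal(burst_metrics(detect_bursts(sh), sh), m1)
  }
})

test_that("burst metrics compute the five reported quantities", {
  # one 3-spike burst among 10 spikes in 200 s
  t <- c(0, 0.05, 0.10, 10 * (2:7), 199)
  tr <- spike_train(t, 200)
  b <- detect_bursts(tr)
  m <- burst_metrics(b, tr)
  expect_equal(m$bursts_per_200s, 1)
  expect_equal(m$pct_spikes_in_bursts, 30)
  expect_equal(m$mean_spikes_per_burst, 3)
  expect_equal(m$mean_intra_burst_isi_s, 0.05)
  expect_equal(m$mean_burst_length_s, 0.10)
  # rate normalization: 2 bursts in 400 s -> 1 per 200 s
  t2 <- c(0, 0.05, 100, 100.05, 399)
  tr2 <- spike_train(t2, 400)
  expect_equal(burst_metrics(detect_bursts(tr2), tr2)$bursts_per_200s, 1)
  # no bursts: counts zero, means missing
  tr3 <- spike_train(c(1, 2, 3), 200)
  m3 <- burst_metrics(detect_bursts(tr3), tr3)
  expect_equal(m3$bursts_per_200s, 0)
  expect_equal(m3$pct_spikes_in_bursts, 0)
  expect_true(is.na(m3$mean_spikes_per_burst))
  # no spikes at all: everything missing
  m4 <- burst_metrics(detect_bursts(spike_train(numeric(0), 200)),
                      spike_train(numeric(0), 200))
  expect_true(all(is.na(unlist(m4[1:5]))))
})

test_that("dose-response table is tidy, order-invariant and flags gaps", {
  neurons <- lapply(1:11, function(i)
    analyze_neuron(make_dose_train(seed = 7000 + i)))
  names(neurons) <- sprintf("n%02d", 1:11)
  long <- dose_response_table(neurons)
  expect_equal(sum(long$metric == "pct_of_baseline"), 55L)
  shuffled <- dose_response_table(neurons[c(4:11, 1:3)])
  expect_equal(long, shuffled)
  # a neuron missing a block is flagged, not dropped
  partial <- neurons
  partial$n01 <- partial$n01[-5, ]
  expect_warning(dose_response_table(partial), "missing block")
})
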