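# Independent oracles used by the unit and acceptance tests. These are
# deliberately written with different mechanics than the package code
# they check.

# Brute-force two-threshold burst finder: vectorized candidate
# enumeration (every spike index whose next ISI opens a burst, extended
# to the last ISI before the next >160 ms gap), then left-to-right
# overlap resolution. No shared code with psgpharm::detect_bursts.
oracle_bursts <- function(times, open_isi = 0.080, close_isi = 0.160) {
  n <- length(times)
  if (n < 2L)
    return(data.frame(first_spike = integer(0), last_spike = integer(0)))
  isi <- diff(times)                      # isi[k] between spikes k, k+1
  opens <- which(isi < open_isi)          # candidate first spikes
  breaks <- which(isi > close_isi)        # gaps no burst can cross
  cand_last <- vapply(opens, function(i) {
    b <- breaks[breaks >= i + 1L]
    # ISI b[1] breaks the run, so the burst's last spike is index b[1];
    # with no break the burst runs to the final spike
    if (length(b)) b[1L] else n
  }, 0L)
  first <- integer(0); last <- integer(0)
  prev_end <- 0L
  for (k in seq_along(opens)) {
    if (opens[k] > prev_end) {
      first <- c(first, opens[k])
      last <- c(last, cand_last[k])
      prev_end <- cand_last[k]
    }
  }
  data.frame(first_spike = first, last_spike = last)
}

# Random homogeneous-Poisson spike train (exponential ISIs), for
# burst-detector equivalence sweeps.
random_poisson_train <- function(rate_hz, duration_s, seed) {
  set.seed(seed)
  t <- cumsum(stats::rexp(ceiling(rate_hz * duration_s * 1.6) + 20,
                          rate_hz))
  t <- t[t < duration_s]
  spike_train(t, duration_s)
}

# Hand-coded sums of squares for a complete one-way repeated-measures
# ANOVA (n subjects x k conditions).
oracle_rm_anova <- function(y, subject, condition) {
  subject <- factor(subject); condition <- factor(condition)
  n <- nlevels(subject); k <- nlevels(condition)
  g <- mean(y)
  ss_total <- sum((y - g)^2)
  ss_subj <- k * sum((tapply(y, subject, mean) - g)^2)
  ss_cond <- n * sum((tapply(y, condition, mean) - g)^2)
  ss_err <- ss_total - ss_subj - ss_cond
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  list(F = f, df = c(df1, df2),
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Hand-coded mixed two-way ANOVA (balanced: n subjects per group, every
# subject at every within level). Returns F for between, within and
# interaction.
oracle_mixed_anova <- function(y, subject, between, within) {
  subject <- factor(subject); between <- factor(between)
  within <- factor(within)
  G <- nlevels(between); W <- nlevels(within)
  N <- nlevels(subject)                      # total subjects
  g <- mean(y)
  subj_mean <- tapply(y, subject, mean)
  subj_grp <- tapply(as.integer(between), subject, function(v) v[1])
  grp_mean <- tapply(y, between, mean)
  w_mean <- tapply(y, within, mean)
  cell_mean <- tapply(y, list(between, within), mean)
  n_per_g <- table(factor(subj_grp, levels = seq_len(G)))
  ss_b <- W * sum(n_per_g * (grp_mean - g)^2)
  ss_sw <- W * sum((subj_mean - grp_mean[subj_grp])^2)
  ss_w <- N * sum((w_mean - g)^2)
  ss_bw <- 0
  for (b in seq_len(G)) for (w in seq_len(W))
    ss_bw <- ss_bw + n_per_g[b] *
      (cell_mean[b, w] - grp_mean[b] - w_mean[w] + g)^2
  ss_total <- sum((y - g)^2)
  ss_err_w <- ss_total - ss_b - ss_sw - ss_w - ss_bw
  df <- list(b = c(G - 1, N - G), w = c(W - 1, (N - G) * (W - 1)),
             bw = c((G - 1) * (W - 1), (N - G) * (W - 1)))
  fs <- c(b = unname((ss_b / df$b[1]) / (ss_sw / df$b[2])),
          w = unname((ss_w / df$w[1]) / (ss_err_w / df$w[2])),
          bw = unname((ss_bw / df$bw[1]) / (ss_err_w / df$bw[2])))
  list(F = fs, df = df,
       ss = c(b = unname(ss_b), w = unname(ss_w), bw = unname(ss_bw),
              err_w = unname(ss_err_w)))
}

# Shared fixture: dose-blocked spike train with known multipliers.
make_dose_train <- function(seed, tonic = 3, mult = c(1, 0.8, 0.5, 0.3, 0.2),
                            block_s = 300) {
  simulate_spike_train(
    spike_model(tonic_rate_hz = tonic, burst_rate_hz = 0.05),
    dose_blocks(block_s = block_s, multipliers = mult),
    seed = seed)
}
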