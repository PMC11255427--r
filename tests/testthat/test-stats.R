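# ddCt quantification and the statistical battery.

test_that("ddCt identities and gauge invariance", {
  # a test sample 2 cycles above the control mean is a 4-fold knockdown
  tab <- ct_table(
    sample_id = rep(c("c1", "c2", "t1"), each = 3),
    group = rep(c("control", "control", "test"), each = 3),
    gene = rep(c("MT1", "ACTB", "POLR2A"), 3),
    ct = c(26, 20, 20, 26, 20, 20, 28, 20, 20))
  d <- ddct(tab)
  expect_equal(d$per_sample$fold_change[d$per_sample$group == "test"], 0.25)
  expect_equal(d$group_means$mean_ddct[d$group_means$group == "control"], 0)
  # test group identical to control -> fold 1
  tab1 <- simulate_qpcr(0, noise_sd = 0, seed = 1)
  expect_equal(ddct(tab1)$group_means$mean_fold_change, c(1, 1))
  # plate-offset gauge: adding a constant to every Ct changes nothing
  tab2 <- tab; tab2$ct <- tab2$ct + 3.7
  expect_equal(ddct(tab2)$per_sample$fold_change,
               d$per_sample$fold_change, tolerance = 1e-12)
  # missing reference gene is caught
  expect_error(ddct(tab[-2, ]), "missing reference")
})

test_that("D'Agostino-Pearson omnibus matches an independent implementation", {
  # scipy.stats.normaltest implements the same K2 composition
  set.seed(121)
  x <- round(rnorm(60, 5, 2), 6)
  r <- normality_test(x)
  py <- sprintf(paste0("import numpy as np\nfrom scipy import stats\n",
                       "k2, p = stats.normaltest(np.array([%s]))\n",
                       "print(float(k2)); print(float(p))"),
                paste(sprintf("%.6f", x), collapse = ","))
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  expect_equal(r$statistic, as.numeric(out[1]), tolerance = 1e-8)
  expect_equal(r$p, as.numeric(out[2]), tolerance = 1e-8)
  expect_error(normality_test(rnorm(5)), "insufficient n")
})

test_that("normality test holds its size and detects skewed data", {
  # empirical type-I error within 2.5 points of nominal over 400 draws
  rej <- vapply(1:400, function(s) {
    set.seed(20000 + s)
    normality_test(rnorm(5000))$p <= 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.025)
  p_exp <- vapply(1:100, function(s) {
    set.seed(30000 + s)
    normality_test(rexp(200))$p
  }, 0)
  expect_gte(mean(p_exp < 0.05), 0.95)
})

test_that("two-group one-way ANOVA equals the squared pooled t", {
  dat <- data.frame(y = c(1, 2, 3, 4, 5, 6),
                    g = rep(c("A", "B"), each = 3))
  a <- anova_oneway(dat, "y", "g")
  t <- ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(a$statistic, 13.5)
  expect_equal(a$df, c(1, 4))
  expect_equal(t$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(t$df, 4)
  expect_equal(a$statistic, t$statistic^2, tolerance = 1e-10)
  # property across random draws
  for (s in 1:10) {
    set.seed(40000 + s)
    x <- rnorm(8); y <- rnorm(6, 1)
    aa <- anova_oneway(data.frame(y = c(x, y),
                                  g = rep(c("a", "b"), c(8, 6))), "y", "g")
    tt <- ttest(x, y)
    expect_equal(aa$statistic, tt$statistic^2, tolerance = 1e-10)
    expect_equal(aa$p, tt$p, tolerance = 1e-10)
  }
})

test_that("identical constants give F = 0, p = 1", {
  dat <- data.frame(y = rep(5, 9), g = rep(c("a", "b", "c"), each = 3))
  a <- anova_oneway(dat, "y", "g")
  expect_equal(a$statistic, 0)
  expect_equal(a$p, 1)
})

test_that("repeated-measures ANOVA matches the sum-of-squares oracle", {
  set.seed(131)
  n <- 9; k <- 4
  subj <- rep(sprintf("s%d", 1:n), each = k)
  cond <- rep(sprintf("c%d", 1:k), n)
  y <- rnorm(n * k) + rep(rnorm(n, sd = 2), each = k) +
    rep(c(0, 0.5, 1, 0.2), n)
  a <- anova_oneway(data.frame(y = y, g = cond, s = subj), "y", "g",
                    repeated = TRUE, subject = "s")
  o <- oracle_rm_anova(y, subj, cond)
  expect_equal(a$statistic, o$F, tolerance = 1e-8)
  expect_equal(a$df, o$df)
  expect_equal(a$p, o$p, tolerance = 1e-8)
  # incomplete design errors with the missing cell named
  expect_error(anova_oneway(data.frame(y = y, g = cond, s = subj)[-1, ],
                            "y", "g", repeated = TRUE, subject = "s"),
               "missing cells")
})

test_that("mixed two-way ANOVA matches the oracle and the published df", {
  set.seed(141)
  # balanced fixture against the hand-coded SS oracle
  n_per <- 6; G <- 3; W <- 2
  subj <- rep(sprintf("g%d_s%d", rep(1:G, each = n_per), 1:n_per), each = W)
  btw <- rep(sprintf("g%d", rep(1:G, each = n_per)), each = W)
  wtn <- rep(c("light", "dark"), G * n_per)
  y <- rnorm(length(subj)) + (btw == "g2") * 0.8 +
    (wtn == "light") * 1.1 + (btw == "g3") * (wtn == "light") * 0.9
  a <- anova_twoway_mixed(data.frame(y, subj, btw, wtn), "y", "btw",
                          "wtn", "subj")
  o <- oracle_mixed_anova(y, subj, btw, wtn)
  fa <- a$factors
  expect_equal(fa$F[fa$factor == "btw"], unname(o$F["b"]), tolerance = 1e-8)
  expect_equal(fa$F[fa$factor == "wtn"], unname(o$F["w"]), tolerance = 1e-8)
  expect_equal(fa$F[fa$factor == "btw:wtn"], unname(o$F["bw"]),
               tolerance = 1e-8)
  expect_equal(c(fa$df1[fa$factor == "btw"], fa$df2[fa$factor == "btw"]),
               o$df$b)

  # the 4-group design with n = (12, 9, 11, 10) rats gives df (3, 38)
  ns <- c(12, 9, 11, 10)
  rows <- do.call(rbind, lapply(1:4, function(g)
    do.call(rbind, lapply(seq_len(ns[g]), function(i)
      data.frame(subject = sprintf("g%d_s%d", g, i),
                 treatment = sprintf("T%d", g),
                 phase = c("light", "dark"), y = rnorm(2))))))
  r <- anova_twoway_mixed(rows, "y", "treatment", "phase", "subject")
  tr_row <- r$factors[r$factors$factor == "treatment", ]
  expect_equal(c(tr_row$df1, tr_row$df2), c(3, 38))
  int_row <- r$factors[r$factors$factor == "treatment:phase", ]
  expect_equal(c(int_row$df1, int_row$df2), c(3, 38))
})

test_that("removing the interaction component zeroes the interaction F", {
  set.seed(142)
  subj <- rep(sprintf("s%d", 1:8), each = 2)
  btw <- rep(rep(c("a", "b"), each = 4), each = 2)
  wtn <- rep(c("l", "d"), 8)
  y <- rnorm(16) + (btw == "b") * 2 + (wtn == "l") * 3
  # subtract the interaction component of the cell means (balanced
  # design): the remaining data are exactly additive, error SS intact
  cm <- tapply(y, list(btw, wtn), mean)
  int_comp <- cm - outer(rowMeans(cm), colMeans(cm), "+") + mean(cm)
  y_add <- y - int_comp[cbind(btw, wtn)]
  a <- anova_twoway_mixed(data.frame(y = y_add, subj, btw, wtn), "y",
                          "btw", "wtn", "subj")
  expect_lt(a$factors$F[a$factors$factor == "btw:wtn"], 1e-10)
})

test_that("paired and degenerate t tests follow the conventions", {
  set.seed(151)
  x <- rnorm(10)
  delta <- 0.8
  noise <- rnorm(10, sd = 0.3)
  t1 <- ttest(x + delta + noise, x, paired = TRUE)
  d <- delta + noise
  expect_equal(t1$statistic, mean(d) * sqrt(10) / sd(d), tolerance = 1e-10)
  # zero-variance identical samples: flagged p = 1 convention
  t0 <- ttest(rep(2, 5), rep(2, 5), paired = TRUE)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  expect_match(t0$note, "zero variance")
  expect_error(ttest(rep(1, 4), rep(2, 4)), "unequal means")
})

test_that("Bonferroni adjustment is capped, monotone and validated", {
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(0.5, m = 3), 1)
  expect_equal(bonferroni(c(0.2, 0.04)), c(0.4, 0.08))
  p <- sort(runif(10))
  expect_true(all(diff(bonferroni(p, m = 10)) >= 0))
  expect_true(all(bonferroni(p, m = 10) >= p))
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "smaller")
  expect_error(bonferroni(1.2), "0, 1")
})

test_that("post hoc contrasts against a reference level are Bonferroni-adjusted", {
  set.seed(161)
  dat <- data.frame(
    y = c(rnorm(8), rnorm(8, 0.2), rnorm(8, 2.5)),
    g = rep(c("vehicle", "low", "high"), each = 8))
  a <- anova_oneway(dat, "y", "g", posthoc_ref = "vehicle")
  ph <- a$posthoc
  expect_equal(nrow(ph), 2L)
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 2))
  expect_true(ph$significant[grepl("high", ph$comparison)])
})
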