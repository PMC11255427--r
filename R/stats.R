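# Relative quantification of qPCR Ct tables and the study's statistical
# battery: D'Agostino-Pearson omnibus normality test, one-way (optionally
# repeated-measures) ANOVA, mixed two-way ANOVA (between x within), two-
# tailed t tests and Bonferroni adjustment.

#' Relative expression by the 2^-ddCt method
#'
#' dCt = Ct(target) - mean Ct over the reference genes, per sample;
#' ddCt = dCt - mean dCt of the control group; fold change = 2^-ddCt.
#' Multiple reference genes are combined by the arithmetic mean of their
#' Ct values (equivalent to the geometric mean of their expression).
#'
#' @param ct a [ct_table()].
#' @param target_gene target gene name.
#' @param reference_genes one or more reference gene names; every sample
#'   must carry the target and all references.
#' @param control_group group used as the calibrator (default
#'   `"control"`).
#' @return List of class `ddct_result`: `per_sample` (sample_id, group,
#'   delta_ct, delta_delta_ct, fold_change) and `group_means`
#'   (group, mean_delta_ct, mean_fold_change). The control group's mean
#'   ddCt is 0 by construction.
#' @export
ddct <- function(ct, target_gene = "MT1",
                 reference_genes = c("ACTB", "POLR2A"),
                 control_group = "control") {
  ct <- as.data.frame(ct)
  samples <- unique(ct$sample_id)
  rows <- lapply(samples, function(s) {
    sub <- ct[ct$sample_id == s, , drop = FALSE]
    tg <- sub$ct[sub$gene == target_gene]
    refs <- sub$ct[sub$gene %in% reference_genes]
    if (length(tg) != 1L)
      stop("ddct: sample ", s, " lacks a single target-gene Ct")
    if (length(refs) != length(reference_genes))
      stop("ddct: sample ", s, " is missing reference gene(s)")
    data.frame(sample_id = s, group = sub$group[1],
               delta_ct = tg - mean(refs), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  ctrl <- per$delta_ct[per$group == control_group]
  if (!length(ctrl)) stop("ddct: empty control group '", control_group, "'")
  per$delta_delta_ct <- per$delta_ct - mean(ctrl)
  per$fold_change <- 2^(-per$delta_delta_ct)
  gm <- do.call(rbind, lapply(split(per, per$group), function(g)
    data.frame(group = g$group[1], mean_delta_ct = mean(g$delta_ct),
               mean_ddct = mean(g$delta_delta_ct),
               mean_fold_change = mean(g$fold_change),
               stringsAsFactors = FALSE)))
  rownames(gm) <- NULL
  structure(list(per_sample = per, group_means = gm),
            class = "ddct_result")
}

stat_result <- function(test, statistic, df, p, factors = NULL,
                        posthoc = NULL, note = NULL, alpha = 0.05) {
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 factors = factors, posthoc = posthoc, note = note,
                 alpha = alpha),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s\n", x$test))
  if (!is.null(x$factors)) {
    for (i in seq_len(nrow(x$factors)))
      cat(sprintf("  %-28s F(%g, %g) = %.4g, p = %.4g\n",
                  x$factors$factor[i], x$factors$df1[i], x$factors$df2[i],
                  x$factors$F[i], x$factors$p[i]))
  } else {
    cat(sprintf("  statistic = %.4g, df = %s, p = %.4g\n", x$statistic,
                paste(x$df, collapse = ", "), x$p))
  }
  if (!is.null(x$posthoc)) {
    cat("  Bonferroni post hoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the normal approximations of the sample skewness
#' (D'Agostino's Z of sqrt(b1)) and kurtosis (Anscombe-Glynn's Z of b2)
#' into K^2 = Z1^2 + Z2^2, referred to a chi-squared distribution with
#' 2 degrees of freedom.
#'
#' @param values numeric sample, `n >= 8` (the kurtosis approximation is
#'   unreliable below that).
#' @return A `stat_result` with the K^2 statistic and p-value.
#' @export
normality_test <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 8) stop("normality_test: insufficient n for omnibus test (n >= 8)")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness: D'Agostino (1970) transformation
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * asinh(y / alpha)

  # kurtosis: Anscombe & Glynn (1983) transformation
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1_b2 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrt_b1_b2 * (2 / sqrt_b1_b2 +
                               sqrt(1 + 4 / sqrt_b1_b2^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  k2 <- z1^2 + z2^2
  stat_result("D'Agostino-Pearson omnibus K2", statistic = k2, df = 2,
              p = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

extract_aov <- function(fit) {
  # flatten summary(aov) across Error strata into factor/F/df/p rows
  s <- summary(fit)
  if (inherits(fit, "aovlist")) tabs <- lapply(s, function(e) e[[1]])
  else tabs <- list(s[[1]])
  rows <- list()
  for (tab in tabs) {
    resid_df <- tab["Residuals", "Df"]
    terms <- setdiff(trimws(rownames(tab)), "Residuals")
    for (tm in terms) {
      # rownames in aov tables are padded; match by trimmed name
      i <- which(trimws(rownames(tab)) == tm)
      rows[[length(rows) + 1L]] <- data.frame(
        factor = tm, df1 = tab[i, "Df"], df2 = resid_df,
        F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' One-way ANOVA (between groups or repeated measures)
#'
#' @param data long data frame.
#' @param dv name of the dependent-variable column.
#' @param group name of the grouping/condition column.
#' @param repeated if `TRUE`, a repeated-measures (within-subject)
#'   one-way ANOVA via an `Error(subject)` stratum; requires a complete
#'   subject x condition design.
#' @param subject subject-identifier column (required when `repeated`).
#' @param posthoc_ref optional reference level (e.g. vehicle): adds
#'   Bonferroni-adjusted pairwise t tests of every other level against
#'   it (paired when `repeated`).
#' @return A `stat_result`; `$factors` holds the F/df/p row.
#' @export
anova_oneway <- function(data, dv, group, repeated = FALSE, subject = NULL,
                         posthoc_ref = NULL) {
  data <- as.data.frame(data)
  data$.y <- data[[dv]]
  data$.g <- factor(data[[group]])
  if (nlevels(data$.g) < 2) stop("anova_oneway: need >= 2 groups")
  constant_dv <- stats::var(data$.y) == 0
  if (repeated) {
    if (is.null(subject)) stop("anova_oneway: repeated design needs subject")
    data$.s <- factor(data[[subject]])
    cells <- table(data$.s, data$.g)
    if (any(cells != 1)) {
      bad <- which(cells == 0, arr.ind = TRUE)
      stop("anova_oneway: incomplete repeated design; missing cells: ",
           paste(sprintf("%s:%s", rownames(cells)[bad[, 1]],
                         colnames(cells)[bad[, 2]]), collapse = ", "))
    }
    fit <- stats::aov(.y ~ .g + Error(.s), data = data)
  } else {
    fit <- stats::aov(.y ~ .g, data = data)
  }
  fac <- extract_aov(fit)
  fac$factor[fac$factor == ".g"] <- group
  # identical constants everywhere: all SS are round-off; F = 0, p = 1
  if (constant_dv) { fac$F[1] <- 0; fac$p[1] <- 1 }
  ph <- NULL
  if (!is.null(posthoc_ref)) {
    others <- setdiff(levels(data$.g), posthoc_ref)
    praw <- numeric(0); comp <- character(0)
    for (lv in others) {
      if (repeated) {
        d <- data[order(data$.s), ]
        xs <- d$.y[d$.g == lv]; ys <- d$.y[d$.g == posthoc_ref]
        tt <- stats::t.test(xs, ys, paired = TRUE)
      } else {
        tt <- stats::t.test(data$.y[data$.g == lv],
                            data$.y[data$.g == posthoc_ref],
                            var.equal = TRUE)
      }
      praw <- c(praw, tt$p.value)
      comp <- c(comp, sprintf("%s vs %s", lv, posthoc_ref))
    }
    padj <- bonferroni(praw, m = length(praw))
    ph <- data.frame(comparison = comp, p_raw = praw, p_adj = padj,
                     significant = padj < 0.05, stringsAsFactors = FALSE)
  }
  stat_result(if (repeated) "one-way repeated-measures ANOVA"
              else "one-way ANOVA",
              statistic = fac$F[1], df = c(fac$df1[1], fac$df2[1]),
              p = fac$p[1], factors = fac, posthoc = ph)
}

#' Mixed two-way ANOVA (between-subject x within-subject)
#'
#' The design used for treatment x phase-of-day analyses: one
#' between-subject factor (treatment group) and one within-subject
#' factor (e.g. light vs dark phase), each subject measured at every
#' within level. Implemented with subject Error strata; no sphericity
#' correction is applied (a two-level within factor needs none).
#'
#' @param data long data frame.
#' @param dv dependent-variable column name.
#' @param between between-subject factor column name.
#' @param within within-subject factor column name.
#' @param subject subject-identifier column name.
#' @return A `stat_result` whose `$factors` table carries the between
#'   main effect, within main effect and interaction (F, df pair, p).
#' @export
anova_twoway_mixed <- function(data, dv, between, within, subject) {
  data <- as.data.frame(data)
  data$.y <- data[[dv]]
  data$.b <- factor(data[[between]])
  data$.w <- factor(data[[within]])
  data$.s <- factor(data[[subject]])
  if (nlevels(data$.b) < 2 || nlevels(data$.w) < 2)
    stop("anova_twoway_mixed: each factor needs >= 2 levels")
  cells <- table(data$.s, data$.w)
  if (any(cells != 1))
    stop("anova_twoway_mixed: every subject needs exactly one value per ",
         "within level")
  fit <- stats::aov(.y ~ .b * .w + Error(.s), data = data)
  fac <- extract_aov(fit)
  fac$factor[fac$factor == ".b"] <- between
  fac$factor[fac$factor == ".w"] <- within
  fac$factor[fac$factor == ".b:.w"] <- paste0(between, ":", within)
  stat_result("two-way mixed ANOVA (between x within)",
              statistic = fac$F[fac$factor ==
                                  paste0(between, ":", within)],
              df = NA, p = fac$p[fac$factor == paste0(between, ":", within)],
              factors = fac)
}

#' Two-tailed t test
#'
#' Sign convention: the statistic is computed for the first argument
#' minus the second. Unpaired tests pool the variance (classical
#' Student's t). The degenerate case of zero variance in both samples
#' with equal means (or zero-variance paired differences) is reported as
#' `t = 0, p = 1` with a note instead of an error.
#'
#' @param x,y numeric samples (equal length if `paired`).
#' @param paired paired or independent samples.
#' @return A `stat_result` with `statistic`, `df`, `p`.
#' @export
ttest <- function(x, y, paired = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    stop("ttest: need n >= 2 per sample")
  if (paired && length(x) != length(y))
    stop("ttest: paired samples must have equal length")
  degenerate <- if (paired) stats::var(x - y) == 0 else
    stats::var(x) == 0 && stats::var(y) == 0
  if (degenerate) {
    equal <- if (paired) all(x == y) else mean(x) == mean(y)
    if (equal)
      return(stat_result(if (paired) "paired t test" else "unpaired t test",
                         statistic = 0,
                         df = if (paired) length(x) - 1 else
                           length(x) + length(y) - 2,
                         p = 1, note = "zero variance; p = 1 by convention"))
    stop("ttest: zero variance with unequal means (t undefined)")
  }
  tt <- stats::t.test(x, y, paired = paired, var.equal = !paired)
  stat_result(if (paired) "paired t test" else "unpaired t test",
              statistic = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value)
}

#' Bonferroni adjustment
#'
#' `adjusted = min(1, p * m)` for an explicit family size `m`.
#'
#' @param pvalues raw p-values in `[0, 1]`.
#' @param m family size; must be at least the number of p-values
#'   supplied.
#' @return Adjusted p-values (monotone, never below the raw values).
#' @export
bonferroni <- function(pvalues, m = length(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1))
    stop("bonferroni: p-values must lie in [0, 1]")
  if (m < length(pvalues))
    stop("bonferroni: m smaller than the number of comparisons")
  pmin(1, pvalues * m)
}
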