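.test_result <- function(feature, groups, statistic, df, p, means = NULL,
                         ses = NULL, method = "") {
  data.frame(feature = feature, groups = paste(groups, collapse = " vs "),
             statistic = statistic, df = df, p_value = p,
             mean_a = means[1] %||% NA_real_, se_a = ses[1] %||% NA_real_,
             mean_b = means[2] %||% NA_real_, se_b = ses[2] %||% NA_real_,
             method = method, stringsAsFactors = FALSE)
}

#' Kolmogorov-Smirnov normality screen (Lilliefors)
#'
#' KS distance of the standardized sample against the standard normal with
#' plug-in mean and SD. Because the parameters are estimated from the same
#' sample, the naive KS null distribution is anti-conservative, so the
#' p-value is calibrated by Monte-Carlo simulation of normal samples of the
#' same size.
#'
#' @param x numeric sample (>= 3 finite values, non-degenerate).
#' @param mc number of Monte-Carlo null draws.
#' @param seed optional seed for the calibration draws.
#' @return one-row data.frame with the D statistic and calibrated p-value.
#' @export
ks_normality <- function(x, mc = 2000, seed = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite values")
  if (stats::sd(x) == 0) stop("degenerate sample: zero variance")
  D <- .lilliefors_d(x)
  Dnull <- .with_seed(seed, vapply(seq_len(mc), function(i)
    .lilliefors_d(stats::rnorm(n)), 0))
  p <- (1 + sum(Dnull >= D)) / (mc + 1)
  .test_result("", "normality", D, NA_real_, p,
               method = sprintf("Lilliefors KS, MC p (%d draws)", mc))
}

.lilliefors_d <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  Fz <- stats::pnorm(z)
  max(max(Fz - (seq_len(n) - 1) / n), max(seq_len(n) / n - Fz))
}

#' Two-group t-test on a feature matrix
#'
#' Student's pooled-variance t-test by default (the published analysis);
#' Welch's unequal-variance variant behind `variant = "welch"`. Identical
#' degenerate samples return t = 0, p = 1.
#'
#' @param mat feature matrix as returned by [direct_feature_matrix()] (must
#'   contain `group` and the feature column).
#' @param feature feature (column) name.
#' @param group_a,group_b arms to compare.
#' @param variant `"student"` (pooled) or `"welch"`.
#' @return one-row data.frame (statistic, df, two-sided p, group means/SEs).
#' @export
two_group_ttest <- function(mat, feature, group_a, group_b,
                            variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (!feature %in% names(mat)) stop("unknown feature '", feature, "'")
  x <- mat[[feature]][mat$group == group_a]
  y <- mat[[feature]][mat$group == group_b]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 animals in each compared group")
  ms <- c(mean(x), mean(y))
  ses <- c(stats::sd(x) / sqrt(length(x)), stats::sd(y) / sqrt(length(y)))
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
    ## both groups constant: no variance to test against
    if (ms[1] == ms[2])
      return(.test_result(feature, c(group_a, group_b), 0,
                          length(x) + length(y) - 2, 1, ms, ses,
                          paste0(variant, " t")))
    stop("degenerate comparison: zero variance with unequal means")
  }
  tt <- stats::t.test(x, y, var.equal = (variant == "student"))
  .test_result(feature, c(group_a, group_b), unname(tt$statistic),
               unname(tt$parameter), tt$p.value, ms, ses,
               paste0(variant, " t"))
}

#' Two-group t-test from summary statistics
#'
#' Re-tests published rows reported as mean, SE and n without raw data.
#'
#' @param mean_a,se_a,n_a,mean_b,se_b,n_b group summaries (SE of the mean).
#' @param variant `"student"` (pooled) or `"welch"`.
#' @return one-row data.frame as [two_group_ttest()].
#' @export
ttest_from_summary <- function(mean_a, se_a, n_a, mean_b, se_b, n_b,
                               variant = c("student", "welch")) {
  variant <- match.arg(variant)
  s2a <- se_a^2 * n_a; s2b <- se_b^2 * n_b     # sample variances
  if (variant == "student") {
    sp2 <- ((n_a - 1) * s2a + (n_b - 1) * s2b) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    se <- sqrt(se_a^2 + se_b^2)
    df <- (se_a^2 + se_b^2)^2 /
      (se_a^4 / (n_a - 1) + se_b^4 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  .test_result("", c("a", "b"), t, df, 2 * stats::pt(-abs(t), df),
               c(mean_a, mean_b), c(se_a, se_b),
               paste0(variant, " t (summary)"))
}

#' Paired left/right asymmetry test
#'
#' Paired t-test on the within-animal left-minus-right differences of two
#' features inside one experimental arm.
#'
#' @param mat feature matrix with `group` and both feature columns.
#' @param left_feature,right_feature paired column names.
#' @param group arm to test.
#' @return one-row data.frame.
#' @export
paired_asymmetry_test <- function(mat, left_feature, right_feature, group) {
  for (f in c(left_feature, right_feature))
    if (!f %in% names(mat)) stop("unknown feature '", f, "'")
  sel <- mat$group == group
  L <- mat[[left_feature]][sel]; R <- mat[[right_feature]][sel]
  if (any(!is.finite(L)) || any(!is.finite(R)))
    stop("pairing error: missing values in paired features")
  d <- L - R
  n <- length(d)
  if (n < 2) stop("need >= 2 animals")
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(.test_result(paste0(left_feature, "-", right_feature),
                          group, 0, n - 1, 1, c(mean(L), mean(R)),
                          c(stats::sd(L), stats::sd(R)) / sqrt(n),
                          "paired t"))
    stop("degenerate-variance error: constant nonzero L-R offset")
  }
  tt <- stats::t.test(L, R, paired = TRUE)
  .test_result(paste0(left_feature, "-", right_feature), group,
               unname(tt$statistic), unname(tt$parameter), tt$p.value,
               c(mean(L), mean(R)),
               c(stats::sd(L), stats::sd(R)) / sqrt(n), "paired t")
}

#' Two-way ANOVA on discriminant scores
#'
#' Tests pathology (control vs diabetes) and experiment duration (1 vs 2
#' months) on each score axis. The default model is additive (no
#' interaction), which with 31 animals yields denominator df 28; partial
#' (Type II) F statistics come from dropping each term from the additive
#' fit. The pathology x duration interaction can be reported from a separate
#' full-factorial fit and is flagged as such.
#'
#' @param scores numeric vector or matrix/data.frame of score axes
#'   (columns named, e.g. `Y1`, `Y2`).
#' @param pathology factor/character: `"control"` or `"diabetes"` per animal.
#' @param duration factor/character or numeric: 1 or 2 (months).
#' @param interaction also report the interaction term.
#' @return data.frame with `axis`, `effect`, `F`, `df1`, `df2`, `p_value`.
#' @export
anova_on_scores <- function(scores, pathology, duration,
                            interaction = FALSE) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("Y", seq_len(ncol(scores)))
  pathology <- factor(pathology); duration <- factor(duration)
  if (nlevels(pathology) != 2 || nlevels(duration) != 2)
    stop("pathology and duration must each have exactly 2 levels")
  if (any(table(pathology, duration) < 2))
    stop("design error: every pathology x duration cell needs >= 2 animals")
  out <- list()
  for (ax in colnames(scores)) {
    y <- scores[, ax]
    dat <- data.frame(y = y, pathology = pathology, duration = duration)
    fit <- stats::lm(y ~ pathology + duration, data = dat)
    if (all(abs(y - mean(y)) < 1e-12 * max(1, abs(mean(y))))) {
      for (eff in c("pathology", "duration"))
        out[[length(out) + 1L]] <- data.frame(
          axis = ax, effect = eff, F = 0, df1 = 1,
          df2 = fit$df.residual, p_value = 1)
      next
    }
    d1 <- stats::drop1(fit, test = "F")
    for (eff in c("pathology", "duration")) {
      i <- match(eff, rownames(d1))
      out[[length(out) + 1L]] <- data.frame(
        axis = ax, effect = eff,
        F = if (is.na(d1$`F value`[i])) 0 else d1$`F value`[i],
        df1 = d1$Df[i], df2 = fit$df.residual,
        p_value = if (is.na(d1$`Pr(>F)`[i])) 1 else d1$`Pr(>F)`[i])
    }
    if (interaction) {
      full <- stats::lm(y ~ pathology * duration, data = dat)
      an <- stats::anova(full)
      i <- match("pathology:duration", rownames(an))
      out[[length(out) + 1L]] <- data.frame(
        axis = ax, effect = "pathology:duration (full-factorial fit)",
        F = if (is.na(an$`F value`[i])) 0 else an$`F value`[i],
        df1 = an$Df[i], df2 = full$df.residual,
        p_value = if (is.na(an$`Pr(>F)`[i])) 1 else an$`Pr(>F)`[i])
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
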