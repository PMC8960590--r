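#' @title Statistical layer
#' @description Thin, auditable wrappers around the standard tests the
#'   mapping and nanostructure analyses call for, each returning a uniform
#'   `stat_result` record. The post-hoc naming follows the source protocol's
#'   "Sidak" (for three-genotype designs) and Tukey (two-group designs)
#'   conventions.
#' @name statistics
NULL

stat_result <- function(test_name, statistic, df, p_value, direction = NA,
                        table = NULL, note = NULL, statistic_aux = NA) {
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, direction = direction, table = table,
                 note = note, statistic_aux = statistic_aux),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(x$df, collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g\n",
              x$test_name, x$statistic, dfs, x$p_value))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  if (!is.null(x$table)) print(x$table)
  invisible(x)
}

#' Two-way ANOVA (genotype x region)
#'
#' Fits the two-factor crossed model on subject-level observations (one
#' value per subject per region — the mouse, not the punctum, is the
#' analysis unit) and reports F and p for both main effects and the
#' interaction. Type-II sums of squares; on the balanced designs the
#' mapping produces these coincide with the sequential decomposition.
#'
#' @param data data frame of observations.
#' @param value name of the response column.
#' @param factor_a,factor_b names of the two factor columns (defaults
#'   `"genotype"` and `"region"`).
#' @return A data frame of class `anova_result` with one row per effect
#'   (`factor_a`, `factor_b`, interaction): `df1`, `df2`, `F`, `p`.
#' @export
two_way_anova <- function(data, value, factor_a = "genotype",
                          factor_b = "region") {
  stopifnot(is.data.frame(data),
            all(c(value, factor_a, factor_b) %in% names(data)))
  a <- factor(data[[factor_a]]); b <- factor(data[[factor_b]])
  if (nlevels(a) < 2 || nlevels(b) < 2) {
    stop("each factor needs at least 2 levels")
  }
  cells <- table(a, b)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop("interaction inestimable; empty cells: ",
         paste(sprintf("(%s, %s)", rownames(cells)[bad[, 1]],
                       colnames(cells)[bad[, 2]]), collapse = ", "))
  }
  df <- data.frame(y = data[[value]], A = a, B = b)
  # one observation per cell saturates the interaction; fit the additive
  # model and report main effects only (the standard unreplicated layout)
  additive <- all(cells == 1)
  fit <- stats::lm(if (additive) y ~ A + B else y ~ A * B, data = df)
  rss <- sum(stats::residuals(fit)^2)
  effects <- c(factor_a, factor_b,
               if (!additive) paste0(factor_a, ":", factor_b))
  keys <- c("A", "B", if (!additive) "A:B")
  if (rss > 1e-10 * max(1, sum(df$y^2))) {
    an <- car::Anova(fit, type = 2)
    df2 <- an["Residuals", "Df"]
    out <- data.frame(
      effect = effects,
      df1 = an[keys, "Df"], df2 = df2,
      F = an[keys, "F value"], p = an[keys, "Pr(>F)"])
  } else {
    # zero residual variance: F = 0 / p = 1 where the effect SS is also
    # zero (identical cell means), degenerate F = Inf / p = 0 otherwise
    an <- suppressWarnings(stats::anova(fit))
    ss <- an[keys, "Sum Sq"]
    out <- data.frame(
      effect = effects, df1 = an[keys, "Df"],
      df2 = an["Residuals", "Df"],
      F = ifelse(ss < 1e-10, 0, Inf),
      p = ifelse(ss < 1e-10, 1, 0))
  }
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Pairwise post-hoc comparisons (Sidak or Tukey)
#'
#' Sidak: pooled-variance pairwise t-tests with family-wise adjustment
#' `1 - (1 - p)^m` over the m comparisons. Tukey: the studentized-range
#' test on the one-way layout of the grouping factor.
#'
#' @param data data frame.
#' @param value response column name.
#' @param grouping factor column name.
#' @param method `"sidak"` or `"tukey"`.
#' @return Data frame: `group1`, `group2`, `estimate` (mean difference
#'   group2 - group1), `p_raw` (Sidak only), `p_adj`.
#' @export
posthoc_pairwise <- function(data, value, grouping,
                             method = c("sidak", "tukey")) {
  method <- match.arg(method)
  g <- factor(data[[grouping]]); y <- data[[value]]
  if (nlevels(g) < 2) stop("post-hoc comparison needs >= 2 groups")
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  m <- ncol(pairs)
  if (method == "sidak") {
    rows <- lapply(seq_len(m), function(k) {
      xi <- y[g == pairs[1, k]]; yi <- y[g == pairs[2, k]]
      tt <- stats::t.test(yi, xi, var.equal = TRUE)
      data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
                 estimate = mean(yi) - mean(xi),
                 p_raw = tt$p.value,
                 p_adj = 1 - (1 - tt$p.value)^m)
    })
    out <- do.call(rbind, rows)
  } else {
    fit <- stats::aov(y ~ g)
    tk <- stats::TukeyHSD(fit)$g
    cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    out <- data.frame(group1 = cmp[, 2], group2 = cmp[, 1],
                      estimate = tk[, "diff"], p_raw = NA_real_,
                      p_adj = tk[, "p adj"])
  }
  rownames(out) <- NULL
  attr(out, "method") <- method
  out
}

#' Pearson chi-squared test on an r x c contingency table
#'
#' `chi^2 = sum (O - E)^2 / E` with `df = (r - 1)(c - 1)`, no continuity
#' correction (matching the subtype-frequency comparisons).
#'
#' @param contingency numeric matrix of counts.
#' @return A `stat_result`.
#' @export
chi_squared <- function(contingency) {
  contingency <- as.matrix(contingency)
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0)) {
    stop("contingency table has an all-zero row or column")
  }
  res <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  if (any(res$expected <= 0)) stop("all expected counts must be positive")
  stat_result("Pearson chi-squared", unname(res$statistic),
              unname(res$parameter), res$p.value,
              table = as.data.frame(as.table(res$expected)))
}

#' Two-sample t-test
#'
#' Student's pooled-variance test by default (df = n1 + n2 - 2, the
#' convention the reported degrees of freedom follow); set `welch = TRUE`
#' for the unequal-variance form.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param welch use Welch's correction instead of pooling.
#' @return A `stat_result` with `direction` = sign of `mean(x) - mean(y)`.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 observations per sample")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      stop("t statistic undefined: both samples constant and equal (zero variance)")
    }
    stop("t statistic undefined: zero variance in both samples")
  }
  res <- stats::t.test(x, y, var.equal = !welch)
  stat_result(if (welch) "Welch two-sample t" else "Two-sample t (pooled)",
              unname(res$statistic), unname(res$parameter), res$p.value,
              direction = sign(mean(x) - mean(y)))
}

#' Pearson correlation
#'
#' `r` with the two-sided t-approximation p-value on n - 2 df.
#'
#' @param x,y numeric vectors (>= 3 pairs).
#' @return A `stat_result`; the t statistic is `statistic`, `r` is carried
#'   in `statistic_aux`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("correlation needs >= 3 paired observations")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in x or y")
  }
  res <- stats::cor.test(x, y, method = "pearson")
  stat_result("Pearson correlation", unname(res$statistic),
              unname(res$parameter), res$p.value,
              direction = sign(unname(res$estimate)),
              statistic_aux = unname(res$estimate))
}

#' Shapiro-Wilk normality test
#' @param x numeric vector (3 to 5000 observations).
#' @return A `stat_result` (`statistic` is W).
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3) stop("Shapiro-Wilk needs >= 3 observations")
  res <- stats::shapiro.test(x)
  stat_result("Shapiro-Wilk", unname(res$statistic), NA, res$p.value)
}
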