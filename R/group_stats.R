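test_result <- function(statistic, df, p_value, test_name,
                        correction_applied = FALSE, note = "") {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 test_name = test_name, correction_applied = correction_applied,
                 note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g%s\n", x$test_name,
              x$statistic, dfs, x$p_value,
              if (x$correction_applied) " (df-corrected)" else ""))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Paired t-test between two ROI measurements
#'
#' Standard paired t-test on within-subject differences, used e.g. to
#' compare kinetic parameters between WMH and NAWM within the same
#' participants.  Degenerate difference vectors (zero variance) are
#' flagged rather than erroring: identical inputs give t = 0, p = 1;
#' constant nonzero differences give an infinite t.
#'
#' @param x,y Paired numeric vectors (same subjects, same order), n >= 3.
#' @return A `test_result`.
#' @export
paired_ttest <- function(x, y) {
  stop_if_not(length(x) == length(y) && length(x) >= 3,
              "paired vectors of equal length >= 3 required")
  d <- x - y
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
    if (mean(d) == 0)
      return(test_result(0, length(d) - 1, 1, "paired t-test",
                         note = "zero variance, zero mean difference"))
    return(test_result(sign(mean(d)) * Inf, length(d) - 1, 0, "paired t-test",
                       note = "zero variance of differences: degenerate t"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
              "paired t-test")
}

#' Levene's test for equality of variances (mean-centered)
#'
#' One-way ANOVA on absolute deviations from the group means (the
#' mean-centering variant, matching common statistical software
#' defaults; Brown-Forsythe median centering is available via `center`).
#'
#' @param x,y Numeric vectors.
#' @param center `"mean"` (default) or `"median"`.
#' @return A `test_result` with the F statistic and (df1, df2).
#' @export
levene_test <- function(x, y, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  v <- c(x, y)
  cf <- if (center == "mean") mean else stats::median
  lt <- car::leveneTest(v, g, center = cf)
  test_result(lt[1, "F value"], c(lt[1, "Df"], lt[2, "Df"]),
              lt[1, "Pr(>F)"], sprintf("Levene (%s-centered)", center))
}

#' Independent-samples t-test with Levene-gated Welch correction
#'
#' Tests equality of variances with Levene's test (mean-centered) at
#' `levene_alpha`; if the assumption is violated the Welch-Satterthwaite
#' degrees-of-freedom correction is applied ("equal variances not
#' assumed"), otherwise the pooled-variance Student t-test is used.
#'
#' @param x,y Numeric vectors, n >= 2 per group.
#' @param levene_alpha Gate level (default 0.05).
#' @return A `test_result`; `correction_applied` records the Welch gate.
#' @export
independent_ttest <- function(x, y, levene_alpha = 0.05) {
  stop_if_not(length(x) >= 2 && length(y) >= 2, "need n >= 2 per group")
  lev <- levene_test(x, y, center = "mean")
  welch <- is.finite(lev$p_value) && lev$p_value < levene_alpha
  tt <- stats::t.test(x, y, var.equal = !welch)
  test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
              if (welch) "Welch t-test" else "pooled t-test",
              correction_applied = welch)
}

#' Pearson correlation between regional CBF and a kinetic parameter
#'
#' @param cbf_values,param_values Paired numeric vectors, n >= 3.
#' @return A `test_result` with the correlation in `statistic` and extra
#'   element `r`.
#' @export
cbf_kinetics_correlation <- function(cbf_values, param_values) {
  stop_if_not(length(cbf_values) == length(param_values) &&
                length(cbf_values) >= 3, "paired vectors of length >= 3 required")
  if (stats::sd(cbf_values) == 0 || stats::sd(param_values) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  ct <- stats::cor.test(cbf_values, param_values, method = "pearson")
  out <- test_result(unname(ct$estimate), unname(ct$parameter), ct$p.value,
                     "Pearson correlation")
  out$r <- unname(ct$estimate)
  out$t <- unname(ct$statistic)
  out
}

#' Two-way fixed-effects ANOVA (group x region)
#'
#' Fixed-effects ANOVA with region and group as factors, using Type II
#' sums of squares so that unbalanced designs (e.g. unequal numbers of
#' cases per group) are handled sensibly.  By default the group x region
#' interaction is included.  With every cell identical the F statistics
#' are reported as 0 (no effect, no residual variation).
#'
#' @param df Data frame with columns `value`, `group`, `region`.
#' @param include_interaction Include the interaction term.
#' @return Named list of `test_result`s (`group`, `region`, and
#'   `interaction` when requested); each `df` is (effect df, error df).
#' @export
two_way_anova <- function(df, include_interaction = TRUE) {
  stop_if_not(all(c("value", "group", "region") %in% names(df)),
              "df must have value, group, region columns")
  df$group <- factor(df$group)
  df$region <- factor(df$region)
  stop_if_not(nlevels(df$group) >= 2 && nlevels(df$region) >= 2,
              "need at least 2 groups and 2 regions")
  cells <- table(df$group, df$region)
  if (include_interaction && any(cells == 0))
    stop("empty cell: interaction not estimable", call. = FALSE)
  form <- if (include_interaction) value ~ group * region else value ~ group + region
  if (stats::var(df$value) < 1e-24) {
    # all observations identical: no effect and no residual variation
    n <- nrow(df)
    dfs <- c(group = nlevels(df$group) - 1, region = nlevels(df$region) - 1)
    if (include_interaction)
      dfs["interaction"] <- dfs[["group"]] * dfs[["region"]]
    err_df <- n - 1 - sum(dfs)
    out <- lapply(names(dfs), function(tm)
      test_result(0, c(dfs[[tm]], err_df), 1, sprintf("ANOVA %s", tm),
                  note = "degenerate: constant response"))
    names(out) <- names(dfs)
    return(out)
  }
  fit <- stats::lm(form, data = df)
  av <- car::Anova(fit, type = 2)
  err_df <- av["Residuals", "Df"]
  err_ss <- av["Residuals", "Sum Sq"]
  one <- function(term) {
    ss <- av[term, "Sum Sq"]; d1 <- av[term, "Df"]
    if (ss < 1e-12) return(test_result(0, c(d1, err_df), 1,
                                       sprintf("ANOVA %s", term),
                                       note = "zero effect sum of squares"))
    Fv <- (ss / d1) / (err_ss / err_df)
    test_result(Fv, c(d1, err_df), stats::pf(Fv, d1, err_df, lower.tail = FALSE),
                sprintf("ANOVA %s", term))
  }
  out <- list(group = one("group"), region = one("region"))
  if (include_interaction) out$interaction <- one("group:region")
  out
}

#' Summarize kinetic parameters across a cohort
#'
#' Runs the paired WMH-vs-NAWM comparisons for each kinetic parameter of
#' interest on a tidy fit table (excluded rows dropped), the canonical
#' PET contrast of the pipeline.
#'
#' @param fit_table Data frame from [fits_to_table()], after
#'   [apply_exclusions()]; needs columns `subject`, `roi` and the
#'   parameter columns.
#' @param params Parameters to compare (default VT, Vb, K1, Kb).
#' @param roi_a,roi_b The two ROIs compared (paired by subject).
#' @return Data frame: parameter, mean_a, mean_b, t, df, p.
#' @export
paired_roi_comparison <- function(fit_table, params = c("VT", "Vb", "K1", "Kb"),
                                  roi_a = "WMH", roi_b = "NAWM") {
  if (!is.null(fit_table$excluded))
    fit_table <- fit_table[!fit_table$excluded, , drop = FALSE]
  a <- fit_table[fit_table$roi == roi_a, , drop = FALSE]
  b <- fit_table[fit_table$roi == roi_b, , drop = FALSE]
  common <- intersect(a$subject, b$subject)
  a <- a[match(common, a$subject), , drop = FALSE]
  b <- b[match(common, b$subject), , drop = FALSE]
  rows <- lapply(params, function(p) {
    x <- a[[p]]; y <- b[[p]]
    ok <- !is.na(x) & !is.na(y)
    tr <- paired_ttest(x[ok], y[ok])
    data.frame(parameter = p, n = sum(ok), mean_a = mean(x[ok]),
               mean_b = mean(y[ok]), t = tr$statistic, df = tr$df,
               p = tr$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", roi_a)
  names(out)[names(out) == "mean_b"] <- paste0("mean_", roi_b)
  out
}
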