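# Common result container for the clinical comparisons.
test_result <- function(statistic, df, p, method) {
  structure(list(statistic = statistic, df = df, p_two_tailed = p,
                 method = method),
            class = "wm_test_result")
}

#' @export
print.wm_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, df = %.4g, two-tailed p = %.4g\n",
              x$method, x$statistic, x$df, x$p_two_tailed))
  invisible(x)
}

#' Two-sample t-test from printed summary statistics
#'
#' Works directly from per-group mean, SD and n, so published summary tables
#' can be desk-checked. The pooled variant uses
#' `sp^2 = ((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2)` with
#' `df = nA + nB - 2`; the Welch variant uses the unequal-variance statistic
#' with Welch-Satterthwaite degrees of freedom. Two-tailed p from the t
#' distribution.
#'
#' @param mean_a,sd_a,n_a group A summary (sd >= 0, n >= 2).
#' @param mean_b,sd_b,n_b group B summary.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A test result with `statistic`, `df`, `p_two_tailed`, `method`.
#'   When both SDs are zero and the means are equal, the statistic is
#'   undefined and returned as `NA` with method flagged `"-undefined"`.
#' @export
ttest_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                               variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (sd_a < 0 || sd_b < 0) stop("standard deviations must be non-negative")
  if (n_a < 2 || n_b < 2) stop("each group needs n >= 2")
  if (variant == "pooled") {
    df <- n_a + n_b - 2
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    method <- "pooled-t"
  } else {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
    method <- "welch-t"
  }
  if (se == 0) {
    if (mean_a == mean_b) {
      return(test_result(NA_real_, df, NA_real_,
                         paste0(method, "-undefined")))
    }
    return(test_result(sign(mean_a - mean_b) * Inf, df, 0, method))
  }
  tv <- (mean_a - mean_b) / se
  test_result(tv, df, 2 * pt(-abs(tv), df), method)
}

#' Two-sample t-test from raw samples
#'
#' Equals [ttest_from_summary()] applied to the samples' own mean, SD and n.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @param variant `"pooled"` or `"welch"`.
#' @return A test result, as [ttest_from_summary()].
#' @export
ttest_from_samples <- function(x, y, variant = c("pooled", "welch")) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  ttest_from_summary(mean(x), sd(x), length(x),
                     mean(y), sd(y), length(y), variant = variant)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Defaults to no continuity correction (the convention that reproduces the
#' reference sex comparison); Yates' correction is available via `yates`.
#'
#' @param counts 2x2 numeric matrix of counts with all marginals positive.
#' @param yates apply the continuity correction.
#' @return A test result (`method = "chi-square"`, df = 1).
#' @export
chisq_2x2 <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  if (!identical(dim(counts), c(2L, 2L))) stop("`counts` must be 2x2")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("all marginals must be positive")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = yates))
  test_result(unname(ct$statistic), unname(ct$parameter),
              unname(ct$p.value), "chi-square")
}

#' Pearson correlation with a two-tailed p-value
#'
#' p from `t = r * sqrt((n - 2) / (1 - r^2))` with `df = n - 2`. Pairs with
#' missing values are dropped.
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs, non-zero
#'   variances).
#' @return A test result with `statistic = r`, `df = n - 2`,
#'   `p_two_tailed`, `method = "pearson-r"`.
#' @export
pearson_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) {
    return(test_result(NA_real_, length(x) - 2, NA_real_,
                       "pearson-r-undefined"))
  }
  ct <- cor.test(x, y, method = "pearson")
  test_result(unname(ct$estimate), unname(ct$parameter),
              unname(ct$p.value), "pearson-r")
}

#' Follow-up event rate among subjects still enrolled
#'
#' @param events event count (`<= enrolled - dropouts`).
#' @param enrolled enrolled subjects.
#' @param dropouts subjects lost to follow-up (`< enrolled`).
#' @return percentage `100 * events / (enrolled - dropouts)`.
#' @export
followup_rate <- function(events, enrolled, dropouts) {
  if (dropouts >= enrolled) stop("`dropouts` must be smaller than `enrolled`")
  at_risk <- enrolled - dropouts
  if (events < 0 || events > at_risk) {
    stop("`events` must lie in [0, enrolled - dropouts]")
  }
  100 * events / at_risk
}

#' Desk-check group comparisons from the reference summary table
#'
#' Runs pooled and Welch t-tests side by side on every continuous row of
#' [table1_summaries()], reporting both p-values (which variant the original
#' software used per row is not recoverable, so both are shown).
#'
#' @return data.frame with `variable`, `t_pooled`, `p_pooled`, `t_welch`,
#'   `p_welch`.
#' @export
table1_tests <- function() {
  ref <- table1_summaries()
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    p <- ttest_from_summary(ref$patient_mean[i], ref$patient_sd[i],
                            ref$patient_n[i], ref$control_mean[i],
                            ref$control_sd[i], ref$control_n[i], "pooled")
    w <- ttest_from_summary(ref$patient_mean[i], ref$patient_sd[i],
                            ref$patient_n[i], ref$control_mean[i],
                            ref$control_sd[i], ref$control_n[i], "welch")
    data.frame(variable = ref$variable[i],
               t_pooled = p$statistic, p_pooled = p$p_two_tailed,
               t_welch = w$statistic, p_welch = w$p_two_tailed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
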