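#' Shapiro-Wilk normality test
#'
#' Royston's approximation of W and its p-value (via `stats::shapiro.test`),
#' with the explicit preconditions of the assay decision chain: sample size
#' in `[3, 5000]` and a non-constant sample.
#'
#' @param x numeric sample.
#' @return List `W`, `p`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 5000)
    stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", length(x))
  if (sd(x) == 0) stopf("Shapiro-Wilk is undefined for a constant sample")
  sw <- shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' F-test for homogeneity of variance
#'
#' `F = var(x) / var(y)` with a two-sided p-value from the F distribution
#' on `(n_x - 1, n_y - 1)` degrees of freedom.
#'
#' @param x,y numeric samples (n >= 2, non-zero variances).
#' @return List `F`, `df`, `p`.
#' @export
f_var_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stopf("F-test requires n >= 2 per group")
  if (var(x) == 0 || var(y) == 0)
    stopf("F-test is undefined for zero-variance samples")
  ft <- var.test(x, y)
  list(F = unname(ft$statistic), df = unname(ft$parameter), p = ft$p.value)
}

#' One-tailed two-sample t-test (Student or Welch)
#'
#' Tests `mean(x) > mean(y)`.  The Student variant pools the variance with
#' `n_x + n_y - 2` degrees of freedom; the Welch variant uses the
#' Welch-Satterthwaite approximation.
#'
#' @param x,y numeric samples (n >= 2).
#' @param kind `"student"` or `"welch"`.
#' @return List `t`, `df`, `p` (one-tailed).
#' @export
one_tailed_t <- function(x, y, kind = c("student", "welch")) {
  kind <- match.arg(kind)
  if (length(x) < 2 || length(y) < 2) stopf("t-test requires n >= 2 per group")
  if (sd(x) == 0 && sd(y) == 0) stopf("t-test is undefined: both samples constant")
  tt <- t.test(x, y, alternative = "greater", var.equal = kind == "student")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Significance of feeding against fixed controls
#'
#' The assay decision chain, per strain x nutrient condition: Shapiro-Wilk
#' on each treatment arm's per_delta values (failures are recorded and
#' warned about, not fatal: triplicates give the test almost no power),
#' an F-test for homogeneity of variance between the live-prey arm and the
#' fixed control, then a one-tailed Student's t-test (or Welch's when the
#' F-test rejects homogeneity at `alpha`) of live > control, significant at
#' `p <= alpha`.  Groups missing either arm are skipped with a warning.
#'
#' @param results a [feeding_results()] data.frame covering the `ct` and
#'   `control` treatments.
#' @param ct treatment label of the live-prey arm.
#' @param control treatment label of the fixed-control arm.
#' @param alpha significance threshold (used for every test in the chain).
#' @param pooled_control use all control per_delta values (pooled across
#'   strains/conditions) as the comparison arm.
#' @return A `stat_report` data.frame: strain, nutrient, n per arm,
#'   shapiro W/p per arm, F and its p, chosen test, t, df, one-tailed p,
#'   significant.
#' @export
feeding_significance <- function(results, ct = "CT", control = "CT_PFA",
                                 alpha = 0.05, pooled_control = FALSE) {
  pooled <- if (pooled_control)
    results$per_delta[results$treatment == control] else NULL
  groups <- unique(results[, c("strain", "nutrient")])
  rows <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    sel <- results$strain == g$strain & results$nutrient == g$nutrient
    x <- results$per_delta[sel & results$treatment == ct]
    y <- pooled %||% results$per_delta[sel & results$treatment == control]
    if (length(x) < 2 || length(y) < 2) {
      warnf("group %s/%s skipped: missing treatment arm", g$strain, g$nutrient)
      next
    }
    sw_x <- tryCatch(shapiro_wilk(x), error = function(e) list(W = NA, p = NA))
    sw_y <- tryCatch(shapiro_wilk(y), error = function(e) list(W = NA, p = NA))
    if (isTRUE(sw_x$p <= alpha) || isTRUE(sw_y$p <= alpha))
      warnf("group %s/%s: per_delta normality rejected (Shapiro-Wilk)",
            g$strain, g$nutrient)
    ft <- tryCatch(f_var_test(x, y),
                   error = function(e) list(F = NA, df = NA, p = NA))
    kind <- if (isTRUE(ft$p <= alpha)) "welch" else "student"
    tt <- one_tailed_t(x, y, kind)
    rows[[length(rows) + 1]] <- data.frame(
      strain = g$strain, nutrient = g$nutrient,
      n_ct = length(x), n_control = length(y),
      shapiro_W_ct = sw_x$W, shapiro_p_ct = sw_x$p,
      shapiro_W_control = sw_y$W, shapiro_p_control = sw_y$p,
      F_statistic = ft$F, F_p = ft$p,
      chosen = kind, t = tt$t, df = tt$df, p = tt$p,
      significant = tt$p <= alpha,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no testable strain x nutrient group in results")
  rownames(out) <- NULL
  class(out) <- c("stat_report", "data.frame")
  out
}
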