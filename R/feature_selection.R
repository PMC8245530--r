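#' Boruta all-relevant feature selection
#'
#' Classic Boruta: each iteration appends a shuffled "shadow" copy of every
#' feature still in play, fits an ensemble of randomised decision trees
#' (permutation importance via `ranger`), and scores a "hit" for every
#' undecided real feature whose importance exceeds the maximum shadow
#' importance.  After each iteration a feature's hit count is tested
#' against Binomial(i, 1/2): significantly more hits than expected
#' (Bonferroni-corrected over features) confirms it, significantly fewer
#' rejects it.  Decisions are sticky; rejected features are removed from
#' subsequent model fits.  Features still tentative at `max_iterations` are
#' resolved by the "rough fix": median importance over the iteration log
#' against the median of the maximum shadow importances.
#'
#' @param X numeric matrix samples x features.
#' @param y binary response (logical, or a 2-level factor).
#' @param max_iterations maximum Boruta iterations (>= 10).
#' @param n_trees trees per ensemble fit.
#' @param alpha binomial-test level in `(0, 0.5)`.
#' @param seed RNG seed; decisions are deterministic given it.
#' @return A `feature_decision`: data.frame `feature`, `decision`
#'   (confirmed/rejected), `tentative_resolved` (TRUE when the rough fix
#'   decided), `hits`, `n_iter`; plus an `iterations` attribute with the
#'   importance log.
#' @export
boruta_select <- function(X, y, max_iterations = 100L, n_trees = 100L,
                          alpha = 0.05, seed = 1L) {
  if (is.null(dim(X)) || ncol(X) < 1) stopf("X must have at least 1 feature")
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2) stopf("y must have exactly two classes")
  if (min(table(y)) < 2) stopf("need >= 2 samples per class")
  if (max_iterations < 10) stopf("max_iterations must be >= 10")
  if (alpha <= 0 || alpha >= 0.5) stopf("alpha must lie in (0, 0.5)")

  set.seed(seed)
  feats <- colnames(X)
  nfeat <- length(feats)
  decision <- setNames(rep("tentative", nfeat), feats)
  hits <- setNames(integer(nfeat), feats)
  tested <- setNames(integer(nfeat), feats)   # iterations a feature was undecided
  imp_log <- vector("list", 0)
  shadow_log <- numeric(0)
  thr <- alpha / nfeat                        # Bonferroni over features

  for (it in seq_len(max_iterations)) {
    active <- feats[decision != "rejected"]
    undecided <- feats[decision == "tentative"]
    if (length(undecided) == 0) break
    Xa <- X[, active, drop = FALSE]
    # shadows: shuffled copies of the active features, padded to at least 5
    # so the max-shadow reference never degenerates late in the run
    shadow_src <- active
    while (length(shadow_src) < 5)
      shadow_src <- c(shadow_src, active[seq_len(min(length(active),
                                                     5 - length(shadow_src)))])
    Xs <- apply(X[, shadow_src, drop = FALSE], 2, sample)
    colnames(Xs) <- sprintf("shadow_%03d", seq_along(shadow_src))
    imp <- importance_zscores(cbind(Xa, Xs), y, n_trees, seed = seed + it)
    shadow_max <- max(imp[startsWith(names(imp), "shadow_")])
    real_imp <- imp[active]
    imp_log[[length(imp_log) + 1]] <- real_imp
    shadow_log <- c(shadow_log, shadow_max)
    hit <- undecided[real_imp[undecided] > shadow_max]
    hits[hit] <- hits[hit] + 1L
    tested[undecided] <- tested[undecided] + 1L
    for (f in undecided) {
      p_conf <- pbinom(hits[f] - 1L, tested[f], 0.5, lower.tail = FALSE)
      p_rej <- pbinom(hits[f], tested[f], 0.5)
      if (p_conf < thr) decision[f] <- "confirmed"
      else if (p_rej < thr) decision[f] <- "rejected"
    }
  }

  rough <- decision == "tentative"
  if (any(rough)) {
    med_shadow <- median(shadow_log)
    for (f in feats[rough]) {
      med_imp <- median(vapply(imp_log, function(v)
        if (f %in% names(v)) v[[f]] else NA_real_, numeric(1)), na.rm = TRUE)
      decision[f] <- if (isTRUE(med_imp > med_shadow)) "confirmed" else "rejected"
    }
  }
  out <- data.frame(feature = feats, decision = unname(decision),
                    tentative_resolved = unname(rough),
                    hits = unname(hits), n_iter = unname(tested),
                    stringsAsFactors = FALSE)
  attr(out, "iterations") <- list(importance = imp_log,
                                  shadow_max = shadow_log)
  class(out) <- c("feature_decision", "data.frame")
  out
}

# importance estimator: permutation importance of a random-forest ensemble,
# scaled by its standard error over trees (the z-score used by the classic
# Boruta hit test); deterministic given the seed
importance_zscores <- function(X, y, n_trees, seed) {
  dat <- data.frame(X, check.names = FALSE)
  dat$.y <- factor(y)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = n_trees, importance = "permutation",
    local.importance = TRUE,
    seed = seed, num.threads = 1, verbose = FALSE)
  imp <- fit$variable.importance
  # standard error over the casewise importance contributions
  loc <- fit$variable.importance.local
  se <- apply(loc, 2, sd) / sqrt(nrow(loc))
  se[se == 0] <- Inf    # a feature with no importance signal scores z = 0
  z <- imp / se
  z[imp == 0 & !is.finite(se)] <- 0
  z
}

#' Confirmed features of a Boruta decision
#' @param decision a [boruta_select()] result.
#' @return Character vector of confirmed feature names.
#' @export
confirmed_features <- function(decision) {
  decision$feature[decision$decision == "confirmed"]
}
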