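#' Fit a probabilistic (Parzen) neural network for one capability
#'
#' Stores the training feature vectors with their binary class labels and
#' class priors (class frequencies, e.g. 16/35 positive for phagocytosis in
#' the default training composition).  The Gaussian kernel bandwidth
#' `sigma` is either given or chosen by a leave-one-out accuracy grid
#' (ties resolved to the smallest bandwidth, recorded in the model).
#' Optional per-vector kernel weights support the weighting contract:
#' duplicating a training vector while halving its weight leaves all
#' posteriors unchanged.
#'
#' @param X numeric matrix samples x features.
#' @param y logical class vector (TRUE = capability present).
#' @param sigma kernel bandwidth (> 0), or `NULL` to select by
#'   leave-one-out grid search.
#' @param sigma_grid candidate bandwidths for the grid.
#' @param weights per-sample kernel weights.
#' @return A `pnn_model`: `X`, `y`, `weights`, `sigma`, `priors`.
#' @export
pnn_fit <- function(X, y, sigma = NULL,
                    sigma_grid = seq(0.05, 1, by = 0.05),
                    weights = rep(1, length(y))) {
  X <- as.matrix(X)
  y <- as.logical(y)
  if (nrow(X) != length(y)) stopf("X and y sizes differ")
  if (!any(y) || all(y)) stopf("both classes must be non-empty")
  if (!is.null(sigma) && sigma <= 0) stopf("sigma must be > 0")
  if (any(weights <= 0)) stopf("kernel weights must be positive")
  # weight-based priors: equal to class frequencies under unit weights, and
  # invariant under the duplicate-and-halve weighting contract
  priors <- c(positive = sum(weights[y]) / sum(weights),
              negative = sum(weights[!y]) / sum(weights))
  if (is.null(sigma)) {
    acc <- vapply(sigma_grid, function(s)
      pnn_loo_accuracy(X, y, s, weights), numeric(1))
    sigma <- sigma_grid[which.max(acc)]   # which.max takes the first = smallest
  }
  structure(list(X = X, y = y, weights = weights, sigma = sigma,
                 priors = priors),
            class = "pnn_model")
}

pnn_loo_accuracy <- function(X, y, sigma, weights) {
  ok <- vapply(seq_len(nrow(X)), function(i) {
    yy <- y[-i]
    if (!any(yy) || all(yy)) return(NA)
    p <- pnn_posterior(X[-i, , drop = FALSE], yy, weights[-i], sigma,
                       X[i, , drop = FALSE])
    (p > 0.5) == y[i]
  }, logical(1))
  mean(ok, na.rm = TRUE)
}

# posterior P(positive | x) for rows of Xnew; log-sum-exp for stability
pnn_posterior <- function(X, y, w, sigma, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rowSums(X^2), "+") - 2 * Xnew %*% t(X)
  d2[d2 < 0] <- 0
  logk <- -d2 / (2 * sigma^2)
  priors <- c(sum(w[y]), sum(w[!y])) / sum(w)
  dens <- function(cls) {
    m <- logk[, cls, drop = FALSE]
    ww <- w[cls]
    mx <- apply(m, 1, max)
    exp(mx) * as.vector(exp(m - mx) %*% ww) / sum(ww)
  }
  g_pos <- priors[1] * dens(y)
  g_neg <- priors[2] * dens(!y)
  p <- g_pos / (g_pos + g_neg)
  # both densities can underflow far from all training points; fall back to
  # the prior there
  p[!is.finite(p)] <- priors[1]
  p
}

#' Predict capability posteriors with a fitted PNN
#'
#' `P(class | x)` is the prior times the weighted mean Gaussian kernel over
#' the class's training vectors, normalised over the two classes.
#'
#' @param model a [pnn_fit()] model.
#' @param x numeric vector or matrix (rows = new organisms) with the
#'   model's feature dimension.
#' @return Numeric vector of posterior probabilities in `[0, 1]`.
#' @export
pnn_predict <- function(model, x) {
  stopifnot(inherits(model, "pnn_model"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != ncol(model$X))
    stopf("feature dimension mismatch: model has %d, input has %d",
          ncol(model$X), ncol(x))
  unname(pnn_posterior(model$X, model$y, model$weights, model$sigma, x))
}

#' Call capabilities at a probability threshold
#'
#' A probability strictly greater than 0.5 (by default) is interpreted as
#' evidence that the organism can carry out the capability; exactly 0.5 is
#' a negative call.
#'
#' @param p numeric vector/matrix of probabilities in `[0, 1]`.
#' @param threshold call threshold.
#' @return Logical of the same shape.
#' @export
call_capabilities <- function(p, threshold = 0.5) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("probabilities must lie in [0, 1]")
  p > threshold
}

#' Trophic-mode category from a capability call triple
#'
#' Categories combine the three calls: phagotrophy with photosynthesis is a
#' phago-mixotroph; photosynthesis alone a photo-autotroph; prototrophy
#' without either a strict osmotroph; phagotrophy without photosynthesis a
#' phago-heterotroph; no capability at all is unclassified.
#'
#' @param phago,photo,proto logical vectors (recycled to common length).
#' @return Character vector of category labels.
#' @export
assign_category <- function(phago, photo, proto) {
  n <- max(length(phago), length(photo), length(proto))
  phago <- rep_len(phago, n); photo <- rep_len(photo, n)
  proto <- rep_len(proto, n)
  out <- character(n)
  out[phago & photo] <- "phago-mixotroph"
  out[!phago & photo] <- "photo-autotroph"
  out[phago & !photo] <- "phago-heterotroph"
  out[!phago & !photo & proto] <- "strict osmotroph"
  out[!phago & !photo & !proto] <- "unclassified"
  out
}

#' Completeness gate on universal marker families
#'
#' Scores the proteome against the universal marker profiles; the missing
#' fraction is `1 - detected/total`.  Sets are kept when the missing
#' fraction is strictly below `max_missing_fraction` (default 0.32,
#' mirroring a <32%-missing universal-ortholog rule) or when the strain is
#' whitelisted in `override_keep`; gated strains are still scored
#' downstream but flagged.
#'
#' @param proteome a [protein_set()].
#' @param marker_profiles list of calibrated universal-marker
#'   [profile_model]s.
#' @param max_missing_fraction gate threshold in `(0, 1)`.
#' @param override_keep strain ids kept regardless of completeness.
#' @return List `completeness` (detected fraction), `missing`, `keep`.
#' @export
completeness_gate <- function(proteome, marker_profiles,
                              max_missing_fraction = 0.32,
                              override_keep = character(0)) {
  if (length(marker_profiles) == 0) stopf("need at least one marker profile")
  if (max_missing_fraction <= 0 || max_missing_fraction >= 1)
    stopf("max_missing_fraction must lie in (0, 1)")
  det <- vapply(marker_profiles, function(pr)
    score_presence(pr, proteome)$present, logical(1))
  missing <- 1 - mean(det)
  keep <- missing < max_missing_fraction ||
    proteome$strain_id %in% override_keep
  list(completeness = mean(det), missing = missing, keep = keep)
}
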