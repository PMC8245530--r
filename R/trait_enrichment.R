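#' Trait enrichment of gene families by two-proportion test
#'
#' For each family, compares its carriage frequency among trait-positive
#' training organisms against trait-negative ones with a one-sided pooled
#' two-proportion z-test (enrichment direction only; depletion is never
#' called).  A family is enriched when `p <= alpha` and the positive-group
#' frequency is strictly higher.
#'
#' @param presence a [presence_matrix()] (or a bare logical matrix
#'   strains x families).
#' @param labels data.frame with `strain_id` and a logical column per trait,
#'   covering every strain in `presence`.
#' @param trait trait column to test.
#' @param alpha significance level.
#' @return Data.frame: family_id, k_in, n_in, k_out, n_out, statistic (z),
#'   p_value, enriched.
#' @export
proportion_enrichment <- function(presence, labels, trait, alpha = 0.05) {
  pres <- if (inherits(presence, "presence_matrix")) presence$present else presence
  if (!trait %in% names(labels)) stopf("unknown trait '%s'", trait)
  if (!all(rownames(pres) %in% labels$strain_id))
    stopf("labels must cover all strains in the presence matrix")
  lab <- setNames(labels[[trait]], labels$strain_id)[rownames(pres)]
  n_in <- sum(lab); n_out <- sum(!lab)
  if (n_in == 0 || n_out == 0)
    stopf("both trait groups must be non-empty (got %d positive, %d negative)",
          n_in, n_out)
  k_in <- colSums(pres[lab, , drop = FALSE])
  k_out <- colSums(pres[!lab, , drop = FALSE])
  zp <- two_prop_z(k_in, n_in, k_out, n_out)
  data.frame(family_id = colnames(pres),
             k_in = unname(k_in), n_in = n_in,
             k_out = unname(k_out), n_out = n_out,
             statistic = zp$z, p_value = zp$p,
             enriched = zp$p <= alpha & (k_in / n_in > k_out / n_out),
             row.names = NULL, stringsAsFactors = FALSE)
}

# one-sided (greater) pooled-variance two-proportion z-test; equal pooled
# proportions of 0 or 1 make the statistic 0/0 -- defined as z = 0 (equal
# observed proportions), one-sided p = 0.5
two_prop_z <- function(k1, n1, k2, n2) {
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  list(z = unname(z), p = unname(pnorm(z, lower.tail = FALSE)))
}

#' Group enriched families by GO biological process
#'
#' One category per GO term; a family annotated with several terms belongs
#' to each of them; families without annotation fall into the
#' `"unassigned"` category.
#'
#' @param enriched_families character vector of enriched family ids.
#' @param annotation named list family -> character vector of GO terms.
#' @return Named list category -> member family ids (empty list when no
#'   family is enriched).
#' @export
go_group <- function(enriched_families, annotation) {
  if (length(enriched_families) == 0) return(structure(list(), names = character(0)))
  terms <- lapply(enriched_families, function(f) {
    tt <- annotation[[f]]
    if (is.null(tt) || length(tt) == 0) "unassigned" else tt
  })
  long <- data.frame(family = rep(enriched_families, lengths(terms)),
                     term = unlist(terms), stringsAsFactors = FALSE)
  split(long$family, long$term)
}

#' Per-organism weighted GO-category scores
#'
#' `score(org, cat) = sum_f present(org, f) * w_f / sum_f w_f` over the
#' category's member families, with enrichment weights
#' `w_f = min(-log10(p_f), 10)`.  Scores therefore lie in `[0, 1]`: 1 when
#' an organism carries every member family, 0 when it carries none.
#'
#' @param presence a [presence_matrix()] or logical matrix (strains x
#'   families).
#' @param categories named list from [go_group()].
#' @param weights named numeric vector of family weights (e.g. from
#'   [enrichment_weights()]).
#' @return Numeric matrix organisms x categories.
#' @export
weighted_scores <- function(presence, categories, weights) {
  pres <- if (inherits(presence, "presence_matrix")) presence$present else presence
  if (length(categories) == 0) stopf("no categories to score")
  out <- matrix(0, nrow(pres), length(categories),
                dimnames = list(rownames(pres), names(categories)))
  for (ci in seq_along(categories)) {
    fams <- intersect(categories[[ci]], colnames(pres))
    if (length(fams) == 0) next
    w <- weights[fams]
    out[, ci] <- as.vector(pres[, fams, drop = FALSE] %*% w) / sum(w)
  }
  out
}

#' Enrichment weights from p-values
#'
#' `w_f = min(-log10(p_f), 10)`; a tiny floor keeps zero p-values finite
#' and fully-null families (p = 1) at a small positive weight so category
#' normalisation stays defined.
#'
#' @param enrichment a [proportion_enrichment()] result.
#' @return Named numeric vector keyed by family id.
#' @export
enrichment_weights <- function(enrichment) {
  w <- pmin(-log10(pmax(enrichment$p_value, 1e-300)), 10)
  w <- pmax(w, 1e-6)
  setNames(w, enrichment$family_id)
}
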