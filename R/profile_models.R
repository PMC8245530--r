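#' Align the members of a gene family
#'
#' Deterministic center-star progressive alignment: the longest member
#' (ties broken by input order) is the center; every other member is
#' globally aligned to it (Needleman-Wunsch via Biostrings under BLOSUM62)
#' and the pairwise alignments are merged on center coordinates, expanding
#' insertion columns as needed.  When all members share one length (the
#' default worlds are substitution-only) the alignment is a gapless stack.
#'
#' @param members named character vector of member sequences.
#' @param family_id identifier carried on the result.
#' @return A `family_alignment`: list with `family_id` and `rows`, a named
#'   character vector of equal-length gapped sequences; removing the gaps
#'   of any row reproduces the member sequence.
#' @export
align_family <- function(members, family_id = "family") {
  if (length(members) == 0) stopf("cannot align an empty family")
  if (is.null(names(members)))
    names(members) <- sprintf("seq%03d", seq_along(members))
  if (length(unique(nchar(members))) == 1 || length(members) == 1) {
    # equal lengths: gapless stack (also covers the single-member case)
    return(structure(list(family_id = family_id, rows = members),
                     class = "family_alignment"))
  }
  center_i <- which.max(nchar(members))
  center <- members[[center_i]]
  others <- members[-center_i]
  # align each member to the center; record, per sequence, the aligned
  # pattern/subject strings
  aligned <- lapply(others, function(s) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(s), Biostrings::AAString(center),
      type = "global",
      substitutionMatrix = blosum62_matrix_full(),
      gapOpening = 11, gapExtension = 1)
    list(pat = as.character(Biostrings::alignedPattern(pa)),
         sub = as.character(Biostrings::alignedSubject(pa)))
  })
  # insertions relative to the center: for each center position (0 = before
  # first) the maximum run of inserted residues across pairwise alignments
  L <- nchar(center)
  ins_max <- integer(L + 1)
  per_seq_cols <- vector("list", length(aligned))
  for (a in seq_along(aligned)) {
    pat <- strsplit(aligned[[a]]$pat, "")[[1]]
    sub <- strsplit(aligned[[a]]$sub, "")[[1]]
    pos <- 0L                       # center residues consumed
    run <- integer(L + 1)           # insertion run after center position pos
    off <- 0L
    for (t in seq_along(pat)) {
      if (sub[t] != "-") { pos <- pos + 1L; off <- 0L }
      else { off <- off + 1L; run[pos + 1L] <- max(run[pos + 1L], off) }
    }
    ins_max <- pmax(ins_max, run)
    per_seq_cols[[a]] <- list(pat = pat, sub = sub)
  }
  # global column layout: ins block 0, match 1, ins block 1, match 2, ...,
  # match L, ins block L; block p has width ins_max[p + 1]
  n_cols <- L + sum(ins_max)
  # column index of center match position p (1-based):
  match_col <- ins_max[1] + cumsum(c(1L, ins_max[2:(L + 1)][seq_len(L - 1)] + 1L))
  build_row <- function(pat, sub) {
    row <- rep("-", n_cols)
    pos <- 0L; off <- 0L
    for (t in seq_along(pat)) {
      if (sub[t] != "-") {
        pos <- pos + 1L; off <- 0L
        if (pat[t] != "-") row[match_col[pos]] <- pat[t]
      } else {
        off <- off + 1L
        # insertion block after center position pos sits just before
        # match_col[pos + 1]; right-pack the run so runs stay contiguous
        anchor <- if (pos < L) match_col[pos + 1L] else n_cols + 1L
        row[anchor - 1L - (ins_max[pos + 1L] - off)] <- pat[t]
      }
    }
    paste(row, collapse = "")
  }
  rows <- c(vapply(seq_along(aligned), function(a)
    build_row(per_seq_cols[[a]]$pat, per_seq_cols[[a]]$sub), character(1)),
    local({ # the center row itself
      row <- rep("-", n_cols)
      row[match_col] <- strsplit(center, "")[[1]]
      paste(row, collapse = "")
    }))
  names(rows) <- c(names(others), names(members)[center_i])
  rows <- rows[names(members)]    # restore input order
  structure(list(family_id = family_id, rows = rows),
            class = "family_alignment")
}

# BLOSUM62 on the full Biostrings alphabet (pairwiseAlignment needs the
# original row/col names)
blosum62_matrix_full <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  get("BLOSUM62", envir = environment())
}

#' @export
print.family_alignment <- function(x, ...) {
  cat(sprintf("<family_alignment> %s: %d rows x %d columns\n", x$family_id,
              length(x$rows), if (length(x$rows)) nchar(x$rows[[1]]) else 0L))
  invisible(x)
}

#' Build a position-specific profile model from a family alignment
#'
#' Columns with more than 50% gaps are dropped from the match states.  The
#' probability of residue `r` in a column is
#' `(count_r + alpha * bg_r) / (n_ungapped + alpha)` with pseudocount weight
#' `alpha` and background `bg` (uniform by default); note the remaining gap
#' mass is spread over the background, so columns sum to 1 only after the
#' gap-free renormalisation applied here.  Log-odds are `log2(p / bg)`.
#'
#' @param alignment a [align_family()] result.
#' @param alpha pseudocount weight (>= 0).
#' @param background length-20 residue background distribution.
#' @return A `profile_model`: `family_id`, `length`, `probs` (L x 20),
#'   `logodds`, `background`, `alpha`, and a `threshold` slot filled by
#'   [calibrate_threshold()].
#' @export
build_profile <- function(alignment, alpha = 1,
                          background = rep(1 / 20, 20)) {
  stopifnot(inherits(alignment, "family_alignment"))
  if (alpha < 0) stopf("pseudocount alpha must be >= 0")
  if (length(background) != 20 || abs(sum(background) - 1) > 1e-9)
    stopf("background must be a length-20 distribution")
  rows <- do.call(rbind, strsplit(alignment$rows, ""))
  gap_frac <- colMeans(rows == "-")
  match_cols <- which(gap_frac <= 0.5)
  if (length(match_cols) == 0) stopf("no match columns after gap filtering")
  probs <- matrix(0, length(match_cols), 20,
                  dimnames = list(NULL, AA_ALPHABET20))
  for (ci in seq_along(match_cols)) {
    col <- rows[, match_cols[ci]]
    col <- col[col != "-"]
    cnt <- table(factor(col, levels = AA_ALPHABET20))
    probs[ci, ] <- (as.numeric(cnt) + alpha * background) /
      (length(col) + alpha)
    probs[ci, ] <- probs[ci, ] / sum(probs[ci, ])
  }
  structure(list(family_id = alignment$family_id,
                 length = length(match_cols),
                 probs = probs,
                 logodds = log2(sweep(probs, 2, background, "/")),
                 background = background, alpha = alpha,
                 threshold = NA_real_),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("<profile_model> %s: %d match columns, threshold %s\n",
              x$family_id, x$length,
              if (is.na(x$threshold)) "uncalibrated" else
                format(x$threshold, digits = 4)))
  invisible(x)
}

#' Calibrate a family-specific presence threshold
#'
#' The threshold is a fraction (default 0.7) of the minimum score obtained
#' by the family's own training members, i.e. a self-calibrated bar that
#' every training member clears.
#'
#' @param profile a [build_profile()] model.
#' @param members the training member sequences.
#' @param frac fraction of the minimum member score.
#' @return The profile with its `threshold` slot set.
#' @export
calibrate_threshold <- function(profile, members, frac = 0.7) {
  sc <- .profile_best_scores(profile$logodds, encode_protein(members))
  m <- min(sc)
  profile$threshold <- if (m >= 0) frac * m else m / frac
  profile
}

#' Score a proteome for family presence
#'
#' The best score over all proteins of the ungapped local (best-window)
#' log-odds profile score decides presence against the family-specific
#' threshold.
#'
#' @param profile a calibrated [profile_model].
#' @param proteome a [protein_set()].
#' @param threshold override of the profile's calibrated threshold.
#' @return List `present` (logical), `best_score` (numeric; `NA` for an
#'   empty proteome).
#' @export
score_presence <- function(profile, proteome, threshold = profile$threshold) {
  stopifnot(inherits(profile, "profile_model"), inherits(proteome, "protein_set"))
  if (length(proteome$proteins) == 0)
    return(list(present = FALSE, best_score = NA_real_))
  if (is.na(threshold)) stopf("profile threshold not calibrated")
  sc <- .profile_best_scores(profile$logodds, encode_protein(proteome$proteins))
  best <- max(sc)
  list(present = best >= threshold, best_score = best)
}

#' Presence/absence matrix of proteomes against a profile bank
#'
#' @param profiles list of calibrated [profile_model]s.
#' @param proteomes list of [protein_set()]s.
#' @return A `presence_matrix`: list with logical `present` and numeric
#'   `score` matrices (strains x families).
#' @export
presence_matrix <- function(profiles, proteomes) {
  fam_ids <- vapply(profiles, function(p) p$family_id, character(1))
  strains <- vapply(proteomes, function(p) p$strain_id, character(1))
  pres <- matrix(FALSE, length(strains), length(fam_ids),
                 dimnames = list(strains, fam_ids))
  score <- matrix(NA_real_, length(strains), length(fam_ids),
                  dimnames = list(strains, fam_ids))
  enc <- lapply(proteomes, function(ps) encode_protein(ps$proteins))
  for (j in seq_along(profiles)) {
    pr <- profiles[[j]]
    if (is.na(pr$threshold)) stopf("profile %s not calibrated", pr$family_id)
    for (i in seq_along(proteomes)) {
      if (length(enc[[i]]) == 0) next
      sc <- .profile_best_scores(pr$logodds, enc[[i]])
      score[i, j] <- max(sc)
      pres[i, j] <- score[i, j] >= pr$threshold
    }
  }
  structure(list(present = pres, score = score), class = "presence_matrix")
}

#' Write a presence matrix as a long-format TSV
#' @param pm a [presence_matrix()].
#' @param path output path.
#' @export
write_presence <- function(pm, path) {
  long <- data.frame(
    strain = rep(rownames(pm$present), ncol(pm$present)),
    family = rep(colnames(pm$present), each = nrow(pm$present)),
    present = as.vector(pm$present),
    score = as.vector(pm$score))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
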