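test_that("family alignment handles the trivial and equal-length cases", {
  a1 <- align_family(c(s1 = "ACDEFGH"))
  expect_identical(unname(a1$rows), "ACDEFGH")
  a2 <- align_family(c(s1 = "ACDEFGH", s2 = "ACDEFGH"))
  expect_identical(unname(a2$rows), c("ACDEFGH", "ACDEFGH"))
  expect_false(any(grepl("-", a2$rows, fixed = TRUE)))
})

test_that("center-star alignment preserves members and bounds the length", {
  members <- c(long = "ACDEFGHIKLMNPQRSTVWY",
               del = "ACDEFGIKLMNPQRSTVWY",     # one deletion
               ins = "ACDEFGHIKWWLMNPQRSTVWY",  # two-residue insertion
               short = "ACDEFGHIKLMNPQRS")
  a <- align_family(members, family_id = "mixed")
  widths <- unique(nchar(a$rows))
  expect_length(widths, 1)
  expect_gte(widths, max(nchar(members)))
  ungapped <- gsub("-", "", a$rows, fixed = TRUE)
  expect_identical(ungapped[names(members)], members)
})

test_that("profile columns follow the pseudocount closed form and sum to 1", {
  aln <- align_family(c(a = "AAAA", b = "AAAC", c = "AACC"))
  # alpha = 0: first column is all A
  p0 <- build_profile(aln, alpha = 0)
  expect_equal(unname(p0$probs[1, "A"]), 1)
  # alpha > 0, uniform background: P(A) = (n + alpha/20) / (n + alpha)
  for (alpha in c(0.5, 1, 5)) {
    p <- build_profile(aln, alpha = alpha)
    expect_equal(unname(p$probs[1, "A"]), (3 + alpha / 20) / (3 + alpha))
    expect_equal(unname(p$probs[2, "A"]), (3 + alpha / 20) / (3 + alpha))
    expect_equal(unname(p$probs[3, "A"]), (2 + alpha / 20) / (3 + alpha))
    expect_true(all(abs(rowSums(p$probs) - 1) < 1e-9))
  }
  expect_error(build_profile(aln, alpha = -1), "alpha")
})

test_that("columns with more than half gaps are dropped from match states", {
  aln <- structure(list(family_id = "gappy",
                        rows = c(a = "AC-", b = "AC-", c = "ACW")),
                   class = "family_alignment")
  p <- build_profile(aln)
  expect_identical(p$length, 2L)
})

test_that("members outscore their shuffled and reversed decoys", {
  set.seed(21)
  anc <- protein_from(trophicmode:::AA_ALPHABET20, 80, seed = 21)
  members <- setNames(vapply(1:6, function(i)
    trophicmode:::mutate_protein(anc, 0.05), character(1)),
    sprintf("m%d", 1:6))
  pr <- calibrate_threshold(build_profile(align_family(members)), members)
  member_scores <- trophicmode:::.profile_best_scores(
    pr$logodds, trophicmode:::encode_protein(members))
  decoys <- c(vapply(members, shuffle_protein, character(1), seed = 3),
              vapply(members, reverse_protein, character(1)))
  decoy_scores <- trophicmode:::.profile_best_scores(
    pr$logodds, trophicmode:::encode_protein(decoys))
  expect_true(all(member_scores > max(decoy_scores)))
  # presence verdicts follow
  expect_true(score_presence(pr, protein_set("s", members[1]))$present)
  expect_false(score_presence(
    pr, protein_set("s", c(d1 = unname(decoys[1]))))$present)
})

test_that("an empty proteome scores absent with an undefined score", {
  members <- c(m1 = "ACDEFGHIKL", m2 = "ACDEFGHIKL")
  pr <- calibrate_threshold(build_profile(align_family(members)), members)
  res <- score_presence(pr, protein_set("empty", setNames(character(0),
                                                          character(0))))
  expect_false(res$present)
  expect_true(is.na(res$best_score))
})

test_that("presence equals planted carriage at zero dropout; false absences track dropout", {
  w <- generate_world(small_world_config(seed = 13))
  train <- w$labels$strain_id[w$labels$role == "training"]
  prot <- unlist(lapply(w$proteomes[train], `[[`, "proteins"))
  names(prot) <- unlist(lapply(w$proteomes[train], function(p) names(p$proteins)))
  fam_of <- setNames(w$truth$family_id, w$truth$protein_id)
  members_of <- split(names(prot), fam_of[names(prot)])
  members_of <- members_of[vapply(members_of, length, integer(1)) >= 3]
  profiles <- lapply(names(members_of), function(fid)
    calibrate_threshold(build_profile(align_family(prot[members_of[[fid]]],
                                                   family_id = fid)),
                        prot[members_of[[fid]]]))
  # zero dropout: presence == carriage
  pm <- presence_matrix(profiles, w$proteomes[train])
  carr <- w$carriage[train, colnames(pm$present), drop = FALSE]
  expect_identical(unname(pm$present), unname(carr))
  # dropout d: false-absence rate ~ d, false-presence rate ~ 0
  d <- 0.3
  deg <- lapply(seq_along(train), function(i)
    degrade_to_transcriptome(w$proteomes[[train[i]]], d, seed = 100 + i))
  pm_d <- presence_matrix(profiles, deg)
  carried <- which(carr)
  false_abs <- sum(!pm_d$present[carried]) / length(carried)
  ci <- qbinom(c(0.005, 0.995), length(carried), d) / length(carried)
  expect_gte(false_abs, ci[1])
  expect_lte(false_abs, ci[2])
  expect_identical(sum(pm_d$present[which(!carr)]), 0L)
})
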