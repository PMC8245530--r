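two_cluster_data <- function(n_pos = 16, n_neg = 19, sep = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_pos * 3, mean = sep, sd = 0.5), n_pos, 3),
             matrix(rnorm(n_neg * 3, mean = 0, sd = 0.5), n_neg, 3))
  list(X = X, y = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
}

test_that("priors equal class frequencies under unit weights", {
  d <- two_cluster_data()
  m <- pnn_fit(d$X, d$y, sigma = 0.3)
  expect_equal(unname(m$priors["positive"]), 16 / 35)
  expect_equal(sum(m$priors), 1)
})

test_that("invalid bandwidths and single-class labels are rejected", {
  d <- two_cluster_data()
  expect_error(pnn_fit(d$X, d$y, sigma = 0), "sigma")
  expect_error(pnn_fit(d$X, d$y, sigma = -1), "sigma")
  expect_error(pnn_fit(d$X, rep(TRUE, 35)), "classes")
})

test_that("the small-bandwidth limit reproduces training labels (1-NN)", {
  d <- two_cluster_data(seed = 2)
  m <- pnn_fit(d$X, d$y, sigma = 0.01)
  p <- pnn_predict(m, d$X)
  expect_identical(p > 0.5, d$y)
})

test_that("an equidistant point between balanced classes scores exactly 0.5", {
  m <- pnn_fit(rbind(c(0, 0), c(2, 0)), c(TRUE, FALSE), sigma = 0.7)
  expect_equal(pnn_predict(m, c(1, 0)), 0.5)
})

test_that("posteriors normalise: flipping the labels gives the complement", {
  d <- two_cluster_data(seed = 3)
  m_pos <- pnn_fit(d$X, d$y, sigma = 0.4)
  m_neg <- pnn_fit(d$X, !d$y, sigma = 0.4)
  xnew <- matrix(rnorm(15), 5, 3)
  expect_lt(max(abs(pnn_predict(m_pos, xnew) + pnn_predict(m_neg, xnew) - 1)),
            1e-12)
})

test_that("posteriors are invariant to feature order and to the duplicate-and-halve weighting contract", {
  d <- two_cluster_data(seed = 4)
  xnew <- matrix(rnorm(9), 3, 3)
  m <- pnn_fit(d$X, d$y, sigma = 0.4)
  perm <- c(3, 1, 2)
  m_perm <- pnn_fit(d$X[, perm], d$y, sigma = 0.4)
  expect_equal(pnn_predict(m, xnew), pnn_predict(m_perm, xnew[, perm]))
  # replace the first training vector by two half-weight copies
  w2 <- c(0.5, rep(1, 34), 0.5)
  m_dup <- pnn_fit(rbind(d$X, d$X[1, , drop = FALSE]),
                   c(d$y, d$y[1]), sigma = 0.4, weights = w2)
  expect_equal(pnn_predict(m, xnew), pnn_predict(m_dup, xnew), tolerance = 1e-12)
})

test_that("bandwidth mismatch on feature dimension errors", {
  d <- two_cluster_data()
  m <- pnn_fit(d$X, d$y, sigma = 0.3)
  expect_error(pnn_predict(m, c(1, 2)), "dimension")
})

test_that("capability calls use a strict 0.5 threshold on the printed scores", {
  # printed phagocyte scores: 0.519 and 0.542 called positive, 0.43 and
  # 0.22 negative, exactly 0.5 negative
  expect_true(call_capabilities(0.519))
  expect_true(call_capabilities(0.542))
  expect_false(call_capabilities(0.43))
  expect_false(call_capabilities(0.22))
  expect_false(call_capabilities(0.5))
  expect_error(call_capabilities(1.2), "0, 1")
})

test_that("capability combinations map to the trophic categories", {
  expect_identical(assign_category(TRUE, TRUE, TRUE), "phago-mixotroph")
  expect_identical(assign_category(TRUE, TRUE, FALSE), "phago-mixotroph")
  expect_identical(assign_category(FALSE, TRUE, TRUE), "photo-autotroph")
  expect_identical(assign_category(FALSE, TRUE, FALSE), "photo-autotroph")
  expect_identical(assign_category(FALSE, FALSE, TRUE), "strict osmotroph")
  expect_identical(assign_category(TRUE, FALSE, TRUE), "phago-heterotroph")
  expect_identical(assign_category(TRUE, FALSE, FALSE), "phago-heterotroph")
  expect_identical(assign_category(FALSE, FALSE, FALSE), "unclassified")
})

marker_bank <- function(n, seed = 5) {
  set.seed(seed)
  seqs <- setNames(vapply(seq_len(n), function(i)
    protein_from(trophicmode:::AA_ALPHABET20, 40, seed = seed + i),
    character(1)), sprintf("M%03d", seq_len(n)))
  profiles <- lapply(names(seqs), function(id)
    calibrate_threshold(build_profile(align_family(seqs[id], family_id = id)),
                        seqs[id]))
  list(seqs = seqs, profiles = profiles)
}

test_that("the completeness gate keeps <32% missing and honours the whitelist", {
  bank <- marker_bank(47)
  # 15 of 47 missing = 31.9%: kept
  keep_ps <- protein_set("ok", bank$seqs[1:32])
  g1 <- completeness_gate(keep_ps, bank$profiles)
  expect_equal(g1$missing, 15 / 47)
  expect_true(g1$keep)
  # 20 of 47 missing = 42.6% (the whitelisted-transcriptome regime): dropped
  # unless overridden
  poor_ps <- protein_set("poor", bank$seqs[1:27])
  g2 <- completeness_gate(poor_ps, bank$profiles)
  expect_false(g2$keep)
  g3 <- completeness_gate(poor_ps, bank$profiles, override_keep = "poor")
  expect_true(g3$keep)
  # complete set: kept
  g4 <- completeness_gate(protein_set("full", bank$seqs), bank$profiles)
  expect_equal(g4$missing, 0)
  expect_true(g4$keep)
  expect_error(completeness_gate(keep_ps, list()), "marker")
})
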