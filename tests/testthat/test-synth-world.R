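test_that("worlds are reproducible from the seed, down to the FASTA bytes", {
  w1 <- generate_world(small_world_config(seed = 3))
  w2 <- generate_world(small_world_config(seed = 3))
  expect_identical(w1$truth, w2$truth)
  expect_identical(lapply(w1$proteomes, `[[`, "proteins"),
                   lapply(w2$proteomes, `[[`, "proteins"))
  d1 <- file.path(tempdir(), "world_a"); d2 <- file.path(tempdir(), "world_b")
  write_world(w1, d1); write_world(w2, d2)
  f1 <- sort(list.files(d1, pattern = "\\.faa$"))
  expect_true(length(f1) > 0)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("degenerate carriage probabilities plant linked families exactly", {
  cfg <- small_world_config(seed = 5, p_in = 1, p_out = 0)
  w <- generate_world(cfg)
  for (tr in c("photosynthesis", "phagocytosis", "prototrophy")) {
    fams <- names(w$family_trait)[w$family_trait == tr]
    pos <- setNames(w$labels[[tr]], w$labels$strain_id)
    carr <- w$carriage[, fams, drop = FALSE]
    expect_true(all(carr[pos[rownames(carr)], ]))
    expect_false(any(carr[!pos[rownames(carr)], ]))
  }
})

test_that("empirical carriage among trait-positives sits in the binomial 99% CI of p_in", {
  cfg <- world_config(seed = 17)   # defaults: 25 linked families per trait
  w <- generate_world(cfg)
  train <- w$labels$role == "training"
  k <- 0; n <- 0
  for (tr in c("photosynthesis", "phagocytosis", "prototrophy")) {
    fams <- names(w$family_trait)[w$family_trait == tr]
    pos <- w$labels[[tr]] & train
    carr <- w$carriage[w$labels$strain_id[pos], fams, drop = FALSE]
    k <- k + sum(carr); n <- n + length(carr)
  }
  ci <- qbinom(c(0.005, 0.995), n, cfg$p_in) / n
  expect_gte(k / n, ci[1])
  expect_lte(k / n, ci[2])
})

test_that("ground-truth membership partitions the generated proteins", {
  w <- generate_world(small_world_config(seed = 9))
  n_prot <- sum(vapply(w$proteomes, function(p) length(p$proteins), integer(1)))
  expect_identical(nrow(w$truth), n_prot)
  expect_identical(anyDuplicated(w$truth$protein_id), 0L)
  expect_true(all(w$truth$family_id %in% names(w$family_trait)))
})

test_that("training trait marginals are matched exactly and labels may overlap", {
  w <- generate_world(world_config(seed = 23))
  tr <- w$labels[w$labels$role == "training", ]
  expect_identical(sum(tr$photosynthesis), 14L)
  expect_identical(sum(tr$phagocytosis), 16L)
  expect_identical(sum(tr$prototrophy), 21L)
  # 14 + 16 + 21 > 35 forces at least one multi-trait organism
  expect_gt(sum(tr$photosynthesis & tr$phagocytosis |
                tr$photosynthesis & tr$prototrophy |
                tr$phagocytosis & tr$prototrophy), 0)
})

test_that("every linked family carries at least one GO term from a finite ontology", {
  w <- generate_world(small_world_config(seed = 2))
  linked <- names(w$family_trait)[!w$family_trait %in% c("background", "universal")]
  expect_true(all(lengths(w$family_go[linked]) >= 1))
  expect_lt(length(unique(unlist(w$family_go))), 40)
})

test_that("transcriptome degradation removes an exact uniform subset", {
  set.seed(1)
  prot <- setNames(replicate(1000, paste(sample(c("A", "C", "G", "W"), 30,
                                                replace = TRUE),
                                         collapse = "")),
                   sprintf("p%04d", 1:1000))
  ps <- protein_set("s1", prot)
  same <- degrade_to_transcriptome(ps, 0, seed = 4)
  expect_identical(same$proteins, ps$proteins)
  expect_identical(same$source, "transcriptome")
  deg <- degrade_to_transcriptome(ps, 0.415, seed = 4)
  expect_identical(length(deg$proteins), 585L)
  expect_true(all(names(deg$proteins) %in% names(ps$proteins)))
  expect_error(degrade_to_transcriptome(ps, 1), "dropout")
  expect_error(degrade_to_transcriptome(ps, -0.1), "dropout")
})

test_that("invalid world configurations are rejected", {
  expect_error(world_config(n_training_genomes = 10,
                            trait_group_sizes = c(photosynthesis = 14,
                                                  phagocytosis = 16,
                                                  prototrophy = 21)),
               "exceed")
  expect_error(world_config(p_in = 0.5, p_out = 0.6), "p_out")
  expect_error(world_config(dropout_fraction_range = c(0, 1)), "dropout")
})

test_that("protein sets enforce canonical sequences and unique ids", {
  expect_error(protein_set("s", c(a = "ACDX")), "non-canonical")
  expect_error(protein_set("s", c(a = "ACD", a = "WYH")), "unique")
  expect_error(protein_set("s", c(a = "ACD", b = "")), "empty")
  ok <- protein_set("s", c(a = "ACD"))
  expect_s3_class(ok, "protein_set")
})
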