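# Shared fixtures: a small world configuration that keeps unit tests fast,
# and hand-built similarity graphs for the clustering oracles.

small_world_config <- function(seed = 7, ...) {
  defaults <- list(
    n_training_genomes = 12,
    trait_group_sizes = c(photosynthesis = 5, phagocytosis = 6, prototrophy = 7),
    n_background_families = 8,
    n_linked_families_per_trait = 6,
    n_universal_families = 10,
    family_seq_length = 60,
    n_heldout_genomes = 4,
    seed = seed)
  do.call(world_config, utils::modifyList(defaults, list(...)))
}

make_graph <- function(nodes, edges, genome = setNames(nodes, nodes)) {
  structure(list(nodes = nodes, genome = genome, edges = edges),
            class = "similarity_graph")
}

make_event_table <- function(fsc, red, green, truth = NULL,
                             timepoint = "t0", treatment = "CT") {
  trophicmode:::event_table(fsc, red, green, "test_strain", treatment,
                            "limited", 1L, timepoint, truth = truth)
}

# default-parameter algal/bacterial mixtures for gating tests
mixed_events <- function(n_algal, n_bact, seed = 3) {
  set.seed(seed)
  make_event_table(
    fsc = c(rlnorm(n_algal, log(500), 0.3), rlnorm(n_bact, log(30), 0.4)),
    red = c(rlnorm(n_algal, log(800), 0.4), rlnorm(n_bact, log(3), 0.5)),
    green = c(rlnorm(n_algal, log(20), 0.25), rlnorm(n_bact, log(300), 0.3)),
    truth = data.frame(is_algal = rep(c(TRUE, FALSE), c(n_algal, n_bact)),
                       fed = FALSE))
}

# three planted groups of 10 nodes: dense unit-weight edges within groups
# (90% of pairs), sparse weak edges across (2% of pairs at weight 0.1)
planted_graph <- function(seed = 42) {
  set.seed(seed)
  nodes <- sprintf("n%02d", 1:30)
  grp <- rep(1:3, each = 10)
  rows <- list()
  for (i in 1:29) for (j in (i + 1):30) {
    if (grp[i] == grp[j]) {
      if (runif(1) < 0.9)
        rows[[length(rows) + 1]] <- data.frame(from = nodes[i], to = nodes[j],
                                               score = 1.0)
    } else if (runif(1) < 0.02) {
      rows[[length(rows) + 1]] <- data.frame(from = nodes[i], to = nodes[j],
                                             score = 0.1)
    }
  }
  list(graph = make_graph(nodes, do.call(rbind, rows)), planted = grp)
}

# one end-to-end train/predict cycle on a default-sized world: 35 training
# genomes (trait marginals 14/16/21), 25 planted families per trait,
# p_in = 0.9 / p_out = 0.05, 20 held-out organisms degraded with protein
# dropout drawn from [0, 0.1]
heldout_accuracy <- function(seed) {
  cfg <- world_config(seed = seed)
  w <- generate_world(cfg)
  model <- train_trophic(world = w)
  held <- w$labels$strain_id[w$labels$role == "heldout"]
  set.seed(seed + 500)
  drops <- runif(length(held), 0, 0.1)
  degraded <- lapply(seq_along(held), function(i)
    degrade_to_transcriptome(w$proteomes[[held[i]]], drops[i],
                             seed = seed + 1000 + i))
  out <- predict_trophic(model, degraded)
  lab <- w$labels[match(held, w$labels$strain_id), ]
  c(phagocytosis = mean(out$predictions$call_phago == lab$phagocytosis),
    photosynthesis = mean(out$predictions$call_photo == lab$photosynthesis),
    prototrophy = mean(out$predictions$call_proto == lab$prototrophy))
}

# proteins drawn from disjoint alphabets can share no k-mers
protein_from <- function(letters, n, seed) {
  set.seed(seed)
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

shuffle_protein <- function(seq, seed = 1) {
  set.seed(seed)
  paste(sample(strsplit(seq, "")[[1]]), collapse = "")
}

reverse_protein <- function(seq) {
  paste(rev(strsplit(seq, "")[[1]]), collapse = "")
}
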