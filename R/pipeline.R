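#' Train the gene-based trophic-mode predictor
#'
#' End-to-end training on a (synthetic) world: all-vs-all similarity and
#' Markov clustering of the training proteomes into gene families, the
#' genome-diversity criterion, family alignment and profile-model building
#' with self-calibrated presence thresholds, presence scoring of the
#' training strains, per-trait enrichment testing, GO grouping with
#' weighted category scores, Boruta feature selection, and per-trait PNN
#' fits.  Families detected in every training genome double as the
#' universal marker set for the completeness gate.
#'
#' @param world a [generate_world()] result (generated from `config` when
#'   `NULL`).
#' @param config a [world_config()] used when `world` is `NULL`.
#' @param alpha enrichment significance level.
#' @param min_genomes diversity criterion.
#' @param score_cutoff,inflation similarity/clustering parameters.
#' @param boruta_iterations,boruta_trees Boruta controls.
#' @param sigma PNN bandwidth (`NULL` = leave-one-out grid).
#' @param threshold_frac presence-threshold calibration fraction.
#' @param verbose log record counts at stage boundaries.
#' @return A `trophic_model` bundle: profiles, marker family ids,
#'   per-trait enrichment tables, GO categories and weights, selected
#'   features, PNN models, training scores, families, config and seed.
#' @export
train_trophic <- function(world = NULL, config = world_config(),
                          alpha = 0.05, min_genomes = 3L,
                          score_cutoff = 50, inflation = 2,
                          boruta_iterations = 100L, boruta_trees = 100L,
                          sigma = NULL, threshold_frac = 0.7,
                          verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  world <- world %||% generate_world(config)
  train <- world$labels$strain_id[world$labels$role == "training"]
  proteomes <- world$proteomes[train]
  traits <- c("phagocytosis", "photosynthesis", "prototrophy")

  proteins <- unlist(lapply(proteomes, function(ps) ps$proteins))
  names(proteins) <- unlist(lapply(proteomes, function(ps) names(ps$proteins)))
  genome_of <- rep(train, vapply(proteomes, function(ps)
    length(ps$proteins), integer(1)))

  g <- pairwise_similarity(proteins, genome_of, score_cutoff = score_cutoff)
  say("similarity graph: %d nodes, %d edges", length(g$nodes), nrow(g$edges))
  membership <- mcl_cluster(g, inflation = inflation)
  fams <- gene_families(membership, setNames(genome_of, names(proteins)))
  say("MCL clusters: %d", nrow(fams$summary))
  elig <- diversity_filter(fams, min_genomes = min_genomes)
  say("families passing diversity criterion: %d", nrow(elig$summary))
  if (nrow(elig$summary) == 0) stopf("training failed: no eligible families")

  members_of <- split(elig$mapping$protein_id, elig$mapping$family_id)
  profiles <- lapply(names(members_of), function(fid) {
    seqs <- proteins[members_of[[fid]]]
    pr <- build_profile(align_family(seqs, family_id = fid))
    calibrate_threshold(pr, seqs, frac = threshold_frac)
  })
  names(profiles) <- names(members_of)
  say("profile models built: %d", length(profiles))

  pm <- presence_matrix(profiles, proteomes)
  markers <- elig$summary$family_id[
    elig$summary$n_genomes == length(train)]
  say("universal marker families: %d", length(markers))

  # cluster-level GO: union of member-protein annotations
  cluster_go <- lapply(members_of, function(pids) {
    sort(unique(unlist(world$protein_go[pids], use.names = FALSE)))
  })

  enrichment <- lapply(traits, function(tr)
    proportion_enrichment(pm, world$labels, tr, alpha = alpha))
  names(enrichment) <- traits
  n_enriched <- vapply(enrichment, function(e) sum(e$enriched), integer(1))
  say("enriched families: %s",
      paste(sprintf("%s=%d", traits, n_enriched), collapse = ", "))
  if (all(n_enriched == 0))
    stopf("training failed: no trait-enriched families (stage: enrichment)")

  categories <- scores <- selected <- models <- vector("list", length(traits))
  names(categories) <- names(scores) <- names(selected) <- names(models) <- traits
  weights <- lapply(enrichment, enrichment_weights)
  for (tr in traits) {
    enr <- enrichment[[tr]]
    if (sum(enr$enriched) == 0)
      stopf("training failed: no enriched families for %s", tr)
    categories[[tr]] <- go_group(enr$family_id[enr$enriched], cluster_go)
    scores[[tr]] <- weighted_scores(pm, categories[[tr]], weights[[tr]])
    y <- setNames(world$labels[[tr]], world$labels$strain_id)[train]
    dec <- boruta_select(scores[[tr]], y,
                         max_iterations = boruta_iterations,
                         n_trees = boruta_trees,
                         seed = world$config$seed + match(tr, traits))
    sel <- confirmed_features(dec)
    if (length(sel) == 0) {
      warnf("Boruta confirmed no %s category; keeping all %d", tr,
            ncol(scores[[tr]]))
      sel <- colnames(scores[[tr]])
    }
    selected[[tr]] <- sel
    models[[tr]] <- pnn_fit(scores[[tr]][, sel, drop = FALSE], y,
                            sigma = sigma)
    say("%s: %d categories, %d selected, sigma %.2f", tr,
        ncol(scores[[tr]]), length(sel), models[[tr]]$sigma)
  }

  structure(list(profiles = profiles, markers = markers,
                 families = elig, cluster_go = cluster_go,
                 enrichment = enrichment, weights = weights,
                 categories = categories, selected = selected,
                 models = models, training_scores = scores,
                 training_presence = pm,
                 traits = traits, config = world$config,
                 seed = world$config$seed),
            class = "trophic_model")
}

#' @export
print.trophic_model <- function(x, ...) {
  cat(sprintf(paste0("<trophic_model> %d profiles (%d universal markers), ",
                     "selected categories: %s\n"),
              length(x$profiles), length(x$markers),
              paste(sprintf("%s=%d", x$traits, lengths(x$selected)),
                    collapse = ", ")))
  invisible(x)
}

#' Predict trophic mode for new protein sets
#'
#' Completeness gate on the universal markers, presence scoring against
#' the model's profile bank, weighted GO-category scores, per-trait PNN
#' posteriors, threshold calls, category assignment and Mollweide map
#' coordinates.  Gated strains (completeness below the bar and not
#' whitelisted) are still scored but flagged.
#'
#' @param model a [train_trophic()] bundle.
#' @param proteomes list of [protein_set()]s.
#' @param max_missing_fraction completeness gate threshold.
#' @param override_keep strain whitelist for the gate.
#' @param threshold call threshold on the posteriors.
#' @return List `predictions` (data.frame strain_id, p_phago, p_photo,
#'   p_proto, call_*, category, completeness, gated) and `map`
#'   (Mollweide coordinates per strain).
#' @export
predict_trophic <- function(model, proteomes,
                            max_missing_fraction = 0.32,
                            override_keep = character(0),
                            threshold = 0.5) {
  stopifnot(inherits(model, "trophic_model"))
  if (inherits(proteomes, "protein_set")) proteomes <- list(proteomes)
  strains <- vapply(proteomes, function(p) p$strain_id, character(1))
  marker_profiles <- model$profiles[model$markers]
  gatez <- lapply(proteomes, function(ps) {
    if (length(ps$proteins) == 0)
      list(completeness = 0, missing = 1, keep = ps$strain_id %in% override_keep)
    else completeness_gate(ps, marker_profiles, max_missing_fraction,
                           override_keep)
  })
  pm <- presence_matrix(model$profiles, proteomes)
  probs <- matrix(NA_real_, length(proteomes), length(model$traits),
                  dimnames = list(strains, model$traits))
  for (tr in model$traits) {
    sc <- weighted_scores(pm, model$categories[[tr]], model$weights[[tr]])
    probs[, tr] <- pnn_predict(model$models[[tr]],
                               sc[, model$selected[[tr]], drop = FALSE])
  }
  calls <- call_capabilities(probs, threshold)
  preds <- data.frame(
    strain_id = strains,
    p_phago = probs[, "phagocytosis"],
    p_photo = probs[, "photosynthesis"],
    p_proto = probs[, "prototrophy"],
    call_phago = calls[, "phagocytosis"],
    call_photo = calls[, "photosynthesis"],
    call_proto = calls[, "prototrophy"],
    category = assign_category(calls[, "phagocytosis"],
                               calls[, "photosynthesis"],
                               calls[, "prototrophy"]),
    completeness = vapply(gatez, function(g) g$completeness, numeric(1)),
    gated = !vapply(gatez, function(g) g$keep, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(predictions = preds, map = trophic_map(preds))
}

#' Run the full cytometric feeding assay on synthetic data
#'
#' Generates a cytometry run, quantifies it ([feeding_results()]),
#' summarises replicates, tests significance of live-prey feeding against
#' the fixed control, and checks FLB fluorescence stability.
#'
#' @param config a [facs_config()].
#' @param gate a [gate_spec()].
#' @param alpha significance threshold.
#' @param strain,nutrient metadata labels.
#' @return List `results`, `summary`, `stats` (`NULL` when the control
#'   arm is absent from the config), `stability` (per treatment).
#' @export
run_facs_assay <- function(config = facs_config(), gate = gate_spec(),
                           alpha = 0.05, strain = "strain_1",
                           nutrient = "limited") {
  run <- generate_facs_run(config, strain = strain, nutrient = nutrient)
  results <- feeding_results(run, gate)
  stats_rep <- NULL
  if (all(c("CT", "CT_PFA") %in% config$treatments))
    stats_rep <- feeding_significance(results, alpha = alpha)
  stability <- lapply(config$treatments, function(trt)
    flb_stability(run$flb_only[[sprintf("%s_t0", trt)]],
                  run$flb_only[[sprintf("%s_t3", trt)]], alpha = alpha))
  names(stability) <- config$treatments
  list(results = results, summary = summarize_feeding(results),
       stats = stats_rep, stability = stability)
}
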