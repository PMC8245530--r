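#' Configuration for the synthetic proteome world
#'
#' Defines the statistical universe the trophic-mode predictor is trained
#' and evaluated on: a set of training genomes with known trait labels
#' (trait marginals default to the 14/16/21-of-35 composition of the
#' training set for photosynthesis, phagocytosis, and prototrophy), plus
#' held-out genomes for evaluation.  Gene families are planted as mutated
#' copies of ancestral sequences: trait-linked families are carried with
#' probability `p_in` by trait-positive genomes and `p_out` by
#' trait-negative genomes; universal marker families (present in every
#' genome, the stand-in for universal single-copy orthologs) support the
#' completeness gate; background families carry no trait signal.
#'
#' @param n_training_genomes number of training genomes.
#' @param trait_group_sizes named count vector (photosynthesis,
#'   phagocytosis, prototrophy); each must be <= `n_training_genomes`.
#'   Traits are not mutually exclusive.
#' @param n_background_families trait-neutral families.
#' @param n_linked_families_per_trait planted trait-linked families per trait.
#' @param n_universal_families marker families present in all genomes.
#' @param p_in,p_out carriage probabilities for linked families in
#'   trait-positive / trait-negative genomes; `0 <= p_out < p_in <= 1`.
#' @param p_background carriage probability of background families.
#' @param family_seq_length ancestral sequence length (residues).
#' @param per_genome_mutation_rate i.i.d. substitution probability per site
#'   applied to each genome's copy of a family.
#' @param indel_rate per-site insertion/deletion probability (default 0 so
#'   family members stay equal-length and the clustering oracle is exact).
#' @param go_terms_per_family integer range, number of synthetic GO
#'   biological-process terms drawn per family.
#' @param dropout_fraction_range range of the protein-dropout fraction used
#'   when held-out proteomes are degraded to transcriptome-like sets.
#' @param n_heldout_genomes held-out evaluation genomes.
#' @param seed RNG seed; the whole world is reproducible from it.
#' @return A validated `world_config` list.
#' @export
world_config <- function(n_training_genomes = 35,
                         trait_group_sizes = c(photosynthesis = 14,
                                               phagocytosis = 16,
                                               prototrophy = 21),
                         n_background_families = 40,
                         n_linked_families_per_trait = 25,
                         n_universal_families = 50,
                         p_in = 0.9,
                         p_out = 0.05,
                         p_background = 0.5,
                         family_seq_length = 120,
                         per_genome_mutation_rate = 0.05,
                         indel_rate = 0,
                         go_terms_per_family = c(1L, 3L),
                         dropout_fraction_range = c(0, 0.1),
                         n_heldout_genomes = 20,
                         seed = 1L) {
  traits <- c("photosynthesis", "phagocytosis", "prototrophy")
  if (!all(traits %in% names(trait_group_sizes)))
    stopf("trait_group_sizes must name %s", paste(traits, collapse = ", "))
  trait_group_sizes <- trait_group_sizes[traits]
  if (any(trait_group_sizes > n_training_genomes))
    stopf("trait group sizes must not exceed n_training_genomes")
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1))
    stopf("need 0 <= p_out < p_in <= 1")
  if (any(dropout_fraction_range < 0) || any(dropout_fraction_range >= 1))
    stopf("dropout fractions must lie in [0, 1)")
  if (length(go_terms_per_family) != 2 || go_terms_per_family[1] < 1)
    stopf("go_terms_per_family must be a range with minimum >= 1")
  if (family_seq_length < 20) stopf("family_seq_length too short")
  structure(list(
    n_training_genomes = as.integer(n_training_genomes),
    trait_group_sizes = trait_group_sizes,
    n_background_families = as.integer(n_background_families),
    n_linked_families_per_trait = as.integer(n_linked_families_per_trait),
    n_universal_families = as.integer(n_universal_families),
    p_in = p_in, p_out = p_out, p_background = p_background,
    family_seq_length = as.integer(family_seq_length),
    per_genome_mutation_rate = per_genome_mutation_rate,
    indel_rate = indel_rate,
    go_terms_per_family = as.integer(go_terms_per_family),
    dropout_fraction_range = dropout_fraction_range,
    n_heldout_genomes = as.integer(n_heldout_genomes),
    seed = as.integer(seed)
  ), class = "world_config")
}

random_protein <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, sub_rate, indel_rate = 0) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  hit <- runif(n) < sub_rate
  if (any(hit)) {
    # substitute with a residue different from the current one
    repl <- vapply(chars[hit], function(a)
      sample(setdiff(AA_ALPHABET20, a), 1L), character(1))
    chars[hit] <- repl
  }
  if (indel_rate > 0) {
    out <- character(0)
    for (i in seq_along(chars)) {
      r <- runif(1)
      if (r < indel_rate / 2) next                       # deletion
      out <- c(out, chars[i])
      if (r >= indel_rate / 2 && r < indel_rate)
        out <- c(out, sample(AA_ALPHABET20, 1L))         # insertion
    }
    chars <- if (length(out)) out else chars[1]
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic proteome world
#'
#' Draws trait labels (training marginals matched exactly, overlaps random;
#' held-out labels Bernoulli at the training marginal frequencies), plants
#' universal, background and trait-linked gene families, and emits one
#' mutated copy of every carried family per genome.  Ground-truth family
#' membership, carriage draws and a flat synthetic GO annotation are
#' recorded for oracle tests.
#'
#' @param config a [world_config()].
#' @return A `trophic_world` list: `proteomes` (named list of `protein_set`
#'   objects for training + held-out strains), `labels` (data.frame with
#'   logical trait columns and a `role` column), `family_go` (named list
#'   family -> GO term character vectors), `protein_go` (protein-level
#'   inheritance of the same terms), `truth` (data.frame protein_id,
#'   strain_id, family_id), `carriage` (logical genomes x families matrix),
#'   `family_trait` (named vector: linked trait, `"background"` or
#'   `"universal"`), and the config.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  traits <- names(config$trait_group_sizes)
  n_tr <- config$n_training_genomes
  train_ids <- sprintf("train_%02d", seq_len(n_tr))
  held_ids <- if (config$n_heldout_genomes > 0)
    sprintf("heldout_%02d", seq_len(config$n_heldout_genomes)) else character(0)
  strains <- c(train_ids, held_ids)

  # labels: exact marginals for training, Bernoulli(marginal) for held-out
  labels <- data.frame(strain_id = strains,
                       role = rep(c("training", "heldout"),
                                  c(n_tr, length(held_ids))),
                       stringsAsFactors = FALSE)
  for (tr in traits) {
    pos <- rep(FALSE, length(strains))
    pos[sample.int(n_tr, config$trait_group_sizes[[tr]])] <- TRUE
    if (length(held_ids))
      pos[n_tr + seq_along(held_ids)] <-
        runif(length(held_ids)) < config$trait_group_sizes[[tr]] / n_tr
    labels[[tr]] <- pos
  }

  # family table
  fam <- data.frame(
    family_id = c(sprintf("UNI%03d", seq_len(config$n_universal_families)),
                  sprintf("BKG%03d", seq_len(config$n_background_families)),
                  unlist(lapply(traits, function(tr)
                    sprintf("%s%03d", toupper(substr(tr, 1, 3)),
                            seq_len(config$n_linked_families_per_trait))))),
    trait = c(rep("universal", config$n_universal_families),
              rep("background", config$n_background_families),
              rep(traits, each = config$n_linked_families_per_trait)),
    stringsAsFactors = FALSE)

  # ancestral sequences
  fam$ancestral <- vapply(seq_len(nrow(fam)), function(i)
    random_protein(config$family_seq_length), character(1))

  # carriage matrix (strains x families)
  carriage <- matrix(FALSE, length(strains), nrow(fam),
                     dimnames = list(strains, fam$family_id))
  for (j in seq_len(nrow(fam))) {
    tr <- fam$trait[j]
    p <- if (tr == "universal") 1
         else if (tr == "background") rep(config$p_background, length(strains))
         else ifelse(labels[[tr]], config$p_in, config$p_out)
    carriage[, j] <- runif(length(strains)) < p
  }

  # synthetic flat GO ontology: per-trait, background and housekeeping pools
  pools <- list(
    photosynthesis = sprintf("GO:%07d", 1001:1006),
    phagocytosis  = sprintf("GO:%07d", 2001:2006),
    prototrophy   = sprintf("GO:%07d", 3001:3006),
    background    = sprintf("GO:%07d", 9001:9012),
    universal     = sprintf("GO:%07d", 8001:8005))
  rng <- config$go_terms_per_family
  family_go <- lapply(seq_len(nrow(fam)), function(j) {
    pool <- pools[[fam$trait[j]]]
    k <- sample(seq(rng[1], rng[2]), 1L)
    sort(sample(pool, min(k, length(pool))))
  })
  names(family_go) <- fam$family_id

  # emit proteomes
  proteomes <- vector("list", length(strains))
  names(proteomes) <- strains
  truth <- vector("list", length(strains))
  for (i in seq_along(strains)) {
    carried <- which(carriage[i, ])
    seqs <- vapply(carried, function(j)
      mutate_protein(fam$ancestral[j], config$per_genome_mutation_rate,
                     config$indel_rate), character(1))
    ids <- sprintf("%s|%s", strains[i], fam$family_id[carried])
    names(seqs) <- ids
    proteomes[[i]] <- protein_set(strains[i], seqs, source = "genome")
    truth[[i]] <- data.frame(protein_id = ids, strain_id = strains[i],
                             family_id = fam$family_id[carried],
                             stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  protein_go <- family_go[truth$family_id]
  names(protein_go) <- truth$protein_id

  structure(list(proteomes = proteomes, labels = labels,
                 family_go = family_go, protein_go = protein_go,
                 truth = truth, carriage = carriage,
                 family_trait = setNames(fam$trait, fam$family_id),
                 config = config),
            class = "trophic_world")
}

#' Construct a protein set
#'
#' The unit of prediction: one strain's predicted proteins.  Sequences must
#' be non-empty strings over the 20 canonical residues with unique ids.
#'
#' @param strain_id strain identifier.
#' @param proteins named character vector of amino-acid sequences.
#' @param source `"genome"` or `"transcriptome"`.
#' @param merged whether several source sets were merged at strain level.
#' @export
protein_set <- function(strain_id, proteins, source = c("genome", "transcriptome"),
                        merged = FALSE) {
  source <- match.arg(source)
  if (length(proteins)) {
    if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
      stopf("protein ids must be present and unique")
    if (any(nchar(proteins) == 0)) stopf("empty sequence in protein set")
    if (any(grepl(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")), proteins)))
      stopf("non-canonical residue in protein set")
  }
  structure(list(strain_id = strain_id, proteins = proteins,
                 source = source, merged = merged),
            class = "protein_set")
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("<protein_set> %s: %d proteins (%s%s)\n", x$strain_id,
              length(x$proteins), x$source, if (x$merged) ", merged" else ""))
  invisible(x)
}

#' Degrade a proteome to a transcriptome-like protein set
#'
#' Removes a fixed count `round(dropout_fraction * n)` of proteins uniformly
#' at random, mimicking the incompleteness of transcriptome assemblies, and
#' marks the set as transcriptome-derived.
#'
#' @param ps a [protein_set()].
#' @param dropout_fraction fraction in `[0, 1)` of proteins to remove.
#' @param seed RNG seed.
#' @return A transcriptome-source [protein_set()] whose ids are a subset of
#'   the input ids.
#' @export
degrade_to_transcriptome <- function(ps, dropout_fraction, seed = 1L) {
  stopifnot(inherits(ps, "protein_set"))
  if (dropout_fraction < 0 || dropout_fraction >= 1)
    stopf("dropout_fraction must lie in [0, 1)")
  set.seed(seed)
  n <- length(ps$proteins)
  n_drop <- round(dropout_fraction * n)
  keep <- if (n_drop > 0) sort(sample.int(n, n - n_drop)) else seq_len(n)
  protein_set(ps$strain_id, ps$proteins[keep], source = "transcriptome",
              merged = ps$merged)
}

#' Write a synthetic world to disk
#'
#' Per-strain protein FASTA, a labels TSV, family GO TSV, ground-truth TSV,
#' and a JSON run manifest recording the seed and per-file MD5 digests.
#'
#' @param world a `trophic_world`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "trophic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ps in world$proteomes) {
    p <- file.path(dir, paste0(ps$strain_id, ".faa"))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(ps$proteins), p)
    paths <- c(paths, p)
  }
  lab <- file.path(dir, "labels.tsv")
  write.table(world$labels, lab, sep = "\t", quote = FALSE, row.names = FALSE)
  go <- file.path(dir, "family_go.tsv")
  write.table(data.frame(
    family_id = rep(names(world$family_go), lengths(world$family_go)),
    go_term = unlist(world$family_go, use.names = FALSE)),
    go, sep = "\t", quote = FALSE, row.names = FALSE)
  tru <- file.path(dir, "truth.tsv")
  write.table(world$truth, tru, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, lab, go, tru)
  manifest <- list(seed = world$config$seed,
                   config = unclass(world$config),
                   files = as.list(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
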