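#' All-vs-all protein similarity graph
#'
#' Builds the weighted undirected similarity graph that feeds Markov
#' clustering.  Candidate pairs are pre-filtered by shared k-mer count
#' (exact k-mer intersection, `k = 5` by default), then scored with
#' affine-gap Smith-Waterman local alignment under a standard amino-acid
#' substitution matrix; edges below `score_cutoff` are dropped.  Scores are
#' symmetric by construction and no self-loops are stored.
#'
#' @param proteins named character vector of amino-acid sequences
#'   (ids unique across the whole input).
#' @param genome_of character vector, same length: genome of origin per
#'   protein.
#' @param k k-mer length of the prefilter.
#' @param min_shared_kmers minimum exact shared k-mers for a pair to be
#'   aligned; pairs sharing none can never gain an edge.
#' @param submat 20x20 substitution matrix (default BLOSUM62 restricted to
#'   the canonical alphabet).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param score_cutoff minimum alignment score kept as an edge.
#' @param band optional Smith-Waterman band half-width (`0` = unbanded).
#' @return A `similarity_graph`: list with `nodes`, `genome` (named), and
#'   `edges` (data.frame `from`, `to`, `score` with `from < to`).
#' @export
pairwise_similarity <- function(proteins, genome_of,
                                k = 5L, min_shared_kmers = 2L,
                                submat = blosum62_matrix(),
                                gap_open = 11, gap_extend = 1,
                                score_cutoff = 50, band = 0L) {
  if (length(proteins) == 0) stopf("empty protein input")
  ids <- names(proteins)
  if (is.null(ids) || anyDuplicated(ids)) stopf("protein ids must be unique")
  if (length(genome_of) != length(proteins))
    stopf("genome_of must match proteins in length")

  cand <- kmer_candidate_pairs(proteins, k = k, min_shared = min_shared_kmers)
  edges <- data.frame(from = character(0), to = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (nrow(cand)) {
    enc <- encode_protein(proteins)
    sc <- .sw_pair_scores(enc, cand$i, cand$j, submat,
                          gap_open, gap_extend, as.integer(band))
    keep <- sc >= score_cutoff
    edges <- data.frame(from = ids[cand$i[keep]], to = ids[cand$j[keep]],
                        score = sc[keep], stringsAsFactors = FALSE)
  }
  structure(list(nodes = ids, genome = setNames(genome_of, ids),
                 edges = edges),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# unordered candidate pairs (i < j) sharing >= min_shared distinct k-mers
kmer_candidate_pairs <- function(proteins, k = 5L, min_shared = 2L) {
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  km <- lapply(proteins, kmers_of)
  dt <- data.table::data.table(
    kmer = unlist(km, use.names = FALSE),
    id = rep(seq_along(proteins), lengths(km)))
  dt2 <- dt[dt, on = "kmer", allow.cartesian = TRUE]
  dt2 <- dt2[dt2[["id"]] < dt2[["i.id"]]]
  pairs <- dt2[, list(shared = .N), by = c("id", "i.id")]
  pairs <- pairs[pairs[["shared"]] >= min_shared]
  data.frame(i = pairs[["id"]], j = pairs[["i.id"]],
             shared = pairs[["shared"]])
}

#' BLOSUM62 restricted to the 20 canonical residues
#'
#' Ordered by the package's internal alphabet so it can be handed directly
#' to the alignment kernel.
#' @return 20x20 numeric matrix.
#' @export
blosum62_matrix <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  m <- get("BLOSUM62", envir = environment())
  m[AA_ALPHABET20, AA_ALPHABET20]
}

# one entrywise-inflation + column-renormalisation step; internal but kept
# separate so the normalisation contract is directly testable
mcl_inflate <- function(M, inflation, pruning = 1e-5) {
  M <- methods::as(M, "CsparseMatrix")
  M@x <- M@x^inflation
  M <- Matrix::drop0(M)
  M@x[M@x < pruning] <- 0
  M <- Matrix::drop0(M)
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

#' Markov clustering of a similarity graph
#'
#' Classic MCL on the column-stochastic matrix derived from edge weights
#' (self-loops are added with the column-maximum weight before
#' normalisation).  Each iteration raises the matrix to the `expansion`
#' power, then applies entrywise `inflation` with column renormalisation and
#' pruning of entries below `pruning`.  Iteration stops when the largest
#' entrywise change falls below `tol`; clusters are the connected components
#' of the converged matrix's support.  Deterministic given graph and
#' parameters.
#'
#' @param g a [pairwise_similarity()] graph.
#' @param expansion integer >= 2 matrix power.
#' @param inflation real > 1 entrywise power.
#' @param max_iterations,tol,pruning iteration controls.
#' @return Named integer vector: cluster membership per node.  Isolated
#'   nodes become singleton clusters.
#' @export
mcl_cluster <- function(g, expansion = 2L, inflation = 2,
                        max_iterations = 100L, tol = 1e-6, pruning = 1e-5) {
  stopifnot(inherits(g, "similarity_graph"))
  if (length(g$nodes) == 0) stopf("empty graph")
  if (expansion < 2) stopf("expansion must be >= 2")
  if (inflation <= 1) stopf("inflation must be > 1")
  n <- length(g$nodes)
  idx <- setNames(seq_len(n), g$nodes)
  e <- g$edges
  i <- c(idx[e$from], idx[e$to])
  j <- c(idx[e$to], idx[e$from])
  x <- c(e$score, e$score)
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  # self-loops at the column max (1 for isolated nodes)
  loop <- apply_colmax(A)
  loop[loop == 0] <- 1
  A <- A + Matrix::Diagonal(x = loop)
  cs <- Matrix::colSums(A)
  M <- A %*% Matrix::Diagonal(x = 1 / cs)
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    Mold <- M
    P <- M
    for (e_i in seq_len(expansion - 1)) P <- P %*% M
    M <- mcl_inflate(P, inflation, pruning)
    if (max(abs(M - Mold)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("MCL did not converge in %d iterations; returning current partition",
          max_iterations)
  # components of the (symmetrised) support
  S <- M + Matrix::t(M)
  membership <- support_components(S)
  setNames(membership, g$nodes)
}

apply_colmax <- function(A) {
  cm <- numeric(ncol(A))
  A <- methods::as(A, "CsparseMatrix")
  p <- A@p
  for (j in seq_len(ncol(A))) {
    if (p[j + 1] > p[j]) cm[j] <- max(A@x[(p[j] + 1):p[j + 1]])
  }
  cm
}

# connected components of a sparse support by breadth-first search
support_components <- function(S) {
  S <- methods::as(S, "CsparseMatrix")
  n <- ncol(S)
  p <- S@p; ri <- S@i
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (p[v + 1] > p[v]) {
        nb <- ri[(p[v] + 1):p[v + 1]] + 1L
        new <- nb[comp[nb] == 0L]
        comp[new] <- cur
        queue <- c(queue, new)
      }
    }
  }
  comp
}

#' Assemble gene families from a cluster membership
#'
#' @param membership named integer vector from [mcl_cluster()].
#' @param genome_of named character vector protein -> genome.
#' @return A `gene_families` object: `mapping` (data.frame protein_id,
#'   family_id, strain_id) and `summary` (data.frame family_id, n_members,
#'   n_genomes).
#' @export
gene_families <- function(membership, genome_of) {
  fam_id <- sprintf("FAM%05d", membership)
  mapping <- data.frame(protein_id = names(membership), family_id = fam_id,
                        strain_id = unname(genome_of[names(membership)]),
                        stringsAsFactors = FALSE)
  agg <- split(mapping$strain_id, mapping$family_id)
  summary <- data.frame(family_id = names(agg),
                        n_members = lengths(agg),
                        n_genomes = vapply(agg, function(s)
                          length(unique(s)), integer(1)),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(mapping = mapping, summary = summary),
            class = "gene_families")
}

#' @export
print.gene_families <- function(x, ...) {
  cat(sprintf("<gene_families> %d families over %d proteins\n",
              nrow(x$summary), nrow(x$mapping)))
  invisible(x)
}

#' Genome-diversity criterion
#'
#' Keeps families containing genes from at least `min_genomes` distinct
#' genomes (default 3), the eligibility rule for building profile models.
#'
#' @param families a [gene_families()] object.
#' @param min_genomes minimum distinct genomes.
#' @return A `gene_families` object restricted to eligible families.
#' @export
diversity_filter <- function(families, min_genomes = 3L) {
  stopifnot(inherits(families, "gene_families"))
  keep <- families$summary$family_id[families$summary$n_genomes >= min_genomes]
  structure(list(
    mapping = families$mapping[families$mapping$family_id %in% keep, ,
                               drop = FALSE],
    summary = families$summary[families$summary$family_id %in% keep, ,
                               drop = FALSE]),
    class = "gene_families")
}

#' Write a family mapping (and optionally the graph) as TSV
#' @param families a [gene_families()] object.
#' @param path output TSV path.
#' @param graph optional [pairwise_similarity()] graph; written as an
#'   edge-list TSV next to `path`.
#' @export
write_families <- function(families, path, graph = NULL) {
  write.table(families$mapping, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(graph))
    write.table(graph$edges, sub("\\.tsv$", "_edges.tsv", path),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
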