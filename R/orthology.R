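# Smith-Waterman bidirectional-best-hit orthology and ortholog-group
# clustering with core / variable / strain-specific classification.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' @noRd
check_protein <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(sprintf("'%s' must be a non-empty amino-acid string", name),
         call. = FALSE)
  if (grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), x))
    stop(sprintf("'%s' contains a residue outside the 20 standard amino acids",
                 name), call. = FALSE)
  invisible(x)
}

#' @noRd
default_scoring <- function() {
  list(matrix = "BLOSUM62", gap_open = 11, gap_ext = 1)
}

.submat_cache <- new.env(parent = emptyenv())

#' @noRd
get_submat <- function(name) {
  if (!exists(name, envir = .submat_cache)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    assign(name, get(name, envir = e), envir = .submat_cache)
  }
  get(name, envir = .submat_cache)
}

# Encode proteins as 0-based indices into the substitution matrix rows.
#' @noRd
encode_protein <- function(x, submat) {
  idx <- match(strsplit(x, "", fixed = TRUE)[[1]], rownames(submat)) - 1L
  if (anyNA(idx))
    stop("residue not covered by the substitution matrix", call. = FALSE)
  idx
}

#' Smith-Waterman local alignment score and identity
#'
#' Local alignment under a substitution matrix with affine gap penalties
#' (defaults: BLOSUM62, gap open 11, extend 1; a gap of length k costs
#' `gap_open + k * gap_ext`). Identity is the fraction of identical
#' residues over all aligned columns, gap columns included in the
#' denominator. When no positive-scoring local alignment exists the score
#' is 0 (the empty alignment) and the identity is reported as 0.
#'
#' @param protein_a,protein_b Non-empty amino-acid strings (20-letter
#'   alphabet).
#' @param scoring List with elements `matrix` (substitution matrix name in
#'   Biostrings), `gap_open` and `gap_ext`.
#' @return List with `score` and `identity` (fraction in \[0, 1\]).
#' @export
sw_identity <- function(protein_a, protein_b, scoring = default_scoring()) {
  check_protein(protein_a, "protein_a")
  check_protein(protein_b, "protein_b")
  submat <- get_submat(scoring$matrix)
  st <- .sw_align_stats_cpp(encode_protein(protein_a, submat),
                            encode_protein(protein_b, submat),
                            submat, scoring$gap_open, scoring$gap_ext)
  if (st[1] <= 0 || st[3] == 0) return(list(score = st[1], identity = 0))
  list(score = st[1], identity = st[2] / st[3])
}

# Score matrix of all proteins in a (rows) against all in b (columns).
#' @noRd
sw_score_matrix <- function(a, b, scoring = default_scoring()) {
  submat <- get_submat(scoring$matrix)
  ea <- lapply(a, encode_protein, submat = submat)
  eb <- lapply(b, encode_protein, submat = submat)
  scores <- .sw_score_matrix_cpp(ea, eb, submat, scoring$gap_open,
                                 scoring$gap_ext)
  dimnames(scores) <- list(names(a), names(b))
  scores
}

#' Bidirectional best hits between two proteomes
#'
#' A pair (a, b) is emitted iff b is a's highest-scoring Smith-Waterman hit
#' in genome B, a is b's highest-scoring hit in genome A, and the alignment
#' identity is at least `min_identity` (default 0.30). Score ties in
#' best-hit selection are broken by lexicographic locus_tag for
#' determinism. Reciprocal pairs whose alignment score falls below
#' `min_score` are discarded: mutual best hits between proteins that both
#' lack a homolog in the partner genome are chance local alignments, and
#' because short random local alignments routinely exceed 30% identity
#' only an alignment-significance floor removes them.
#'
#' @param proteins_a,proteins_b Named character vectors of protein
#'   sequences; names are locus_tags.
#' @param genome_a,genome_b Genome identifiers recorded in the output.
#' @param min_identity Identity threshold in \[0, 1\].
#' @param min_score Minimum raw alignment score for a reported pair.
#' @param scoring See [sw_identity()].
#' @return `data.frame` with columns `genome_a`, `genome_b`, `locus_a`,
#'   `locus_b`, `score`, `identity`. An empty result is valid.
#' @export
bbh_orthologs <- function(proteins_a, proteins_b,
                          genome_a = "A", genome_b = "B",
                          min_identity = 0.30, min_score = 50,
                          scoring = default_scoring()) {
  stopifnot(length(proteins_a) > 0L, length(proteins_b) > 0L,
            !is.null(names(proteins_a)), !is.null(names(proteins_b)))
  scores <- sw_score_matrix(proteins_a, proteins_b, scoring)

  best_of <- function(v, labels) {
    cand <- which(v == max(v))
    cand[order(labels[cand])][1]
  }
  best_in_b <- vapply(seq_along(proteins_a),
                      function(i) best_of(scores[i, ], names(proteins_b)), 0L)
  best_in_a <- vapply(seq_along(proteins_b),
                      function(j) best_of(scores[, j], names(proteins_a)), 0L)
  rows <- list()
  for (i in seq_along(proteins_a)) {
    j <- best_in_b[i]
    if (best_in_a[j] != i) next
    if (scores[i, j] < min_score) next
    idt <- sw_identity(proteins_a[[i]], proteins_b[[j]], scoring)$identity
    if (idt < min_identity) next
    rows[[length(rows) + 1L]] <- data.frame(
      genome_a = genome_a, genome_b = genome_b,
      locus_a = names(proteins_a)[i], locus_b = names(proteins_b)[j],
      score = scores[i, j], identity = idt, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(genome_a = character(0), genome_b = character(0),
                      locus_a = character(0), locus_b = character(0),
                      score = numeric(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' BBH pairs across all genome pairs
#'
#' @param proteomes Named list: genome_id -> named character vector of
#'   protein sequences (locus_tag -> sequence).
#' @inheritParams bbh_orthologs
#' @return Row-bound BBH pair table over all unordered genome pairs.
#' @export
bbh_all_pairs <- function(proteomes, min_identity = 0.30, min_score = 50,
                          scoring = default_scoring()) {
  ids <- names(proteomes)
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      if (length(proteomes[[i]]) == 0L || length(proteomes[[j]]) == 0L) next
      out[[length(out) + 1L]] <- bbh_orthologs(
        proteomes[[i]], proteomes[[j]], ids[i], ids[j],
        min_identity = min_identity, min_score = min_score,
        scoring = scoring)
    }
  }
  do.call(rbind, out)
}

#' Cluster BBH pairs into ortholog groups
#'
#' Groups are the connected components of the BBH graph; proteins without
#' any BBH edge become singleton groups. Each group is named by the
#' locus_tag of its member in the model genome (the first genome of
#' `proteomes`) when one exists, otherwise by its lexicographically first
#' `genome|locus` member.
#'
#' @param pairs BBH pair table from [bbh_all_pairs()] (or row-bound
#'   [bbh_orthologs()] results).
#' @param proteomes Named list genome_id -> named protein vector; defines
#'   the full protein universe and the model genome.
#' @return `data.frame` with one row per protein: `group_id`, `genome_id`,
#'   `locus_tag`, `conservation_class`.
#' @export
cluster_ortholog_groups <- function(pairs, proteomes) {
  ids <- names(proteomes)
  vert <- do.call(rbind, lapply(ids, function(g)
    data.frame(genome_id = g, locus_tag = names(proteomes[[g]]),
               stringsAsFactors = FALSE)))
  vert$key <- paste(vert$genome_id, vert$locus_tag, sep = "|")
  if (!is.null(pairs) && nrow(pairs)) {
    ka <- paste(pairs$genome_a, pairs$locus_a, sep = "|")
    kb <- paste(pairs$genome_b, pairs$locus_b, sep = "|")
    missing <- setdiff(c(ka, kb), vert$key)
    if (length(missing))
      stop("BBH pair references unknown protein: ",
           paste(missing, collapse = ", "), call. = FALSE)
    gph <- igraph::graph_from_data_frame(
      data.frame(from = ka, to = kb), directed = FALSE,
      vertices = data.frame(name = vert$key))
  } else {
    gph <- igraph::make_empty_graph(n = nrow(vert), directed = FALSE)
    gph <- igraph::set_vertex_attr(gph, "name", value = vert$key)
  }
  comp <- igraph::components(gph)$membership
  vert$comp <- comp[vert$key]

  model <- ids[1]
  group_name <- vapply(split(seq_len(nrow(vert)), vert$comp), function(idx) {
    in_model <- idx[vert$genome_id[idx] == model]
    if (length(in_model)) sort(vert$locus_tag[in_model])[1]
    else sort(vert$key[idx])[1]
  }, "")
  vert$group_id <- group_name[as.character(vert$comp)]

  span <- vapply(split(vert$genome_id, vert$group_id),
                 function(g) length(unique(g)), 0L)
  n_genomes <- length(ids)
  cls <- ifelse(span == n_genomes, "core",
                ifelse(span == 1L, "strain_specific", "variable"))
  vert$conservation_class <- cls[vert$group_id]
  out <- vert[order(vert$group_id, vert$genome_id, vert$locus_tag),
              c("group_id", "genome_id", "locus_tag", "conservation_class")]
  rownames(out) <- NULL
  out
}

#' Conservation-class summary of ortholog groups
#'
#' Classifies each group as core (present in all genomes), strain-specific
#' (exactly one genome) or variable (at least two but not all), and
#' reports counts plus integer percentages of the group total.
#'
#' @param groups Group table from [cluster_ortholog_groups()].
#' @param n_genomes Number of genomes in the analyzed set.
#' @return `data.frame` with rows core/variable/strain_specific and
#'   columns `n_groups`, `percent`; total group count as attribute
#'   `"total"`.
#' @export
classify_conservation <- function(groups, n_genomes) {
  check_scalar_int(n_genomes, "n_genomes", min = 1)
  per_group <- tapply(groups$genome_id, groups$group_id,
                      function(g) length(unique(g)))
  if (any(per_group > n_genomes))
    stop("group cites more genomes than n_genomes", call. = FALSE)
  counts <- c(core = sum(per_group == n_genomes),
              variable = sum(per_group > 1L & per_group < n_genomes),
              strain_specific = sum(per_group == 1L))
  conservation_percentages(counts[["core"]], counts[["variable"]],
                           counts[["strain_specific"]])
}

#' Conservation-class percentages from class counts
#'
#' The printed-summary arithmetic: percentages are class count over total
#' group count, rounded to the nearest integer percent.
#'
#' @param n_core,n_variable,n_specific Group counts per class.
#' @return `data.frame` with columns `class`, `n_groups`, `percent`;
#'   attribute `"total"` carries the group total.
#' @export
conservation_percentages <- function(n_core, n_variable, n_specific) {
  total <- n_core + n_variable + n_specific
  out <- data.frame(
    class = c("core", "variable", "strain_specific"),
    n_groups = c(n_core, n_variable, n_specific),
    percent = round(100 * c(n_core, n_variable, n_specific) / total),
    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}
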