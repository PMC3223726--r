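# Comparative analytics over reconstructed regulons: TF repertoire
# summaries, regulon overlap and cascades, and expression-correlation
# subregulon detection.

#' TF repertoire summary per protein family and genome
#'
#' @param genomes Named list of [genome] objects whose gene tables carry
#'   `tf_family` labels (`NA` for non-TF genes).
#' @return List with `counts` (family x genome integer matrix), `totals`
#'   (TF genes per genome) and `multi_member_fraction` (per genome, the
#'   fraction of its TFs that belong to families with at least two members
#'   in that genome).
#' @export
repertoire_summary <- function(genomes) {
  gids <- vapply(genomes, function(g) g$genome_id, "")
  tf <- do.call(rbind, lapply(genomes, function(g) {
    sel <- !is.na(g$genes$tf_family)
    if (!any(sel)) return(NULL)
    data.frame(genome_id = g$genome_id, family = g$genes$tf_family[sel],
               stringsAsFactors = FALSE)
  }))
  if (is.null(tf) || nrow(tf) == 0L) {
    counts <- matrix(0L, nrow = 0, ncol = length(gids),
                     dimnames = list(NULL, gids))
    return(list(counts = counts,
                totals = stats::setNames(integer(length(gids)), gids),
                multi_member_fraction = stats::setNames(
                  rep(NA_real_, length(gids)), gids)))
  }
  counts <- table(factor(tf$family), factor(tf$genome_id, levels = gids))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  totals <- colSums(counts)
  multi <- vapply(seq_along(gids), function(j) {
    if (totals[j] == 0L) return(NA_real_)
    sum(counts[counts[, j] >= 2L, j]) / totals[j]
  }, 0)
  list(counts = counts, totals = totals,
       multi_member_fraction = stats::setNames(multi, gids))
}

#' Regulon overlap report
#'
#' Maps each regulated operon to the regulons controlling it, reports the
#' degree histogram (number of operons controlled by exactly k regulons)
#' and detects regulatory cascades: member operons containing a gene that
#' is itself the regulator of another reconstructed regulon in the same
#' genome.
#'
#' @param regulons Named list of `regulon` objects.
#' @param groups Optional ortholog-group table; needed (together with
#'   `operons_by_genome`) for cascade detection.
#' @param operons_by_genome Optional named list of operon tables used to
#'   resolve operon member genes for cascades.
#' @return List with `controllers` (`data.frame`: `genome_id`,
#'   `operon_id`, `regulons` comma-joined, `degree`), `histogram` (named
#'   integer vector k -> count) and `cascades` (`data.frame`:
#'   `regulator_regulon`, `target_regulon`, `genome_id`, `tf_gene`).
#' @export
regulon_overlap <- function(regulons, groups = NULL,
                            operons_by_genome = NULL) {
  nm <- names(regulons)
  if (is.null(nm)) nm <- vapply(regulons, function(r) as.character(r$tf_group), "")
  pairs <- do.call(rbind, lapply(seq_along(regulons), function(i) {
    m <- regulons[[i]]$members
    if (nrow(m) == 0L) return(NULL)
    data.frame(regulon = nm[i], genome_id = m$genome_id,
               operon_id = m$operon_id, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) {
    return(list(controllers = data.frame(genome_id = character(0),
                                         operon_id = character(0),
                                         regulons = character(0),
                                         degree = integer(0)),
                histogram = integer(0),
                cascades = empty_cascades()))
  }
  key <- paste(pairs$genome_id, pairs$operon_id, sep = "|")
  ctl <- lapply(split(pairs$regulon, key), function(r) sort(unique(r)))
  controllers <- data.frame(
    genome_id = sub("\\|.*$", "", names(ctl)),
    operon_id = sub("^.*\\|", "", names(ctl)),
    regulons = vapply(ctl, paste, "", collapse = ","),
    degree = vapply(ctl, length, 0L), stringsAsFactors = FALSE)
  rownames(controllers) <- NULL
  hist <- table(controllers$degree)
  histogram <- stats::setNames(as.integer(hist), names(hist))

  cascades <- empty_cascades()
  if (!is.null(groups) && !is.null(operons_by_genome)) {
    rows <- list()
    for (j in seq_along(regulons)) {
      tf_grp <- regulons[[j]]$tf_group
      if (is.na(tf_grp)) next
      tf_loci <- groups[groups$group_id == tf_grp, , drop = FALSE]
      for (i in seq_along(regulons)) {
        if (i == j) next
        m <- regulons[[i]]$members
        for (k in seq_len(nrow(m))) {
          gid <- m$genome_id[k]
          ops <- operons_by_genome[[gid]]
          if (is.null(ops)) next
          genes <- ops$members[[match(m$operon_id[k], ops$operon_id)]]
          hit <- tf_loci$locus_tag[tf_loci$genome_id == gid &
                                     tf_loci$locus_tag %in% genes]
          if (length(hit)) {
            rows[[length(rows) + 1L]] <- data.frame(
              regulator_regulon = nm[i], target_regulon = nm[j],
              genome_id = gid, tf_gene = hit[1], stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(rows)) cascades <- unique(do.call(rbind, rows))
    rownames(cascades) <- NULL
  }
  list(controllers = controllers, histogram = histogram, cascades = cascades)
}

#' @noRd
empty_cascades <- function() {
  data.frame(regulator_regulon = character(0), target_regulon = character(0),
             genome_id = character(0), tf_gene = character(0),
             stringsAsFactors = FALSE)
}

#' Pairwise Pearson correlation matrix over a gene set
#'
#' @param expr Numeric matrix, genes in rows, conditions in columns (at
#'   least 3 conditions). Genes with a constant profile (undefined
#'   correlation) are excluded with a warning rather than propagating
#'   `NaN`.
#' @return Symmetric correlation matrix with unit diagonal over the
#'   retained genes.
#' @export
pearson_matrix <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L)
    stop("at least 3 conditions are required", call. = FALSE)
  const <- apply(expr, 1L, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("excluding constant-profile genes: ",
            paste(rownames(expr)[const], collapse = ", "), call. = FALSE)
    expr <- expr[!const, , drop = FALSE]
  }
  r <- stats::cor(t(expr))
  diag(r) <- 1
  r
}

#' Split a regulon into co-expression subregulons
#'
#' Builds the graph whose edges connect gene pairs with Pearson r at least
#' `r_threshold` and returns its connected components (single-linkage
#' clustering at the threshold).
#'
#' @param cormat Symmetric correlation matrix from [pearson_matrix()].
#' @param r_threshold Correlation threshold in (-1, 1); default 0.5.
#' @return List with `labels` (named integer cluster labels partitioning
#'   the gene set), `n_clusters` and `r_threshold`.
#' @export
split_subregulons <- function(cormat, r_threshold = 0.5) {
  if (!is.numeric(r_threshold) || length(r_threshold) != 1L ||
      r_threshold <= -1 || r_threshold >= 1)
    stop("r_threshold must lie in (-1, 1)", call. = FALSE)
  cormat <- as.matrix(cormat)
  adj <- (cormat >= r_threshold)
  diag(adj) <- TRUE
  gph <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
  comp <- igraph::components(gph)$membership
  labels <- stats::setNames(as.integer(comp), rownames(cormat))
  list(labels = labels, n_clusters = max(labels), r_threshold = r_threshold)
}
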