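# Cross-genome regulon assembly: the consistency filter, propagation of
# known regulons, ab initio inference of novel regulons, TF attribution
# and conservation matrices.

#' Cross-genome consistency filter
#'
#' A candidate operon in genome g is retained iff orthologs of its lead
#' gene in at least `min_other_genomes` genomes other than g are
#' themselves lead genes of candidate operons (i.e. their upstreams also
#' carry a site above the scan threshold). Candidates listed in
#' `functional_links` are retained regardless and flagged
#' `functionally_linked` (user-supplied pathway evidence).
#'
#' @param candidates `data.frame` with at least `genome_id`, `operon_id`,
#'   `lead_gene` (one row per candidate operon).
#' @param groups Ortholog-group table from [cluster_ortholog_groups()].
#' @param min_other_genomes Required number of other genomes with a
#'   hit-bearing ortholog (default 2).
#' @param functional_links Optional character vector of
#'   `"genome_id|operon_id"` keys to retain on functional evidence.
#' @return The retained subset of `candidates` with an added `evidence`
#'   column (`"site_conserved"` or `"functionally_linked"`). Output is
#'   always a subset of the input.
#' @export
consistency_filter <- function(candidates, groups, min_other_genomes = 2,
                               functional_links = NULL) {
  check_scalar_int(min_other_genomes, "min_other_genomes", min = 0)
  if (nrow(candidates) == 0L) {
    candidates$evidence <- character(0)
    return(candidates)
  }
  gkey <- paste(groups$genome_id, groups$locus_tag, sep = "|")
  cand_group <- groups$group_id[match(
    paste(candidates$genome_id, candidates$lead_gene, sep = "|"), gkey)]
  if (anyNA(cand_group))
    stop("candidate lead gene not found in any ortholog group: ",
         paste(candidates$lead_gene[is.na(cand_group)], collapse = ", "),
         call. = FALSE)
  keep <- logical(nrow(candidates))
  evid <- rep("site_conserved", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    grp <- cand_group[i]
    supporters <- unique(candidates$genome_id[cand_group == grp &
                                                candidates$genome_id !=
                                                  candidates$genome_id[i]])
    keep[i] <- length(supporters) >= min_other_genomes
  }
  if (!is.null(functional_links)) {
    key <- paste(candidates$genome_id, candidates$operon_id, sep = "|")
    linked <- key %in% functional_links & !keep
    keep <- keep | linked
    evid[linked] <- "functionally_linked"
  }
  out <- candidates[keep, , drop = FALSE]
  out$evidence <- evid[keep]
  rownames(out) <- NULL
  out
}

# Shared per-genome precomputation: operons and upstream regions.
#' @noRd
genome_context <- function(genomes, max_gap = 200, max_len = 350) {
  ops <- lapply(genomes, call_operons, max_gap_bp = max_gap)
  regs <- mapply(function(g, o) upstream_regions(g, o, max_len = max_len),
                 genomes, ops, SIMPLIFY = FALSE)
  list(operons = ops, regions = regs)
}

# Candidate table from scan hits: one row per (genome, operon), keeping
# the best-scoring site per operon.
#' @noRd
hits_to_candidates <- function(hits, operons_by_genome) {
  if (nrow(hits) == 0L) {
    return(data.frame(genome_id = character(0), operon_id = character(0),
                      lead_gene = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sequence = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  hits <- hits[!is.na(hits$target_operon), , drop = FALSE]
  key <- paste(hits$genome_id, hits$target_operon, sep = "|")
  best <- tapply(seq_len(nrow(hits)), key, function(idx)
    idx[which.max(hits$score[idx])])
  h <- hits[unlist(best), , drop = FALSE]
  lead <- vapply(seq_len(nrow(h)), function(i) {
    ops <- operons_by_genome[[h$genome_id[i]]]
    ops$lead_gene[match(h$target_operon[i], ops$operon_id)]
  }, "")
  data.frame(genome_id = h$genome_id, operon_id = h$target_operon,
             lead_gene = lead, start = h$start, end = h$end,
             strand = h$strand, sequence = h$sequence, score = h$score,
             stringsAsFactors = FALSE)
}

# Training regions for a set of target lead genes: the upstreams of the
# operons led by orthologs of those genes in the given genomes.
#' @noRd
ortholog_training_regions <- function(target_keys, groups, genome_ids, ctx) {
  gkey <- paste(groups$genome_id, groups$locus_tag, sep = "|")
  target_groups <- unique(groups$group_id[match(target_keys, gkey)])
  target_groups <- target_groups[!is.na(target_groups)]
  sel <- groups[groups$group_id %in% target_groups &
                  groups$genome_id %in% genome_ids, , drop = FALSE]
  regions <- character(0)
  ops_of <- character(0)
  for (i in seq_len(nrow(sel))) {
    gid <- sel$genome_id[i]
    ops <- ctx$operons[[gid]]
    row <- which(vapply(ops$members, function(m) sel$locus_tag[i] %in% m, TRUE))
    if (length(row) == 0L) next
    # train on operon lead upstreams only
    if (ops$lead_gene[row] != sel$locus_tag[i]) next
    reg <- ctx$regions[[gid]]
    j <- match(ops$operon_id[row], reg$operon_id)
    if (is.na(j) || reg$empty[j]) next
    nm <- paste(gid, ops$operon_id[row], sep = "|")
    regions[nm] <- reg$sequence[j]
    ops_of[nm] <- ops$operon_id[row]
  }
  regions
}

#' Propagate a known regulon across a genome set
#'
#' Implements the five-step comparative propagation workflow:
#' (i) locate orthologs of the model-genome regulator; (ii) take the known
#' target genes (and sites) in the model genome; (iii) collect orthologs
#' of the targets in every genome encoding the regulator and extract their
#' upstream regions; (iv) rediscover the binding motif on that training
#' set and compare it with the seed motif; (v) scan all upstream regions
#' of the regulator-encoding genomes at the training-minimum threshold and
#' apply the cross-genome consistency filter. When the filtered membership
#' differs from the training set the procedure is repeated once from step
#' (iii) with the enlarged training set.
#'
#' @param seed_regulon List with `model_genome`, `tf_locus` (regulator
#'   locus_tag in the model genome), `targets` (character vector of target
#'   lead-gene locus_tags in the model genome), optional `sites`
#'   (character vector of known site sequences used to build the seed
#'   motif) and optional `motif` (a [weight_matrix] overriding `sites`).
#' @param genomes Named list of [genome] objects (model genome included).
#' @param groups Ortholog-group table from [cluster_ortholog_groups()].
#' @param params List of tuning parameters: `motif_len` (required unless
#'   seed sites are given), `max_mismatched_pairs`, `max_ignored` (default
#'   0 for propagation: known targets are trusted), `max_iter`,
#'   `max_seeds`, `min_other_genomes` (default 2), `max_gap`, `max_len`,
#'   `functional_links`, `repeat_once` (default TRUE).
#' @return An object of class `regulon` with fields `tf_group`, `motif`,
#'   `threshold`, `members`, `provenance = "propagated"`, `comparison`
#'   (seed-vs-rediscovered motif, when a seed motif was available),
#'   `genomes` and `iterated`; or, when the regulator has no ortholog in
#'   any genome, a skip report `list(skipped = TRUE, reason = ...)`.
#' @export
propagate_regulon <- function(seed_regulon, genomes, groups, params = list()) {
  p <- utils::modifyList(list(
    motif_len = NULL, max_mismatched_pairs = NULL, max_ignored = 0,
    max_iter = 30, max_seeds = 100, min_other_genomes = 2,
    max_gap = 200, max_len = 350, functional_links = NULL,
    repeat_once = TRUE), params)

  seed_motif <- seed_regulon$motif
  if (is.null(seed_motif) && !is.null(seed_regulon$sites))
    seed_motif <- symmetrize(weight_matrix(site_counts(seed_regulon$sites)))
  L <- if (!is.null(p$motif_len)) p$motif_len
       else if (!is.null(seed_motif)) seed_motif$L
       else stop("params$motif_len required when the seed has no sites/motif",
                 call. = FALSE)
  if (is.null(p$max_mismatched_pairs)) p$max_mismatched_pairs <- ceiling(L / 4)

  # step i: regulator orthologs
  gkey <- paste(groups$genome_id, groups$locus_tag, sep = "|")
  tf_key <- paste(seed_regulon$model_genome, seed_regulon$tf_locus, sep = "|")
  tf_group <- groups$group_id[match(tf_key, gkey)]
  if (is.na(tf_group)) {
    return(list(skipped = TRUE,
                reason = sprintf("regulator %s not found in ortholog groups",
                                 seed_regulon$tf_locus)))
  }
  tf_genomes <- intersect(names(genomes),
                          unique(groups$genome_id[groups$group_id == tf_group]))
  if (length(tf_genomes) == 0L) {
    return(list(skipped = TRUE,
                reason = sprintf("regulator group %s has no member in the genome set",
                                 tf_group)))
  }

  ctx <- genome_context(genomes[tf_genomes], p$max_gap, p$max_len)

  # steps ii-iii
  target_keys <- paste(seed_regulon$model_genome, seed_regulon$targets,
                       sep = "|")
  run_once <- function(target_keys) {
    training <- ortholog_training_regions(target_keys, groups, tf_genomes, ctx)
    if (length(training) < 3L)
      stop(sprintf("regulon for %s: fewer than 3 orthologous target upstreams",
                   seed_regulon$tf_locus), call. = FALSE)
    # step iv
    wm <- discover_motif(training, L,
                         max_mismatched_pairs = p$max_mismatched_pairs,
                         max_ignored = p$max_ignored, max_iter = p$max_iter,
                         max_seeds = p$max_seeds)
    # step v
    thr <- training_threshold(wm)
    all_regions <- do.call(rbind, ctx$regions[tf_genomes])
    hits <- scan_sites(wm, thr, regions = all_regions)
    cand <- hits_to_candidates(hits, ctx$operons)
    members <- consistency_filter(cand, groups, p$min_other_genomes,
                                  p$functional_links)
    list(wm = wm, threshold = thr, members = members, training = training)
  }

  res <- run_once(target_keys)
  iterated <- FALSE
  if (p$repeat_once) {
    got <- sort(unique(paste(res$members$genome_id, res$members$operon_id,
                             sep = "|")))
    trained <- sort(names(res$training))
    if (!identical(got, trained)) {
      new_keys <- unique(c(target_keys,
                           paste(res$members$genome_id, res$members$lead_gene,
                                 sep = "|")))
      res <- run_once(new_keys)
      iterated <- TRUE
    }
  }

  comparison <- if (!is.null(seed_motif))
    compare_motifs(res$wm, seed_motif) else NULL
  structure(list(
    tf_group = tf_group, motif = res$wm, threshold = res$threshold,
    members = res$members, provenance = "propagated",
    comparison = comparison, genomes = tf_genomes, iterated = iterated,
    skipped = FALSE), class = "regulon")
}

#' Infer a novel regulon from a training set of operons
#'
#' Ab initio workflow for regulons without a characterized regulator:
#' discover a shared palindromic motif in the pooled upstream regions of a
#' training set of potentially co-regulated operons, scan all genomes'
#' upstream regions at the training-minimum threshold, and apply the
#' consistency filter. The regulator is left unassigned (see
#' [attribute_tf()]); a regulon whose motif information content falls
#' below `min_ic_per_col` bits per column is flagged `low_ic` (no
#' confident motif).
#'
#' @param training Named character vector of training upstream sequences,
#'   names `"genome_id|operon_id"`.
#' @param genomes Named list of [genome] objects to scan.
#' @param groups Ortholog-group table.
#' @param params As in [propagate_regulon()]; `motif_len` required;
#'   `max_ignored` defaults to `floor(n/5)`; plus `min_ic_per_col`
#'   (default 1.0 bits).
#' @return An object of class `regulon` with `provenance = "ab_initio"`,
#'   `tf_group = NA` and logical `low_ic`.
#' @export
infer_novel_regulon <- function(training, genomes, groups, params = list()) {
  p <- utils::modifyList(list(
    motif_len = NULL, max_mismatched_pairs = NULL, max_ignored = NULL,
    max_iter = 30, max_seeds = 100, min_other_genomes = 2,
    max_gap = 200, max_len = 350, functional_links = NULL,
    min_ic_per_col = 1.0), params)
  if (is.null(p$motif_len)) stop("params$motif_len is required", call. = FALSE)
  if (length(training) < 3L)
    stop("need at least 3 training operons with non-empty upstreams",
         call. = FALSE)
  if (is.null(p$max_mismatched_pairs))
    p$max_mismatched_pairs <- ceiling(p$motif_len / 4)

  wm <- discover_motif(training, p$motif_len,
                       max_mismatched_pairs = p$max_mismatched_pairs,
                       max_ignored = p$max_ignored, max_iter = p$max_iter,
                       max_seeds = p$max_seeds)
  thr <- training_threshold(wm)
  ctx <- genome_context(genomes, p$max_gap, p$max_len)
  all_regions <- do.call(rbind, ctx$regions)
  hits <- scan_sites(wm, thr, regions = all_regions)
  cand <- hits_to_candidates(hits, ctx$operons)
  members <- consistency_filter(cand, groups, p$min_other_genomes,
                                p$functional_links)
  low_ic <- (wm$ic / wm$L) < p$min_ic_per_col
  if (low_ic)
    warning("discovered motif has low information content; ",
            "no confident regulon", call. = FALSE)
  structure(list(
    tf_group = NA_character_, motif = wm, threshold = thr,
    members = members, provenance = "ab_initio", comparison = NULL,
    genomes = names(genomes), iterated = FALSE, low_ic = low_ic,
    skipped = FALSE), class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> TF group: %s (%s)\n",
              ifelse(is.na(x$tf_group), "unassigned", x$tf_group),
              x$provenance))
  cat(sprintf("  %d member operons in %d genomes; threshold %.2f; motif %s\n",
              nrow(x$members), length(unique(x$members$genome_id)),
              x$threshold, x$motif$consensus))
  invisible(x)
}

#' Attribute a regulon to a candidate transcription factor
#'
#' Scores every TF-labelled ortholog group on three boolean evidence
#' types: (i) positional clustering -- a group member lies within 2 genes
#' of a member operon on its chromosome; (ii) autoregulation -- the
#' group's own operon is among the regulon members; (iii) phylogenetic
#' pattern -- the group's genome-presence set equals the regulon's.
#' Groups with the highest evidence count are returned; ties are reported,
#' not broken. An empty attribution (no TF with any evidence) is valid: a
#' regulon may have a hitherto unknown cognate regulator.
#'
#' @param regulon A `regulon` object.
#' @param genomes Named list of [genome] objects (for `tf_family` labels
#'   and gene order).
#' @param groups Ortholog-group table.
#' @param operons_by_genome Named list of operon tables (from
#'   [call_operons()]); computed with defaults when `NULL`.
#' @return `data.frame` of the top-scoring TF groups (zero rows when no
#'   evidence): `group_id`, `tf_family`, `positional`, `autoregulated`,
#'   `pattern_match`, `n_evidence`.
#' @export
attribute_tf <- function(regulon, genomes, groups, operons_by_genome = NULL) {
  if (is.null(operons_by_genome))
    operons_by_genome <- lapply(genomes, call_operons)
  # TF-labelled groups: any member gene carries a tf_family label
  labels <- do.call(rbind, lapply(genomes, function(g)
    g$genes[!is.na(g$genes$tf_family),
            c("locus_tag", "tf_family"), drop = FALSE]))
  if (is.null(labels) || nrow(labels) == 0L) return(empty_attribution())
  gkey <- paste(groups$genome_id, groups$locus_tag, sep = "|")
  tf_groups <- unique(groups$group_id[groups$locus_tag %in% labels$locus_tag])
  if (length(tf_groups) == 0L) return(empty_attribution())

  mem_key <- paste(regulon$members$genome_id, regulon$members$operon_id,
                   sep = "|")
  regulon_presence <- sort(unique(regulon$members$genome_id))

  rows <- lapply(tf_groups, function(grp) {
    sel <- groups[groups$group_id == grp, , drop = FALSE]
    fam <- labels$tf_family[match(sel$locus_tag, labels$locus_tag)]
    fam <- fam[!is.na(fam)][1]
    positional <- FALSE; autoreg <- FALSE
    for (i in seq_len(nrow(sel))) {
      gid <- sel$genome_id[i]
      if (!gid %in% names(genomes)) next
      g <- genomes[[gid]]
      tf_idx <- match(sel$locus_tag[i], g$genes$locus_tag)
      if (is.na(tf_idx)) next
      ops <- operons_by_genome[[gid]]
      mem_ops <- regulon$members$operon_id[regulon$members$genome_id == gid]
      if (length(mem_ops)) {
        mem_gene_idx <- unlist(lapply(mem_ops, function(op) {
          m <- ops$members[[match(op, ops$operon_id)]]
          match(m, g$genes$locus_tag)
        }))
        if (any(abs(mem_gene_idx - tf_idx) <= 2L)) positional <- TRUE
        own_op <- ops$operon_id[vapply(ops$members, function(m)
          sel$locus_tag[i] %in% m, TRUE)]
        if (length(own_op) && paste(gid, own_op[1], sep = "|") %in% mem_key)
          autoreg <- TRUE
      }
    }
    pattern <- identical(sort(unique(sel$genome_id[sel$genome_id %in%
                                                     names(genomes)])),
                         regulon_presence)
    data.frame(group_id = grp, tf_family = fam, positional = positional,
               autoregulated = autoreg, pattern_match = pattern,
               n_evidence = positional + autoreg + pattern,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_evidence > 0L, , drop = FALSE]
  if (nrow(out) == 0L) return(empty_attribution())
  out <- out[out$n_evidence == max(out$n_evidence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @noRd
empty_attribution <- function() {
  data.frame(group_id = character(0), tf_family = character(0),
             positional = logical(0), autoregulated = logical(0),
             pattern_match = logical(0), n_evidence = integer(0),
             stringsAsFactors = FALSE)
}

#' Regulon-by-genome conservation matrix
#'
#' @param regulons Named list of `regulon` objects (names become row ids;
#'   unnamed regulons use their TF group).
#' @param genome_ids Character vector of genome columns.
#' @return Character matrix with entries `"+"` (regulon has at least one
#'   member operon in that genome) and `"-"`; row and column sums of
#'   presences attached as attributes `"row_marginals"` and
#'   `"col_marginals"`.
#' @export
conservation_matrix <- function(regulons, genome_ids) {
  if (length(regulons) == 0L) {
    m <- matrix(character(0), nrow = 0, ncol = length(genome_ids),
                dimnames = list(NULL, genome_ids))
    attr(m, "row_marginals") <- integer(0)
    attr(m, "col_marginals") <- stats::setNames(integer(length(genome_ids)),
                                                genome_ids)
    return(m)
  }
  nm <- names(regulons)
  if (is.null(nm))
    nm <- vapply(regulons, function(r) as.character(r$tf_group), "")
  m <- t(vapply(regulons, function(r)
    ifelse(genome_ids %in% unique(r$members$genome_id), "+", "-"),
    character(length(genome_ids))))
  dimnames(m) <- list(nm, genome_ids)
  attr(m, "row_marginals") <- rowSums(m == "+")
  attr(m, "col_marginals") <- colSums(m == "+")
  m
}
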