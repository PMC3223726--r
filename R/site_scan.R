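# PWM site scanning with the training-set-minimum threshold.

#' Scan threshold from a training set
#'
#' The threshold for site search is the lowest score observed in the
#' training set, so every training site is re-detected by construction
#' (comparison in [scan_sites()] is `>=`).
#'
#' @param wm A [weight_matrix].
#' @param training_windows Character vector of training site windows; when
#'   `NULL`, the member windows stored in `wm` are used.
#' @return The minimum training-window score.
#' @export
training_threshold <- function(wm, training_windows = NULL) {
  if (is.null(training_windows)) {
    if (is.null(wm$members) || nrow(wm$members) == 0L)
      stop("empty training set: no windows given and motif has no members",
           call. = FALSE)
    return(min(score_site(wm, wm$members$sequence)))
  }
  if (length(training_windows) == 0L)
    stop("empty training set", call. = FALSE)
  min(score_site(wm, training_windows))
}

#' Scan sequences for motif sites above a threshold
#'
#' Every window scoring at least `threshold` is reported. Either a set of
#' upstream `regions` (the default search space: candidate regulatory
#' sites in upstream regions) or a whole `genome` may be scanned. For
#' palindromically symmetric profiles a window and its reverse complement
#' score identically, so only the forward strand is enumerated and hits
#' are reported once with strand `"+"`; for asymmetric profiles both
#' strands are scanned and duplicate intervals with equal scores keep the
#' forward-strand record. Windows containing N are skipped.
#'
#' @param wm A [weight_matrix].
#' @param threshold Finite score threshold (use [training_threshold()] for
#'   the training-set minimum rule).
#' @param regions Upstream-region table from [upstream_regions()]
#'   (possibly row-bound across genomes).
#' @param genome A [genome] object for genome-wide scanning.
#' @param both_strands Scan the reverse strand too (ignored, and
#'   effectively TRUE, for symmetric profiles).
#' @return `data.frame` of hits sorted by (genome, start): `genome_id`,
#'   `start`, `end` (genomic 0-based half-open), `strand`, `sequence`
#'   (site in its reported orientation), `score`, `target_operon` (`NA`
#'   for genome-wide hits) and `region_offset`.
#' @export
scan_sites <- function(wm, threshold, regions = NULL, genome = NULL,
                       both_strands = TRUE) {
  stopifnot(inherits(wm, "weight_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("threshold must be a single finite number", call. = FALSE)
  if (is.null(regions) == is.null(genome))
    stop("supply exactly one of 'regions' or 'genome'", call. = FALSE)

  if (!is.null(genome)) {
    regions <- data.frame(operon_id = NA_character_,
                          genome_id = genome$genome_id, strand = "+",
                          start = 0L, end = nchar(genome$sequence),
                          length = nchar(genome$sequence), empty = FALSE,
                          sequence = genome$sequence,
                          stringsAsFactors = FALSE)
  }
  L <- wm$L
  hits <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    wins <- window_matrix(r$sequence, L)
    if (length(wins$offsets) == 0L) next
    rows <- list()
    fwd_sc <- score_window_matrix(wins$mat, wm$weights)
    keep <- fwd_sc >= threshold
    if (any(keep)) {
      rows$fwd <- data.frame(offset = wins$offsets[keep],
                             rc = FALSE, score = fwd_sc[keep],
                             sequence = decode_windows(wins$mat[keep, , drop = FALSE]),
                             stringsAsFactors = FALSE)
    }
    if (both_strands && !wm$symmetric) {
      rc_mat <- matrix(COMP_IDX[wins$mat[, L:1, drop = FALSE]],
                       nrow = nrow(wins$mat))
      rc_sc <- score_window_matrix(rc_mat, wm$weights)
      keep <- rc_sc >= threshold
      if (any(keep)) {
        rows$rev <- data.frame(offset = wins$offsets[keep],
                               rc = TRUE, score = rc_sc[keep],
                               sequence = decode_windows(rc_mat[keep, , drop = FALSE]),
                               stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0L) next
    h <- do.call(rbind, rows)
    # drop reverse-strand duplicates of equal-scoring forward hits
    if (any(h$rc) && any(!h$rc)) {
      fwd <- h[!h$rc, ]
      dup <- h$rc & (h$offset %in% fwd$offset) &
        vapply(seq_len(nrow(h)), function(k) {
          h$rc[k] && any(fwd$offset == h$offset[k] &
                           abs(fwd$score - h$score[k]) < 1e-9)
        }, TRUE)
      h <- h[!dup, , drop = FALSE]
    }
    # map region-local offsets to genomic coordinates and strands
    if (r$strand == "+") {
      gstart <- r$start + h$offset
      strand <- ifelse(h$rc, "-", "+")
    } else {
      gstart <- r$end - h$offset - L
      strand <- ifelse(h$rc, "+", "-")
    }
    hits[[i]] <- data.frame(genome_id = r$genome_id, start = gstart,
                            end = gstart + L, strand = strand,
                            sequence = h$sequence, score = h$score,
                            target_operon = r$operon_id,
                            region_offset = h$offset,
                            stringsAsFactors = FALSE)
  }
  hits <- hits[!vapply(hits, is.null, TRUE)]
  if (length(hits) == 0L) {
    return(data.frame(genome_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sequence = character(0), score = numeric(0),
                      target_operon = character(0), region_offset = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$genome_id, out$start, out$target_operon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign genome-wide hits to target operons
#'
#' Hits falling entirely inside an operon's upstream region get that operon
#' as target; a hit inside a divergent intergenic segment shared by two
#' upstream regions yields two records, one per operon. In
#' `"upstream_only"` mode hits outside every upstream region are dropped;
#' in `"genome_wide"` mode they are kept and flagged `intragenic` or
#' `intergenic` depending on overlap with annotated gene bodies.
#'
#' @param hits Hit table from [scan_sites()] (typically a genome-wide scan).
#' @param regions Upstream-region table from [upstream_regions()].
#' @param mode `"upstream_only"` (default) or `"genome_wide"`.
#' @param genome Optional [genome] used to distinguish intragenic from
#'   intergenic unassigned hits in `"genome_wide"` mode.
#' @return Hit table with `target_operon` and a `location` column
#'   (`"upstream"`, `"intragenic"` or `"intergenic"`).
#' @export
assign_targets <- function(hits, regions,
                           mode = c("upstream_only", "genome_wide"),
                           genome = NULL) {
  mode <- match.arg(mode)
  if (nrow(hits) == 0L) {
    hits$location <- character(0)
    return(hits)
  }
  out <- vector("list", nrow(hits))
  for (k in seq_len(nrow(hits))) {
    h <- hits[k, ]
    inside <- regions$genome_id == h$genome_id &
      regions$start <= h$start & regions$end >= h$end & !regions$empty
    if (any(inside)) {
      reg <- regions[inside, , drop = FALSE]
      rep_h <- h[rep(1L, nrow(reg)), , drop = FALSE]
      rep_h$target_operon <- reg$operon_id
      rep_h$location <- "upstream"
      out[[k]] <- rep_h
    } else if (mode == "genome_wide") {
      h$target_operon <- NA_character_
      h$location <- "intergenic"
      if (!is.null(genome)) {
        g <- genome$genes
        if (any(g$start < h$end & g$end > h$start)) h$location <- "intragenic"
      }
      out[[k]] <- h
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    hits <- hits[0, , drop = FALSE]
    hits$location <- character(0)
    return(hits)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
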