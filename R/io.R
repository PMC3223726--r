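# Flat-file exports: motifs in MEME minimal text format, site hits as
# BED6(+), regulons as JSON-lines and TSV, conservation matrices as CSV.

#' Write a motif in MEME minimal text format
#'
#' Emits a uniform background line and the letter-probability matrix of
#' the motif (pseudocounted frequencies), plus `nsites`. A sidecar TSV of
#' member windows (`region`, `offset`, `sequence`, `score`) is written
#' next to it when the motif has members.
#'
#' @param wm A [weight_matrix].
#' @param path Output path; the sidecar (if any) gets suffix
#'   `.members.tsv`.
#' @param name Motif name written in the file.
#' @return Invisibly, `path`.
#' @export
write_motif_meme <- function(wm, path, name = "motif1") {
  stopifnot(inherits(wm, "weight_matrix"))
  N <- sum(wm$counts[, 1])
  f <- (wm$counts + 0.5) / (N + 2)
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", "",
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            wm$L, wm$n_sites),
    apply(f, 2L, function(col) paste(sprintf("%.6f", col), collapse = " ")))
  writeLines(lines, path)
  if (!is.null(wm$members) && nrow(wm$members)) {
    utils::write.table(wm$members, paste0(path, ".members.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a MEME minimal motif file back into a weight matrix
#'
#' Inverts [write_motif_meme()]: probabilities are converted back to
#' counts using the recorded `nsites` and the 0.5 pseudocount.
#'
#' @param path Path to a MEME minimal text file with one motif.
#' @return A [weight_matrix].
#' @export
read_motif_meme <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^letter-probability matrix:", lines)
  if (length(hdr) != 1L) stop("expected exactly one motif", call. = FALSE)
  w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr]))
  n <- as.integer(sub(".*nsites= *([0-9]+).*", "\\1", lines[hdr]))
  rows <- lines[(hdr + 1L):(hdr + w)]
  f <- t(vapply(rows, function(x) as.numeric(strsplit(trimws(x), " +")[[1]]),
                numeric(4)))
  counts <- round(t(f) * (n + 2) - 0.5)
  counts[counts < 0] <- 0
  weight_matrix(check_count_matrix(counts))
}

#' Write site hits as BED6 plus score/operon/sequence columns
#'
#' BED coordinates are 0-based half-open, matching the internal
#' convention directly.
#'
#' @param hits Hit table from [scan_sites()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sites_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$genome_id, chromStart = hits$start,
                    chromEnd = hits$end,
                    name = ifelse(is.na(hits$target_operon), ".",
                                  hits$target_operon),
                    score = sprintf("%.4f", hits$score),
                    strand = hits$strand, sequence = hits$sequence)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write regulons as JSON-lines and a flat TSV
#'
#' One JSON object per line per regulon (`tf_group`, `provenance`,
#' `threshold`, `consensus`, `members`); the TSV flattens members to one
#' row per (regulon, genome, operon) with site interval and score.
#'
#' @param regulons Named list of `regulon` objects.
#' @param jsonl_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, `NULL`.
#' @export
write_regulons <- function(regulons, jsonl_path = NULL, tsv_path = NULL) {
  nm <- names(regulons)
  if (is.null(nm)) nm <- vapply(regulons, function(r) as.character(r$tf_group), "")
  if (!is.null(jsonl_path)) {
    lines <- vapply(seq_along(regulons), function(i) {
      r <- regulons[[i]]
      jsonlite::toJSON(list(
        regulon = nm[i], tf_group = r$tf_group, provenance = r$provenance,
        threshold = r$threshold, consensus = r$motif$consensus,
        members = r$members), auto_unbox = TRUE, digits = NA)
    }, "")
    writeLines(lines, jsonl_path)
  }
  if (!is.null(tsv_path)) {
    flat <- do.call(rbind, lapply(seq_along(regulons), function(i) {
      m <- regulons[[i]]$members
      if (nrow(m) == 0L) return(NULL)
      cbind(data.frame(regulon = nm[i], stringsAsFactors = FALSE), m)
    }))
    utils::write.table(flat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}

#' Write a conservation matrix as CSV
#'
#' @param mat Matrix from [conservation_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_conservation_csv <- function(mat, path) {
  utils::write.csv(as.data.frame(mat), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
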