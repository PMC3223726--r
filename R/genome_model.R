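# Genome / gene / operon data model and I/O.
#
# Coordinate conventions: in memory everything is 0-based half-open
# [start, end); GFF3 on disk is 1-based inclusive; BED on disk is 0-based
# half-open. Conversion happens only at the I/O boundary.

#' Construct a genome object
#'
#' A genome bundles a single replicon sequence with its gene annotations.
#' Gene coordinates are 0-based half-open intervals on the forward strand;
#' genes are stored sorted by start coordinate.
#'
#' @param genome_id Single string identifying the replicon.
#' @param sequence DNA string (A/C/G/T/N) of the replicon.
#' @param genes `data.frame` with columns `locus_tag`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`) and optionally `protein` (amino-acid string),
#'   `product` and `tf_family` (transcription-factor family label, `NA` for
#'   non-TF genes).
#' @return An object of class `genome`.
#' @export
genome <- function(genome_id, sequence, genes = empty_gene_table()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("genome sequence may contain only A/C/G/T/N", call. = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  for (col in c("protein", "product", "tf_family"))
    if (is.null(genes[[col]])) genes[[col]] <- rep(NA_character_, nrow(genes))
  required <- c("locus_tag", "start", "end", "strand")
  if (!all(required %in% names(genes)))
    stop("gene table must have columns locus_tag, start, end, strand",
         call. = FALSE)
  if (nrow(genes)) {
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
    if (anyDuplicated(genes$locus_tag))
      stop("duplicate locus_tag in gene table", call. = FALSE)
    if (any(!genes$strand %in% c("+", "-")))
      stop("gene strand must be '+' or '-'", call. = FALSE)
    if (any(genes$start >= genes$end))
      stop("gene intervals must satisfy start < end", call. = FALSE)
    if (any(genes$start < 0L) || any(genes$end > nchar(sequence)))
      stop("gene coordinates outside sequence bounds", call. = FALSE)
    genes <- genes[order(genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(genome_id = genome_id, sequence = sequence, genes = genes),
            class = "genome")
}

#' @noRd
empty_gene_table <- function() {
  data.frame(locus_tag = character(0), start = integer(0), end = integer(0),
              strand = character(0), protein = character(0),
              product = character(0), tf_family = character(0),
              stringsAsFactors = FALSE)
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s bp, %d genes\n",
              x$genome_id, format(nchar(x$sequence), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Read a genome from FASTA + GFF3
#'
#' Reads one replicon from a nucleotide FASTA file and its gene annotations
#' from GFF3. Gene protein translations are taken from a `translation`
#' attribute on the feature, or from an optional protein FASTA keyed by
#' locus_tag. GFF3 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention.
#'
#' @param fasta_path Path to a single-record nucleotide FASTA.
#' @param gff3_path Path to a GFF3 file whose `gene` (or `CDS`) features
#'   carry a `locus_tag` attribute.
#' @param protein_fasta Optional path to a protein FASTA whose record names
#'   are locus_tags.
#' @param genome_id Replicon identifier; defaults to the FASTA record name.
#' @return A [genome] object.
#' @export
read_genome <- function(fasta_path, gff3_path, protein_fasta = NULL,
                        genome_id = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L)
    stop("expected exactly one FASTA record per replicon; got ",
         length(seqs), call. = FALSE)
  if (is.null(genome_id))
    genome_id <- sub("\\s.*$", "", names(seqs)[1])
  sequence <- as.character(seqs[[1]])

  gr <- rtracklayer::import(gff3_path, format = "gff3")
  if (length(gr)) {
    keep <- as.character(gr$type) %in% c("gene", "CDS")
    gr <- gr[keep]
  }
  if (length(gr)) {
    # prefer gene features; fall back to CDS when no gene rows exist
    types <- as.character(gr$type)
    if (any(types == "gene")) gr <- gr[types == "gene"]
    mc <- as.data.frame(S4Vectors::mcols(gr))
    get_attr <- function(name) {
      if (name %in% names(mc)) as.character(mc[[name]])
      else rep(NA_character_, length(gr))
    }
    locus <- get_attr("locus_tag")
    if (anyNA(locus)) stop("GFF3 feature without locus_tag", call. = FALSE)
    if (anyDuplicated(locus))
      stop("duplicate locus_tag in GFF3: ",
           paste(unique(locus[duplicated(locus)]), collapse = ", "),
           call. = FALSE)
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(!strand %in% c("+", "-")))
      stop("unknown strand symbol in GFF3 (must be + or -)", call. = FALSE)
    genes <- data.frame(
      locus_tag = locus,
      start = BiocGenerics::start(gr) - 1L,  # 1-based inclusive -> 0-based
      end = BiocGenerics::end(gr),           # inclusive end -> half-open end
      strand = strand,
      protein = get_attr("translation"),
      product = get_attr("product"),
      tf_family = get_attr("tf_family"),
      stringsAsFactors = FALSE
    )
    if (any(genes$end > nchar(sequence)) || any(genes$start < 0L))
      stop("GFF3 feature outside sequence bounds", call. = FALSE)
  } else {
    genes <- empty_gene_table()
  }

  if (!is.null(protein_fasta)) {
    prot <- Biostrings::readAAStringSet(protein_fasta)
    nm <- sub("\\s.*$", "", names(prot))
    hit <- match(genes$locus_tag, nm)
    genes$protein <- ifelse(is.na(hit), genes$protein,
                            as.character(prot)[hit])
  }
  genome(genome_id, sequence, genes)
}

#' Write a genome to FASTA + GFF3
#'
#' Inverse of [read_genome()]: emits the replicon FASTA and a GFF3 file of
#' `gene` features with `locus_tag`, `product`, `tf_family` and
#' `translation` attributes (the latter three only when present).
#'
#' @param genome A [genome] object.
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, the genome.
#' @export
write_genome <- function(genome, fasta_path, gff3_path) {
  dna <- Biostrings::DNAStringSet(genome$sequence)
  names(dna) <- genome$genome_id
  Biostrings::writeXStringSet(dna, fasta_path)

  lines <- "##gff-version 3"
  g <- genome$genes
  if (nrow(g)) {
    attr_str <- vapply(seq_len(nrow(g)), function(i) {
      parts <- c(sprintf("ID=%s", g$locus_tag[i]),
                 sprintf("locus_tag=%s", g$locus_tag[i]))
      if (!is.na(g$product[i]))
        parts <- c(parts, sprintf("product=%s", g$product[i]))
      if (!is.na(g$tf_family[i]))
        parts <- c(parts, sprintf("tf_family=%s", g$tf_family[i]))
      if (!is.na(g$protein[i]))
        parts <- c(parts, sprintf("translation=%s", g$protein[i]))
      paste(parts, collapse = ";")
    }, "")
    lines <- c(lines, sprintf("%s\tpanregulon\tgene\t%d\t%d\t.\t%s\t.\t%s",
                              genome$genome_id, g$start + 1L, g$end,
                              g$strand, attr_str))
  }
  writeLines(lines, gff3_path)
  invisible(genome)
}

#' Group genes into operons
#'
#' Consecutive co-directional genes whose intergenic gap is at most
#' `max_gap_bp` are merged into one operon; every gene belongs to exactly
#' one operon. The lead gene is the 5'-most member in transcription order
#' (smallest start on `+`, largest end on `-`).
#'
#' @param genome A [genome] object.
#' @param max_gap_bp Maximum intergenic gap (bp) merged within an operon.
#' @return `data.frame` with one row per operon: `operon_id`, `strand`,
#'   `start`, `end`, `lead_gene`, `n_genes` and a list-column `members` of
#'   locus_tags in transcription order.
#' @export
call_operons <- function(genome, max_gap_bp = 200) {
  if (!is.numeric(max_gap_bp) || length(max_gap_bp) != 1L || max_gap_bp < 0)
    stop("max_gap_bp must be a single non-negative number", call. = FALSE)
  g <- genome$genes
  n <- nrow(g)
  if (n == 0L) {
    return(data.frame(operon_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      lead_gene = character(0), n_genes = integer(0),
                      members = I(list())))
  }
  # genes are sorted by start; break whenever strand flips or gap too large
  brk <- logical(n)
  brk[1] <- TRUE
  if (n > 1L) {
    for (i in 2:n) {
      gap <- g$start[i] - g$end[i - 1L]
      brk[i] <- g$strand[i] != g$strand[i - 1L] || gap > max_gap_bp
    }
  }
  grp <- cumsum(brk)
  ids <- sprintf("%s_op%04d", genome$genome_id, seq_len(max(grp)))
  rows <- lapply(seq_len(max(grp)), function(k) {
    idx <- which(grp == k)
    strand <- g$strand[idx[1]]
    members <- g$locus_tag[idx]            # chromosomal order
    if (strand == "-") members <- rev(members)  # transcription order
    data.frame(operon_id = ids[k], strand = strand,
               start = min(g$start[idx]), end = max(g$end[idx]),
               lead_gene = members[1], n_genes = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- I(lapply(seq_len(max(grp)), function(k) {
    idx <- which(grp == k)
    m <- g$locus_tag[idx]
    if (g$strand[idx[1]] == "-") rev(m) else m
  }))
  rownames(out) <- NULL
  out
}

#' Extract the upstream region of an operon
#'
#' Returns the intergenic segment immediately 5' of the operon's lead gene,
#' truncated at `max_len` bp or at the boundary of the nearest annotated
#' gene, whichever is shorter. The sequence of `-` strand operons is
#' reverse-complemented so that position 0 is always the end of the region
#' farthest from the start codon. Divergently transcribed neighbors share
#' the same intergenic segment: the region is reported for both operons.
#'
#' @param genome A [genome] object.
#' @param operon One row of the table returned by [call_operons()] (or a
#'   list with fields `operon_id`, `strand`, `start`, `end`).
#' @param max_len Maximum region length in bp (default 350).
#' @return One-row `data.frame`: `operon_id`, `genome_id`, `strand`,
#'   `start`, `end` (genomic, 0-based half-open), `length`, `empty` flag
#'   and `sequence` (oriented; empty string when no intergenic space).
#' @export
extract_upstream <- function(genome, operon, max_len = 350) {
  check_scalar_int(max_len, "max_len", min = 1)
  g <- genome$genes
  seqlen <- nchar(genome$sequence)
  members <- if (is.list(operon$members)) operon$members[[1]] else operon$members
  other <- g[!g$locus_tag %in% members, , drop = FALSE]

  if (operon$strand == "+") {
    s <- operon$start
    if (nrow(other) && any(other$start < s & other$end > s)) {
      a <- b <- s  # a foreign gene spans the operon start: no room
    } else {
      bound <- if (nrow(other)) max(c(0L, other$end[other$end <= s])) else 0L
      a <- max(bound, s - max_len)
      b <- s
    }
    seq <- if (a < b) substr(genome$sequence, a + 1L, b) else ""
  } else {
    e <- operon$end
    if (nrow(other) && any(other$start < e & other$end > e)) {
      a <- b <- e
    } else {
      bound <- if (nrow(other)) min(c(seqlen, other$start[other$start >= e])) else seqlen
      a <- e
      b <- min(bound, e + max_len)
    }
    seq <- if (a < b) revcomp(substr(genome$sequence, a + 1L, b)) else ""
  }
  data.frame(operon_id = operon$operon_id, genome_id = genome$genome_id,
             strand = operon$strand, start = a, end = b,
             length = b - a, empty = a == b, sequence = seq,
             stringsAsFactors = FALSE)
}

#' Upstream regions for all operons of a genome
#'
#' @param genome A [genome] object.
#' @param operons Operon table from [call_operons()]; computed with the
#'   default gap when missing.
#' @param max_len Maximum region length in bp.
#' @param drop_empty Drop zero-length regions (a lead gene at a contig edge
#'   with no intergenic space); such regions are excluded from training
#'   sets.
#' @return `data.frame` of upstream regions, one row per operon.
#' @export
upstream_regions <- function(genome, operons = NULL, max_len = 350,
                             drop_empty = TRUE) {
  if (is.null(operons)) operons <- call_operons(genome)
  if (nrow(operons) == 0L) {
    return(data.frame(operon_id = character(0), genome_id = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      empty = logical(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(operons)), function(i)
    extract_upstream(genome, operons[i, ], max_len))
  out <- do.call(rbind, rows)
  if (drop_empty) out <- out[!out$empty, , drop = FALSE]
  rownames(out) <- NULL
  out
}
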