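# Palindrome-seeded iterative motif discovery and the position weight
# matrix (PWM) recognition model.
#
# The weight of base b at column j is the log2 odds of its pseudocounted
# frequency against a uniform 25% background:
#
#     f(b,j) = (count[b,j] + 0.5) / (N + 2)
#     w(b,j) = log2( f(b,j) / 0.25 )
#
# A site score is the sum of the weights of its bases, and the information
# content of a profile is sum_j sum_b f(b,j) * log2(f(b,j)/0.25) bits.

#' Positional nucleotide weights from a count matrix
#'
#' @param counts 4 x L non-negative integer matrix with rows A, C, G, T;
#'   all column sums must equal the number of aligned sites N.
#' @return 4 x L matrix of log2-odds weights against a uniform background,
#'   with pseudocount 0.5 per cell.
#' @export
positional_weights <- function(counts) {
  counts <- check_count_matrix(counts)
  N <- sum(counts[, 1])
  f <- (counts + 0.5) / (N + 2)
  w <- log2(f / 0.25)
  dimnames(w) <- list(DNA_BASES, NULL)
  w
}

#' @noRd
check_count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A,C,G,T)", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  cs <- colSums(counts)
  if (cs[1] <= 0 || any(abs(cs - cs[1]) > 1e-9))
    stop("count matrix column sums must all equal the same N > 0", call. = FALSE)
  rownames(counts) <- DNA_BASES
  counts
}

#' Information content of a count matrix, in bits
#'
#' Uses the same pseudocounted frequencies as [positional_weights()], so a
#' uniform column contributes exactly 0 bits and a fully conserved column
#' approaches 2 bits as N grows.
#'
#' @inheritParams positional_weights
#' @return Total information content in bits (non-negative).
#' @export
information_content <- function(counts) sum(column_ic(counts))

#' Per-column information content, in bits
#'
#' @inheritParams positional_weights
#' @return Numeric vector of length L.
#' @export
column_ic <- function(counts) {
  counts <- check_count_matrix(counts)
  N <- sum(counts[, 1])
  f <- (counts + 0.5) / (N + 2)
  colSums(f * log2(f / 0.25))
}

#' Build a weight-matrix motif model from aligned site counts
#'
#' @inheritParams positional_weights
#' @param members Optional `data.frame` of the member site windows
#'   (`region`, `offset`, `sequence`, `score`).
#' @param symmetric Whether the counts were palindromically symmetrized
#'   (see [symmetrize()]).
#' @param converged For discovered motifs, whether the iteration reached a
#'   fixed point.
#' @return Object of class `weight_matrix` with elements `L`, `counts`,
#'   `weights`, `n_sites`, `ic`, `consensus`, `members`, `symmetric`,
#'   `converged`.
#' @export
weight_matrix <- function(counts, members = NULL, symmetric = FALSE,
                          converged = TRUE) {
  counts <- check_count_matrix(counts)
  w <- positional_weights(counts)
  structure(list(
    L = ncol(counts),
    counts = counts,
    weights = w,
    n_sites = as.integer(round(sum(counts[, 1]))),
    ic = information_content(counts),
    consensus = consensus_of(w),
    members = members,
    symmetric = symmetric,
    converged = converged
  ), class = "weight_matrix")
}

# Consensus = per-column argmax of the weights; ties resolved
# alphabetically (A < C < G < T), which which.max provides for free given
# the fixed row order.
#' @noRd
consensus_of <- function(weights) {
  paste(DNA_BASES[apply(weights, 2L, which.max)], collapse = "")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> L=%d, N=%d sites, IC=%.2f bits, consensus %s%s\n",
              x$L, x$n_sites, x$ic, x$consensus,
              if (x$symmetric) " (symmetrized)" else ""))
  invisible(x)
}

#' Count matrix from aligned site sequences
#'
#' @param sites Character vector of equal-length DNA strings (no N).
#' @return 4 x L count matrix.
#' @export
site_counts <- function(sites) {
  stopifnot(length(sites) >= 1L)
  L <- nchar(sites[1])
  if (any(nchar(sites) != L)) stop("sites must all have equal length", call. = FALSE)
  mat <- t(vapply(sites, encode_dna, integer(L)))
  if (anyNA(mat)) stop("sites must contain only A/C/G/T", call. = FALSE)
  counts <- matrix(0L, 4L, L, dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(L)) counts[, j] <- tabulate(mat[, j], nbins = 4L)
  counts
}

#' Score a site window under a weight matrix
#'
#' The score is the sum over positions of the weight of the observed base.
#'
#' @param wm A [weight_matrix] (or bare 4 x L weights matrix).
#' @param window Character vector of DNA windows of length `L` (no N).
#' @return Numeric vector of scores.
#' @export
score_site <- function(wm, window) {
  w <- if (inherits(wm, "weight_matrix")) wm$weights else wm
  L <- ncol(w)
  if (any(nchar(window) != L))
    stop(sprintf("window length must equal motif length %d", L), call. = FALSE)
  mat <- t(vapply(window, encode_dna, integer(L)))
  if (anyNA(mat))
    stop("window must contain only A/C/G/T", call. = FALSE)
  unname(score_window_matrix(mat, w))
}

#' Find weak palindromes in a region
#'
#' A weak palindrome is a window whose number of mismatched complementary
#' pairs -- positions (i, L-1-i) where the base at i is not the complement
#' of the base at L-1-i -- is at most `max_mismatched_pairs`. Palindromic
#' windows are strand-symmetric, so only forward-strand enumeration is
#' needed. Windows containing N are skipped.
#'
#' @param sequence DNA string to search.
#' @param motif_len Even window length L.
#' @param max_mismatched_pairs Maximum mismatched complementary pairs m,
#'   with 0 <= m <= L/2. Default `ceiling(L/4)`.
#' @return `data.frame` with `offset` (0-based), `sequence` and
#'   `mismatched_pairs`, one row per qualifying window. Regions shorter
#'   than L yield zero rows.
#' @export
find_weak_palindromes <- function(sequence, motif_len,
                                  max_mismatched_pairs = ceiling(motif_len / 4)) {
  L <- check_scalar_int(motif_len, "motif_len", min = 2)
  if (L %% 2L != 0L) stop("motif_len must be even", call. = FALSE)
  m <- check_scalar_int(max_mismatched_pairs, "max_mismatched_pairs", min = 0)
  if (m > L / 2) stop("max_mismatched_pairs must be <= L/2", call. = FALSE)
  wins <- window_matrix(sequence, L)
  mm <- mismatched_pairs(wins$mat)
  keep <- mm <= m
  data.frame(offset = wins$offsets[keep],
             sequence = decode_windows(wins$mat[keep, , drop = FALSE]),
             mismatched_pairs = mm[keep],
             stringsAsFactors = FALSE)
}

#' Palindromic symmetrization of a motif model
#'
#' Adds to each count cell the count of the complementary base at the
#' mirrored column: `counts'[b, j] = counts[b, j] +
#' counts[comp(b), L-1-j]`. After symmetrization a window and its reverse
#' complement score identically, so single-strand scanning suffices.
#'
#' @param wm A [weight_matrix] with even L.
#' @return A symmetrized [weight_matrix] (member windows are preserved).
#' @export
symmetrize <- function(wm) {
  stopifnot(inherits(wm, "weight_matrix"))
  if (wm$L %% 2L != 0L) stop("symmetrize requires even motif length", call. = FALSE)
  counts2 <- wm$counts + wm$counts[4:1, wm$L:1]
  weight_matrix(counts2, members = wm$members, symmetric = TRUE,
                converged = wm$converged)
}

#' Iterative palindrome-seeded motif discovery
#'
#' Implements an iterative profile-refinement procedure over a set of
#' (upstream) regions assumed to share one binding-site box each:
#'
#' 1. Weak palindromes are enumerated in every region.
#' 2. Each weak palindrome in turn serves as a seed: the seed plus its
#'    nearest weak palindrome (Hamming distance) from every other region
#'    form an initial profile.
#' 3. The profile is refined by scoring all weak palindromes, keeping the
#'    best-scoring window per region, dropping the `max_ignored`
#'    lowest-scoring regions, and rebuilding the counts -- iterated until
#'    the selected window set repeats or `max_iter` is reached.
#' 4. Among all converged profiles the one with the largest information
#'    content is returned (ties broken by lexicographically smallest
#'    consensus).
#'
#' Seeds are explored in order of increasing mismatched-pair count
#' (strongest palindromes first), capped at `max_seeds` distinct seed
#' sequences; real binding boxes are near-palindromic and therefore sort to
#' the front of this order.
#'
#' @param regions Named character vector (or list) of region sequences;
#'   names identify the regions.
#' @param motif_len Even motif length L.
#' @param max_mismatched_pairs Weak-palindrome tolerance m (default
#'   `ceiling(L/4)`).
#' @param max_ignored Number of lowest-scoring regions to drop from the
#'   profile (sequences allowed to be ignored); default `floor(n/5)` for n
#'   usable regions.
#' @param max_iter Iteration cap per seed.
#' @param symmetrize Palindromically symmetrize each profile (default TRUE
#'   for palindromic motifs).
#' @param max_seeds Cap on the number of distinct seed windows explored.
#' @return A [weight_matrix] whose `members` table lists the final site
#'   window per retained region; `converged` is FALSE if the best profile
#'   hit `max_iter` without repeating a selection.
#' @export
discover_motif <- function(regions, motif_len,
                           max_mismatched_pairs = ceiling(motif_len / 4),
                           max_ignored = NULL, max_iter = 30,
                           symmetrize = TRUE, max_seeds = 100) {
  L <- check_scalar_int(motif_len, "motif_len", min = 2)
  regions <- unlist(regions)
  if (is.null(names(regions)) || anyDuplicated(names(regions)))
    stop("regions must be uniquely named", call. = FALSE)

  pal <- lapply(regions, find_weak_palindromes, motif_len = L,
                max_mismatched_pairs = max_mismatched_pairs)
  n_with <- sum(vapply(pal, nrow, 0L) > 0L)
  if (n_with < 3L)
    stop("motif discovery requires weak palindromes in at least 3 regions",
         call. = FALSE)
  tab <- do.call(rbind, lapply(names(pal), function(r) {
    p <- pal[[r]]
    if (nrow(p) == 0L) return(NULL)
    cbind(data.frame(region = r, stringsAsFactors = FALSE), p)
  }))
  enc <- t(vapply(tab$sequence, encode_dna, integer(L)))
  region_ids <- unique(tab$region)
  region_f <- factor(tab$region, levels = region_ids)
  n_regions <- length(region_ids)

  if (is.null(max_ignored)) max_ignored <- floor(n_regions / 5)
  d <- check_scalar_int(max_ignored, "max_ignored", min = 0)
  if (n_regions - d < 3L)
    stop("max_ignored leaves fewer than 3 regions", call. = FALSE)
  n_keep <- n_regions - d

  # seed order: strongest palindromes first, then input order; distinct
  # sequences only
  ord <- order(tab$mismatched_pairs, as.integer(region_f), tab$offset)
  seed_idx <- ord[!duplicated(tab$sequence[ord])]
  seed_idx <- seed_idx[seq_len(min(length(seed_idx), max_seeds))]

  build_profile <- function(rows) {
    counts <- matrix(0L, 4L, L, dimnames = list(DNA_BASES, NULL))
    sub <- enc[rows, , drop = FALSE]
    for (j in seq_len(L)) counts[, j] <- tabulate(sub[, j], nbins = 4L)
    if (symmetrize) counts <- counts + counts[4:1, L:1]
    counts
  }

  best <- NULL
  for (s in seed_idx) {
    # initial membership: seed plus nearest weak palindrome per region
    hd <- hamming_to(enc, enc[s, ])
    o <- order(hd, as.integer(region_f), tab$offset)
    init <- o[!duplicated(region_f[o])]
    counts <- build_profile(init)
    weights <- positional_weights(counts)

    history <- character(0)
    selection <- NULL
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      sc <- score_window_matrix(enc, weights)
      # best-scoring window per region (ties: earlier offset)
      o <- order(as.integer(region_f), -sc, tab$offset)
      per_region <- o[!duplicated(region_f[o])]
      # drop the d lowest-scoring regions (ties: later region dropped first)
      keep <- per_region[order(-sc[per_region],
                               as.integer(region_f[per_region]))][seq_len(n_keep)]
      selection <- sort(keep)
      key <- paste(selection, collapse = ",")
      if (key %in% history) { converged <- TRUE; break }
      history <- c(history, key)
      counts <- build_profile(selection)
      weights <- positional_weights(counts)
    }
    counts <- build_profile(selection)
    cand <- weight_matrix(
      counts,
      members = {
        sc <- score_window_matrix(enc, positional_weights(counts))
        data.frame(region = tab$region[selection],
                   offset = tab$offset[selection],
                   sequence = tab$sequence[selection],
                   score = sc[selection],
                   stringsAsFactors = FALSE)
      },
      symmetric = symmetrize, converged = converged)
    if (is.null(best) ||
        cand$ic > best$ic + 1e-12 ||
        (abs(cand$ic - best$ic) <= 1e-12 && cand$consensus < best$consensus)) {
      best <- cand
    }
  }
  best
}

#' Compare two motif models at conserved positions
#'
#' Conserved positions are the columns of `motif_a` whose per-column
#' information content is at least `ic_threshold_bits`. Consensus
#' mismatches are counted only at those positions, and the divergence class
#' follows the bins 0 (conserved), 1-2 (slight), 3-4 (moderate), >= 5
#' (different). Motifs of unequal length are aligned at the ungapped offset
#' of their consensi with the most matches; conserved positions falling
#' outside the overlap count as mismatches.
#'
#' @param motif_a,motif_b [weight_matrix] objects; `motif_a` defines the
#'   conserved positions.
#' @param ic_threshold_bits Per-column information content (bits) required
#'   to call a position conserved.
#' @return List with `conserved_positions` (1-based column indices in
#'   `motif_a`), `consensus_mismatches` and `divergence_class` (one of
#'   `"conserved"`, `"slight"`, `"moderate"`, `"different"`).
#' @export
compare_motifs <- function(motif_a, motif_b, ic_threshold_bits = 1.0) {
  stopifnot(inherits(motif_a, "weight_matrix"),
            inherits(motif_b, "weight_matrix"))
  ca <- motif_a$consensus
  cb <- motif_b$consensus
  icol <- column_ic(motif_a$counts)
  conserved <- which(icol >= ic_threshold_bits)

  # equal lengths compare column-to-column; otherwise align the consensi
  # at the ungapped offset with the most matches (shift of b relative to a)
  La <- motif_a$L; Lb <- motif_b$L
  best_shift <- 0L; best_match <- -1L
  shifts <- if (La == Lb) 0L else (-Lb + 1L):(La - 1L)
  for (shift in shifts) {
    ja <- max(1L, 1L + shift):min(La, Lb + shift)
    if (length(ja) == 0L) next
    jb <- ja - shift
    nm <- sum(substring(ca, ja, ja) == substring(cb, jb, jb))
    if (nm > best_match) { best_match <- nm; best_shift <- shift }
  }
  mism <- 0L
  for (j in conserved) {
    jb <- j - best_shift
    if (jb < 1L || jb > Lb || substring(ca, j, j) != substring(cb, jb, jb))
      mism <- mism + 1L
  }
  class <- if (mism == 0L) "conserved"
           else if (mism <= 2L) "slight"
           else if (mism <= 4L) "moderate"
           else "different"
  list(conserved_positions = conserved,
       consensus_mismatches = mism,
       divergence_class = class)
}
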