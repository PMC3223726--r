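# Independent brute-force oracles and small fixtures used across tests.
# Everything here is deliberately naive and separate from the package's
# own code paths.

# --- Smith-Waterman dynamic-programming oracle (plain R, full matrices) ---
# Same scoring convention as the package states: affine gaps, a gap of
# length k costs gap_open + k * gap_ext; local alignment clamped at 0.
oracle_sw_score <- function(a, b, submat, gap_open = 11, gap_ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  NEG <- -1e30
  H <- matrix(0, na + 1, nb + 1)
  E <- matrix(NEG, na + 1, nb + 1)
  F <- matrix(NEG, na + 1, nb + 1)
  best <- 0
  for (i in 2:(na + 1)) {
    for (j in 2:(nb + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_ext, H[i, j - 1] - gap_open - gap_ext)
      F[i, j] <- max(F[i - 1, j] - gap_ext, H[i - 1, j] - gap_open - gap_ext)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + submat[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

random_protein <- function(n) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# --- exhaustive sliding-window PWM scan oracle (both strands) ---
oracle_scan <- function(sequence, weights, threshold) {
  L <- ncol(weights)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- nchar(sequence)
  hits <- list()
  if (n < L) return(data.frame(start = integer(0), strand = character(0),
                               score = numeric(0)))
  for (s in 0:(n - L)) {
    win <- substr(sequence, s + 1, s + L)
    ch <- strsplit(win, "")[[1]]
    if (any(!ch %in% bases)) next
    rcch <- rev(unname(comp[ch]))
    fwd <- 0; rev_sc <- 0
    for (j in seq_len(L)) {
      fwd <- fwd + weights[ch[j], j]
      rev_sc <- rev_sc + weights[rcch[j], j]
    }
    if (fwd >= threshold)
      hits[[length(hits) + 1]] <- data.frame(start = s, strand = "+",
                                             score = fwd)
    if (rev_sc >= threshold && abs(rev_sc - fwd) >= 1e-9)
      hits[[length(hits) + 1]] <- data.frame(start = s, strand = "-",
                                             score = rev_sc)
  }
  if (!length(hits)) return(data.frame(start = integer(0),
                                       strand = character(0),
                                       score = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), ]
}

# --- exhaustive weak-palindrome enumeration oracle ---
oracle_weak_palindromes <- function(sequence, L, m) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- nchar(sequence)
  res <- integer(0)
  if (n < L) return(res)
  for (s in 0:(n - L)) {
    ch <- strsplit(substr(sequence, s + 1, s + L), "")[[1]]
    if (any(!ch %in% names(comp))) next
    mm <- sum(vapply(seq_len(L / 2), function(i)
      ch[i] != comp[ch[L + 1 - i]], TRUE))
    if (mm <= m) res <- c(res, s)
  }
  res
}

# --- small fixtures ---

# two-gene toy genome: gene A (+) at 100..400, gene B (-) at 700..1000
toy_genome <- function(seed = 1) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE),
               collapse = "")
  genome("toy", seq, data.frame(
    locus_tag = c("tg_0005", "tg_0010"),
    start = c(100L, 700L), end = c(400L, 1000L),
    strand = c("+", "-"),
    protein = c("MKTAYIAKQR", "MLSERVWQHD"),
    product = c("alpha protein", "beta protein"),
    tf_family = c(NA, "LysR"), stringsAsFactors = FALSE))
}

# compact simulator configuration for fast unit tests
small_config <- function(seed = 1, ...) {
  sim_config(n_genomes = 6, n_core_families = 8, n_variable_families = 2,
             n_specific_per_genome = 1, n_target_families = 5,
             decoy_count = 2, motif_len = 10,
             motif_consensus = "TTGACGTCAA", seed = seed, ...)
}

# implanted pangenome plus its ortholog groups taken from ground truth
# (used where the unit under test is downstream of orthology)
truth_groups <- function(truth) {
  p <- truth$partition
  data.frame(group_id = p$family_id, genome_id = p$genome_id,
             locus_tag = p$locus_tag,
             conservation_class = truth$families$class[
               match(p$family_id, truth$families$family_id)],
             stringsAsFactors = FALSE)
}

# training regions (upstreams of true target operons) from a pangenome
truth_training_regions <- function(pan, decoy = FALSE) {
  regs <- character(0)
  sites <- pan$truth$sites[pan$truth$sites$decoy == decoy, ]
  for (gid in unique(sites$genome_id)) {
    g <- pan$genomes[[gid]]
    ur <- upstream_regions(g, call_operons(g))
    sel <- ur[ur$operon_id %in% sites$operon_id[sites$genome_id == gid], ]
    regs[paste(gid, sel$operon_id, sep = "|")] <- sel$sequence
  }
  regs
}

# member-level precision/recall of a regulon against simulator truth
truth_precision_recall <- function(regulon, truth) {
  truth_m <- unique(paste(truth$sites$genome_id, truth$sites$operon_id,
                          sep = "|")[!truth$sites$decoy])
  got <- paste(regulon$members$genome_id, regulon$members$operon_id,
               sep = "|")
  list(precision = if (length(got)) mean(got %in% truth_m) else NA_real_,
       recall = mean(truth_m %in% got))
}
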