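# Weak palindromes, PWM weights/scores/information content, the iterative
# discovery procedure, symmetrization and motif comparison.

test_that("mismatched complementary pairs are counted correctly", {
  # AAGTACTT is a perfect palindrome
  p0 <- find_weak_palindromes("AAGTACTT", 8, 0)
  expect_equal(nrow(p0), 1L)
  expect_equal(p0$mismatched_pairs, 0L)
  # AAGTACTA breaks pair (0,7): A vs complement(A)=T
  p1 <- find_weak_palindromes("AAGTACTA", 8, 1)
  expect_equal(p1$mismatched_pairs, 1L)
  expect_equal(nrow(find_weak_palindromes("AAGTACTA", 8, 0)), 0L)
})

test_that("weak-palindrome windows match exhaustive enumeration", {
  set.seed(21)
  s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  for (m in 0:3) {
    got <- find_weak_palindromes(s, 8, m)
    expect_equal(got$offset, oracle_weak_palindromes(s, 8, m))
  }
  # windows containing N are skipped
  sN <- paste0(substr(s, 1, 20), "N", substr(s, 22, 60))
  got <- find_weak_palindromes(sN, 8, 4)
  expect_false(any(got$offset %in% 13:20))
  # region shorter than L is empty, not an error
  expect_equal(nrow(find_weak_palindromes("ACGT", 8, 2)), 0L)
})

test_that("positional weights follow the pseudocounted log-odds formula", {
  # uniform column -> weight 0 everywhere
  u <- matrix(1L, 4, 3)
  expect_equal(positional_weights(u), matrix(0, 4, 3, dimnames = list(c("A","C","G","T"), NULL)))
  # N=2, column A:2 -> f_A = 2.5/4, weight log2(2.5)
  c1 <- matrix(c(2L, 0L, 0L, 0L), 4, 1)
  w1 <- positional_weights(c1)
  expect_equal(unname(w1["A", 1]), log2(2.5), tolerance = 1e-12)
  # N=4, column A:2,C:1,G:1,T:0 -> weight_T = log2((0.5/6)/0.25)
  c2 <- matrix(c(2L, 1L, 1L, 0L), 4, 1)
  expect_equal(unname(positional_weights(c2)["T", 1]),
               log2((0.5 / 6) / 0.25), tolerance = 1e-12)
  expect_error(positional_weights(matrix(c(1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L),
                                         4, 2)),
               "column sums")
})

test_that("site scores are additive positional lookups", {
  w <- matrix(-1, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  w["A", 1] <- 1.0
  w[, 2] <- -0.5
  w["T", 2] <- 0.5
  wm <- list(weights = w)
  class(wm) <- "weight_matrix"
  expect_equal(score_site(wm, "AT"), 1.5)
  expect_equal(score_site(wm, "AA"), 0.5)
  expect_error(score_site(wm, "A"), "length")
  expect_error(score_site(wm, "AN"), "A/C/G/T")
})

test_that("the consensus maximizes the score over all windows", {
  set.seed(5)
  sites <- replicate(6, paste(sample(c("A", "C", "G", "T"), 4, TRUE),
                              collapse = ""))
  wm <- weight_matrix(site_counts(sites))
  all4 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1,
                paste, collapse = "")
  expect_equal(max(score_site(wm, all4)), score_site(wm, wm$consensus))
  # scores equal independent per-position recomputation
  idx <- sample(all4, 50, replace = TRUE)
  manual <- vapply(idx, function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(vapply(1:4, function(j) wm$weights[ch[j], j], 0))
  }, 0)
  expect_equal(score_site(wm, idx), unname(manual))
})

test_that("information content matches closed forms and limits", {
  expect_equal(information_content(matrix(2L, 4, 5)), 0)
  # N=4, single all-A column
  c1 <- matrix(c(4L, 0L, 0L, 0L), 4, 1)
  expect_equal(information_content(c1),
               0.75 * log2(3) + 3 * (1 / 12) * log2(1 / 3),
               tolerance = 1e-12)
  # conserved column tends to 2 bits as N grows
  big <- matrix(c(1e6, 0, 0, 0), 4, 1)
  expect_equal(information_content(big), 2, tolerance = 1e-3)
  # IC is never negative (random count matrices)
  set.seed(8)
  for (i in 1:20) {
    sites <- replicate(5, paste(sample(c("A", "C", "G", "T"), 6, TRUE),
                                collapse = ""))
    expect_gte(information_content(site_counts(sites)), 0)
  }
})

test_that("symmetrization mirrors counts and enforces strand symmetry", {
  # asymmetric toy: A:4 at position 1, T:0 -> mirrored to A:4/T:4 ends
  sites <- c("AACC", "AACC", "AAGC", "AATC")
  wm <- weight_matrix(site_counts(sites))
  sym <- symmetrize(wm)
  expect_equal(sym$counts["A", 1], wm$counts["A", 1] + wm$counts["T", 4])
  expect_equal(unname(sym$counts["T", 4]), unname(sym$counts["A", 1]))
  # already-symmetric counts double but keep the consensus
  pal_sites <- c("TTGACGTCAA", "TTGACGTCAA", "TTGATATCAA")
  wm2 <- weight_matrix(site_counts(pal_sites))
  sym2 <- symmetrize(wm2)
  expect_equal(sym2$counts, wm2$counts * 2L, ignore_attr = TRUE)
  expect_identical(sym2$consensus, wm2$consensus)
  # property: score(w) == score(revcomp(w)) after symmetrization
  set.seed(13)
  wins <- replicate(40, paste(sample(c("A", "C", "G", "T"), 4, TRUE),
                              collapse = ""))
  expect_equal(score_site(sym, wins), score_site(sym, revcomp(wins)),
               tolerance = 1e-9)
  expect_error(symmetrize(weight_matrix(site_counts(c("ACT", "ACT", "GGT")))),
               "even")
})

# plant one copy of a palindromic consensus into each of n random regions
planted_regions <- function(n, consensus, region_len = 80, seed = 1,
                            skip = integer(0)) {
  set.seed(seed)
  L <- nchar(consensus)
  regs <- character(n)
  offs <- integer(n)
  for (i in seq_len(n)) {
    s <- paste(sample(c("A", "C", "G", "T"), region_len, TRUE), collapse = "")
    if (!i %in% skip) {
      o <- sample(0:(region_len - L), 1)
      substr(s, o + 1, o + L) <- consensus
      offs[i] <- o
    }
    regs[i] <- s
  }
  names(regs) <- sprintf("r%02d", seq_len(n))
  attr(regs, "offsets") <- offs
  regs
}

test_that("discovery recovers an exact planted palindrome and its sites", {
  cons <- "TTAGCGCTAA"
  regs <- planted_regions(10, cons, seed = 31)
  wm <- discover_motif(regs, 10, max_ignored = 0)
  expect_identical(wm$consensus, cons)
  expect_true(wm$converged)
  expect_equal(nrow(wm$members), 10L)
  expect_identical(sort(wm$members$region), sort(names(regs)))
  expect_equal(wm$members$offset[order(wm$members$region)],
               attr(regs, "offsets"))
})

test_that("a planted motif carries more information than pure background", {
  cons <- "TTAGCGCTAA"
  ic_sig <- ic_bg <- numeric(3)
  for (k in 1:3) {
    regs <- planted_regions(10, cons, seed = 40 + k)
    ic_sig[k] <- discover_motif(regs, 10, max_ignored = 0)$ic
    set.seed(140 + k)
    bg <- vapply(1:10, function(i)
      paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = ""), "")
    names(bg) <- sprintf("b%02d", 1:10)
    ic_bg[k] <- discover_motif(bg, 10, max_ignored = 0)$ic
  }
  expect_true(all(ic_sig > ic_bg))
})

test_that("discovery drops exactly the signal-free regions", {
  cons <- "TTAGCGCTAA"
  regs <- planted_regions(12, cons, seed = 77, skip = c(4, 9))
  wm <- discover_motif(regs, 10, max_ignored = 2)
  expect_equal(nrow(wm$members), 10L)
  expect_setequal(setdiff(names(regs), wm$members$region),
                  c("r04", "r09"))
  expect_identical(wm$consensus, cons)
})

test_that("discovery refuses degenerate inputs", {
  expect_error(discover_motif(c(a = "ACGT", b = "ACGT"), 10),
               "at least 3 regions")
  regs <- planted_regions(4, "TTAGCGCTAA", seed = 2)
  expect_error(discover_motif(regs, 10, max_ignored = 3),
               "fewer than 3")
})

test_that("motif comparison classifies divergence at conserved positions", {
  sites_a <- rep("TTGACGTCAA", 8)
  wm_a <- weight_matrix(site_counts(sites_a))
  expect_identical(compare_motifs(wm_a, wm_a)$divergence_class, "conserved")
  expect_equal(compare_motifs(wm_a, wm_a)$consensus_mismatches, 0L)
  # three mismatches at fully conserved columns -> moderate
  wm_b <- weight_matrix(site_counts(rep("TACTCGTCAA", 8)))
  cmp <- compare_motifs(wm_a, wm_b)
  expect_equal(cmp$consensus_mismatches, 3L)
  expect_identical(cmp$divergence_class, "moderate")
  # differences confined to low-IC columns are invisible
  mixed <- c("ATGACGTCAA", "CTGACGTCAA", "GTGACGTCAA", "TTGACGTCAA")
  wm_c <- weight_matrix(site_counts(mixed))       # column 1 uninformative
  wm_d <- weight_matrix(site_counts(rep("CTGACGTCAA", 4)))
  cmp2 <- compare_motifs(wm_c, wm_d)
  expect_equal(cmp2$consensus_mismatches, 0L)
  expect_false(1L %in% cmp2$conserved_positions)
  # 1-2 mismatches -> slight; >=5 -> different
  wm_e <- weight_matrix(site_counts(rep("TAGACGTCAA", 8)))
  expect_identical(compare_motifs(wm_a, wm_e)$divergence_class, "slight")
  wm_f <- weight_matrix(site_counts(rep("CCTGGATGGC", 8)))
  expect_identical(compare_motifs(wm_a, wm_f)$divergence_class, "different")
})
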