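# Consistency filter, regulon propagation, ab initio inference, TF
# attribution and conservation matrices.

# hand-built candidate table + ortholog groups for filter unit tests:
# group X spans G1..G4 (lead genes xg1..xg4), group Y spans G1..G3
fixture_groups <- function() {
  data.frame(
    group_id = c(rep("X", 4), rep("Y", 3)),
    genome_id = c("G1", "G2", "G3", "G4", "G1", "G2", "G3"),
    locus_tag = c("x1", "x2", "x3", "x4", "y1", "y2", "y3"),
    conservation_class = c(rep("core", 4), rep("variable", 3)),
    stringsAsFactors = FALSE)
}

cand_row <- function(genome, operon, lead) {
  data.frame(genome_id = genome, operon_id = operon, lead_gene = lead,
             start = 0L, end = 10L, strand = "+", sequence = "A",
             score = 5, stringsAsFactors = FALSE)
}

test_that("candidates conserved in two other genomes are retained", {
  cands <- rbind(cand_row("G1", "op1", "x1"),
                 cand_row("G2", "op2", "x2"),
                 cand_row("G3", "op3", "x3"),
                 cand_row("G1", "opY", "y1"))
  kept <- consistency_filter(cands, fixture_groups())
  # x candidates have >= 2 hit-bearing ortholog genomes; y1 has none
  expect_setequal(kept$lead_gene, c("x1", "x2", "x3"))
  expect_identical(unique(kept$evidence), "site_conserved")
  # one supporting genome is not enough
  kept2 <- consistency_filter(rbind(cand_row("G1", "op1", "x1"),
                                    cand_row("G2", "op2", "x2")),
                              fixture_groups())
  expect_equal(nrow(kept2), 0L)
  # ... unless the candidate is functionally linked
  kept3 <- consistency_filter(rbind(cand_row("G1", "op1", "x1"),
                                    cand_row("G2", "op2", "x2")),
                              fixture_groups(),
                              functional_links = "G1|op1")
  expect_equal(nrow(kept3), 1L)
  expect_identical(kept3$evidence, "functionally_linked")
})

test_that("the filter is a monotone subset operator", {
  cands <- rbind(cand_row("G1", "op1", "x1"), cand_row("G2", "op2", "x2"),
                 cand_row("G3", "op3", "x3"), cand_row("G4", "op4", "x4"),
                 cand_row("G1", "opY", "y1"), cand_row("G2", "opY2", "y2"))
  prev <- cands
  for (k in 0:4) {
    kept <- consistency_filter(cands, fixture_groups(),
                               min_other_genomes = k)
    # subset of the input and of any laxer filtering
    expect_true(all(paste(kept$genome_id, kept$operon_id) %in%
                      paste(cands$genome_id, cands$operon_id)))
    expect_true(all(paste(kept$genome_id, kept$operon_id) %in%
                      paste(prev$genome_id, prev$operon_id)))
    prev <- kept
  }
  # unknown lead gene is a consistency error
  expect_error(consistency_filter(cand_row("G1", "op", "zz"),
                                  fixture_groups()),
               "not found in any ortholog group")
})

test_that("decoys die by consistency while conserved members survive", {
  cfg <- small_config(seed = 61)
  pan <- implant_regulon(generate_pangenome(cfg), cfg)
  groups <- truth_groups(pan$truth)
  ctx_ops <- lapply(pan$genomes, call_operons)
  regs <- do.call(rbind, lapply(pan$genomes, function(g)
    upstream_regions(g, ctx_ops[[g$genome_id]])))
  wm <- discover_motif(truth_training_regions(pan), cfg$motif_len,
                       max_ignored = 0)
  hits <- scan_sites(wm, training_threshold(wm), regions = regs)
  cands <- panregulon:::hits_to_candidates(hits, ctx_ops)
  kept <- consistency_filter(cands, groups)
  kept_key <- paste(kept$genome_id, kept$operon_id)
  s <- pan$truth$sites
  decoy_key <- paste(s$genome_id, s$operon_id)[s$decoy]
  true_key <- paste(s$genome_id, s$operon_id)[!s$decoy]
  expect_equal(sum(decoy_key %in% kept_key), 0L)
  expect_equal(mean(true_key %in% kept_key), 1.0)
})

test_that("propagation recovers the implanted regulon exactly", {
  cfg <- small_config(seed = 67)
  pan <- implant_regulon(generate_pangenome(cfg), cfg)
  groups <- truth_groups(pan$truth)
  truth <- pan$truth
  model_loci <- function(fams)
    truth$partition$locus_tag[truth$partition$family_id %in% fams &
                                truth$partition$genome_id == "G01"]
  seed <- list(model_genome = "G01",
               tf_locus = model_loci(cfg$tf_family_id),
               targets = model_loci(cfg$target_family_ids),
               sites = truth$sites$sequence[truth$sites$genome_id == "G01" &
                                              !truth$sites$decoy])
  reg <- propagate_regulon(seed, pan$genomes, groups,
                           params = list(motif_len = cfg$motif_len))
  expect_s3_class(reg, "regulon")
  expect_false(reg$skipped)
  expect_identical(reg$provenance, "propagated")
  pr <- truth_precision_recall(reg, truth)
  expect_equal(pr$precision, 1.0)
  expect_equal(pr$recall, 1.0)
  # every member is backed by a site at or above the regulon threshold
  expect_true(all(reg$members$score >= reg$threshold))
})

test_that("an unmutated implant propagates with a conserved motif", {
  cfg <- small_config(seed = 71, site_mutations_max = 0)
  pan <- implant_regulon(generate_pangenome(cfg), cfg)
  groups <- truth_groups(pan$truth)
  truth <- pan$truth
  model_loci <- function(fams)
    truth$partition$locus_tag[truth$partition$family_id %in% fams &
                                truth$partition$genome_id == "G01"]
  seed <- list(model_genome = "G01",
               tf_locus = model_loci(cfg$tf_family_id),
               targets = model_loci(cfg$target_family_ids),
               sites = truth$sites$sequence[truth$sites$genome_id == "G01" &
                                              !truth$sites$decoy])
  reg <- propagate_regulon(seed, pan$genomes, groups,
                           params = list(motif_len = cfg$motif_len))
  expect_identical(reg$comparison$divergence_class, "conserved")
  expect_equal(reg$comparison$consensus_mismatches, 0L)
  expect_identical(reg$motif$consensus, cfg$motif_consensus)
})

test_that("a regulator without orthologs yields a skip report", {
  cfg <- small_config(seed = 73)
  pan <- implant_regulon(generate_pangenome(cfg), cfg)
  groups <- truth_groups(pan$truth)
  seed <- list(model_genome = "G01", tf_locus = "nonexistent_locus",
               targets = "whatever")
  res <- propagate_regulon(seed, pan$genomes, groups,
                           params = list(motif_len = cfg$motif_len))
  expect_true(res$skipped)
  expect_match(res$reason, "not found")
})

test_that("ab initio inference recovers members from a pathway training set", {
  cfg <- small_config(seed = 79)
  pan <- implant_regulon(generate_pangenome(cfg), cfg)
  groups <- truth_groups(pan$truth)
  training <- truth_training_regions(pan)
  reg <- infer_novel_regulon(training, pan$genomes, groups,
                             params = list(motif_len = cfg$motif_len,
                                           max_ignored = 0))
  expect_identical(reg$provenance, "ab_initio")
  expect_true(is.na(reg$tf_group))
  expect_false(reg$low_ic)
  pr <- truth_precision_recall(reg, pan$truth)
  expect_equal(pr$precision, 1.0)
  expect_equal(pr$recall, 1.0)
  # self-detection: members never fewer than hit-bearing training operons
  expect_gte(nrow(reg$members), length(training))
})

test_that("an unrelated training set is flagged as low-information", {
  cfg <- small_config(seed = 83)
  pan <- generate_pangenome(cfg)  # no implant: upstreams are background
  groups <- truth_groups(pan$truth)
  g <- pan$genomes[[1]]
  regs <- upstream_regions(g, call_operons(g))
  training <- setNames(regs$sequence, paste("G01", regs$operon_id, sep = "|"))
  training <- training[1:8]
  expect_warning(
    reg <- infer_novel_regulon(training, pan$genomes[1:3], groups,
                               params = list(motif_len = cfg$motif_len,
                                             max_ignored = 0)),
    "low information")
  expect_true(reg$low_ic)
})

test_that("TF attribution scores positional, autoregulatory and pattern evidence", {
  cfg <- small_config(seed = 89, autoregulate = TRUE)
  pan <- implant_regulon(generate_pangenome(cfg), cfg)
  groups <- truth_groups(pan$truth)
  training <- truth_training_regions(pan)
  reg <- infer_novel_regulon(training, pan$genomes, groups,
                             params = list(motif_len = cfg$motif_len,
                                           max_ignored = 0))
  att <- attribute_tf(reg, pan$genomes, groups)
  expect_equal(nrow(att), 1L)
  expect_identical(att$group_id, cfg$tf_family_id)
  expect_identical(att$tf_family, cfg$tf_label)
  expect_true(att$autoregulated)
  # without any labelled TF genes the attribution is empty
  stripped <- lapply(pan$genomes, function(g) {
    g$genes$tf_family <- NA_character_
    g
  })
  expect_equal(nrow(attribute_tf(reg, stripped, groups)), 0L)
})

test_that("tied TF candidates are reported together, not broken", {
  # two regulons' worth of synthetic evidence: two TF groups, each with
  # exactly one evidence type
  members <- data.frame(genome_id = "G1", operon_id = "op1",
                        lead_gene = "t1", start = 0L, end = 10L,
                        strand = "+", sequence = "A", score = 5,
                        evidence = "site_conserved")
  reg <- structure(list(tf_group = NA, members = members), class = "regulon")
  seqs <- strrep("A", 2200)
  g1 <- genome("G1", seqs, data.frame(
    locus_tag = c("t1", "tfA", "far"), start = c(100L, 300L, 2000L),
    end = c(200L, 400L, 2100L), strand = "+",
    tf_family = c(NA, "LysR", NA), stringsAsFactors = FALSE))
  g2 <- genome("G2", seqs, data.frame(
    locus_tag = c("tfB",  "t2"), start = c(100L, 2000L),
    end = c(200L, 2100L), strand = "+",
    tf_family = c("AraC", NA), stringsAsFactors = FALSE))
  groups <- data.frame(
    group_id = c("T", "A", "B", "FAR", "T2"),
    genome_id = c("G1", "G1", "G2", "G1", "G2"),
    locus_tag = c("t1", "tfA", "tfB", "far", "t2"),
    conservation_class = "strain_specific")
  # tfA: positional (adjacent to member operon, genome G1)
  # tfB: pattern match (present exactly in {G1}? no -> in G2) ...
  att <- attribute_tf(reg, list(G1 = g1, G2 = g2), groups)
  expect_identical(att$group_id, "A")  # only positional evidence exists
  # now give B a pattern match by restricting it to G1 (the 'far' locus
  # moves wholesale from group FAR into group B)
  groups <- groups[groups$group_id != "FAR", ]
  groups$genome_id[groups$group_id == "B"] <- "G1"
  groups$locus_tag[groups$group_id == "B"] <- "far"
  g1b <- g1
  g1b$genes$tf_family[g1b$genes$locus_tag == "far"] <- "AraC"
  att2 <- attribute_tf(reg, list(G1 = g1b, G2 = g2), groups)
  expect_equal(nrow(att2), 2L)
  expect_setequal(att2$group_id, c("A", "B"))
  expect_equal(unique(att2$n_evidence), 1L)
})

test_that("conservation matrices mirror member presence", {
  mk_reg <- function(genomes) {
    structure(list(tf_group = "R",
                   members = data.frame(genome_id = genomes,
                                        operon_id = paste0("op", genomes))),
              class = "regulon")
  }
  gids <- sprintf("G%02d", 1:16)
  m <- conservation_matrix(list(full = mk_reg(gids),
                                partial = mk_reg(gids[1:15])), gids)
  expect_equal(unname(attr(m, "row_marginals")), c(16L, 15L))
  expect_true(all(m["full", ] == "+"))
  expect_identical(m["partial", "G16"], "-")
  m0 <- conservation_matrix(list(), gids)
  expect_equal(nrow(m0), 0L)
})
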