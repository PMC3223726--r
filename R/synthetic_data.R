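# Seeded pangenome simulator with full ground truth: orthologous gene
# families (core / variable / strain-specific), implanted palindromic
# binding sites with per-site mutational noise, single-genome decoy sites,
# and a block-correlated expression matrix.
#
# The defaults emulate the study design the package is built around: 16
# genomes, an 18-bp palindromic consensus implanted upstream of 12 core
# target families with at most 2 point mutations per site, and decoy sites
# (same consensus) confined to a single genome so that only the
# cross-genome consistency filter -- never the score -- can remove them.

#' Simulator configuration
#'
#' Validates and assembles the configuration for [generate_pangenome()],
#' [implant_regulon()] and [generate_expression()]. All randomness is a
#' pure function of `seed`.
#'
#' Family layout: families `F001 .. F<n_core>` are core (present in every
#' genome); the first `n_target_families` of them are the regulon targets,
#' the next one is the regulator (labelled with `tf_family`), and the
#' remaining core families host the decoy sites. Variable families follow,
#' then one strain-specific family per genome.
#'
#' @param n_genomes Number of genomes (>= 3; the consistency filter needs
#'   at least two "other" genomes).
#' @param n_core_families,n_variable_families,n_specific_per_genome Family
#'   counts per conservation class.
#' @param gene_len_bp,intergenic_len_bp Length distributions `c(mean, sd)`
#'   in bp.
#' @param protein_len_aa Protein length distribution `c(mean, sd)` in
#'   residues (ortholog family members share one length).
#' @param motif_len Even motif length; must equal
#'   `nchar(motif_consensus)`.
#' @param motif_consensus Palindromic DNA consensus implanted at target
#'   sites.
#' @param site_mutations_max Maximum seeded point mutations per implanted
#'   site.
#' @param n_target_families Number of core families receiving a site.
#' @param autoregulate Also implant a site upstream of the regulator's own
#'   gene.
#' @param decoy_count Number of decoy sites (each upstream of a distinct
#'   non-target core family).
#' @param decoy_genome Index of the single genome receiving the decoys.
#' @param protein_divergence Per-residue substitution rate applied
#'   independently to each ortholog relative to the family ancestor.
#' @param tf_label,decoy_tf_label Transcription-factor family labels given
#'   to the regulator family and to one decoy family (exercises TF
#'   attribution against a competitor).
#' @param strand_policy `"plus"` places every gene on the forward strand
#'   so each promoter is private to its operon; `"random"` draws strands
#'   independently (divergent promoters then share intergenic segments).
#' @param expr_n_conditions,expr_corr,expr_noise_sd Expression design: two
#'   blocks of target families with expected within-block Pearson
#'   correlation `expr_corr`; `expr_noise_sd` overrides the noise standard
#'   deviation implied by `expr_corr` when non-NULL.
#' @param seed Integer seed controlling all simulator randomness.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genomes = 16,
                       n_core_families = 18,
                       n_variable_families = 4,
                       n_specific_per_genome = 1,
                       gene_len_bp = c(300, 30),
                       intergenic_len_bp = c(280, 25),
                       protein_len_aa = c(60, 6),
                       motif_len = 18,
                       motif_consensus = "ATTGACAATATTGTCAAT",
                       site_mutations_max = 2,
                       n_target_families = 12,
                       autoregulate = FALSE,
                       decoy_count = 5,
                       decoy_genome = 2,
                       protein_divergence = 0.05,
                       tf_label = "LacI",
                       decoy_tf_label = "TetR",
                       strand_policy = c("plus", "random"),
                       expr_n_conditions = 50,
                       expr_corr = 0.8,
                       expr_noise_sd = NULL,
                       seed = 1) {
  strand_policy <- match.arg(strand_policy)
  check_scalar_int(n_genomes, "n_genomes", min = 3)
  check_scalar_int(motif_len, "motif_len", min = 4)
  if (motif_len %% 2L != 0L) stop("motif_len must be even", call. = FALSE)
  if (nchar(motif_consensus) != motif_len)
    stop("motif_consensus length must equal motif_len", call. = FALSE)
  if (!is_palindromic(motif_consensus))
    stop("motif_consensus must equal its own reverse complement",
         call. = FALSE)
  check_scalar_int(site_mutations_max, "site_mutations_max", min = 0)
  check_scalar_int(n_target_families, "n_target_families", min = 1)
  check_scalar_int(decoy_count, "decoy_count", min = 0)
  if (n_core_families < n_target_families + 1 + decoy_count)
    stop("n_core_families must cover targets + regulator + decoys",
         call. = FALSE)
  if (decoy_genome < 1 || decoy_genome > n_genomes)
    stop("decoy_genome out of range", call. = FALSE)
  if (protein_divergence < 0 || protein_divergence >= 1)
    stop("protein_divergence must be in [0, 1)", call. = FALSE)
  if (intergenic_len_bp[1] < motif_len + 40)
    stop("mean intergenic length too short to host implanted sites",
         call. = FALSE)
  cfg <- as.list(environment())
  cfg$target_family_ids <- sprintf("F%03d", seq_len(n_target_families))
  cfg$tf_family_id <- sprintf("F%03d", n_target_families + 1L)
  cfg$decoy_family_ids <- if (decoy_count > 0)
    sprintf("F%03d", n_target_families + 1L + seq_len(decoy_count))
  else character(0)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic pangenome with ground truth
#'
#' Draws one ancestor protein per ortholog family, derives each genome's
#' member by i.i.d. residue substitutions at `protein_divergence`, and
#' assembles each genome as alternating intergenic spacers (i.i.d. uniform
#' A/C/G/T) and gene bodies in a fixed family order (conserved synteny).
#' Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config].
#' @return List with `genomes` (list of [genome] objects) and `truth`, a
#'   list holding `families` (family_id, class, tf_family), `partition`
#'   (family_id, genome_id, locus_tag), `consensus`, `expr_blocks`, and a
#'   `sites` slot filled by [implant_regulon()].
#' @export
generate_pangenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genomes
  genome_ids <- sprintf("G%02d", seq_len(ng))

  fam <- data.frame(
    family_id = sprintf("F%03d", seq_len(config$n_core_families +
                                           config$n_variable_families +
                                           ng * config$n_specific_per_genome)),
    stringsAsFactors = FALSE)
  n_core <- config$n_core_families
  n_var <- config$n_variable_families
  fam$class <- c(rep("core", n_core), rep("variable", n_var),
                 rep("strain_specific", ng * config$n_specific_per_genome))
  fam$tf_family <- NA_character_
  fam$tf_family[fam$family_id == config$tf_family_id] <- config$tf_label
  if (length(config$decoy_family_ids))
    fam$tf_family[fam$family_id == config$decoy_family_ids[1]] <-
      config$decoy_tf_label

  # presence map: core everywhere; variable in a random subset of size
  # 2..(ng-1); strain-specific in one genome each
  presence <- list()
  for (i in seq_len(nrow(fam))) {
    presence[[fam$family_id[i]]] <- switch(
      fam$class[i],
      core = genome_ids,
      variable = sort(sample(genome_ids, sample(2:(ng - 1L), 1L))),
      strain_specific = genome_ids[
        ((i - n_core - n_var - 1L) %% ng) + 1L])
  }

  # family ancestors: protein + gene length
  plen <- pmax(30L, round(stats::rnorm(nrow(fam), config$protein_len_aa[1],
                                       config$protein_len_aa[2])))
  glen <- pmax(90L, round(stats::rnorm(nrow(fam), config$gene_len_bp[1],
                                       config$gene_len_bp[2])))
  ancestors <- lapply(plen, function(n)
    sample(AA_ALPHABET, n, replace = TRUE))
  names(ancestors) <- fam$family_id

  mutate_protein <- function(anc, rate) {
    n_mut <- stats::rbinom(1L, length(anc), rate)
    if (n_mut == 0L) return(paste(anc, collapse = ""))
    pos <- sample(length(anc), n_mut)
    for (p in pos) anc[p] <- sample(setdiff(AA_ALPHABET, anc[p]), 1L)
    paste(anc, collapse = "")
  }

  genomes <- vector("list", ng)
  names(genomes) <- genome_ids
  partition <- list()
  for (gi in seq_len(ng)) {
    gid <- genome_ids[gi]
    fams_here <- fam$family_id[vapply(fam$family_id,
                                      function(f) gid %in% presence[[f]], TRUE)]
    pieces <- character(0)
    pos <- 0L
    genes <- list()
    for (k in seq_along(fams_here)) {
      f <- fams_here[k]
      ig_len <- max(config$motif_len + 40L,
                    round(stats::rnorm(1L, config$intergenic_len_bp[1],
                                       config$intergenic_len_bp[2])))
      fi <- match(f, fam$family_id)
      strand <- if (config$strand_policy == "plus") "+"
                else sample(c("+", "-"), 1L)
      gene_seq <- random_dna(glen[fi])
      spacer <- random_dna(ig_len)
      pieces <- c(pieces, spacer, gene_seq)
      start <- pos + ig_len
      end <- start + glen[fi]
      pos <- end
      locus <- sprintf("%s_%04d", gid, k * 5L)
      genes[[k]] <- data.frame(
        locus_tag = locus, start = start, end = end, strand = strand,
        protein = mutate_protein(ancestors[[f]], config$protein_divergence),
        product = sprintf("family %s protein", f),
        tf_family = fam$tf_family[fi], stringsAsFactors = FALSE)
      partition[[length(partition) + 1L]] <- data.frame(
        family_id = f, genome_id = gid, locus_tag = locus,
        stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, random_dna(60L))  # trailing spacer
    genomes[[gi]] <- genome(gid, paste(pieces, collapse = ""),
                            do.call(rbind, genes))
  }

  half <- floor(config$n_target_families / 2)
  truth <- list(
    families = fam,
    partition = do.call(rbind, partition),
    presence = presence,
    consensus = config$motif_consensus,
    expr_blocks = list(block1 = config$target_family_ids[seq_len(half)],
                       block2 = config$target_family_ids[-seq_len(half)]),
    sites = NULL,
    motif_counts = NULL)
  list(genomes = genomes, truth = truth)
}

#' Implant a regulon's binding sites into a pangenome
#'
#' Writes one motif instance into the upstream region of each target
#' family's operon in every genome where the family is present, at a
#' seeded random offset and with a seeded number (0 ..
#' `site_mutations_max`) of point mutations. Decoy instances -- the same
#' consensus -- are written upstream of the decoy families in
#' `decoy_genome` only. All implanted intervals are recorded in the
#' returned truth.
#'
#' @param pan List `(genomes, truth)` from [generate_pangenome()].
#' @param config The same [sim_config].
#' @return The modified `(genomes, truth)` list; `truth$sites` gains one
#'   row per implanted site (`genome_id`, `start`, `end`, `strand`,
#'   `family_id`, `operon_id`, `sequence` in upstream orientation,
#'   `n_mut`, `decoy`) and `truth$motif_counts` the count matrix of the
#'   non-decoy site sequences.
#' @export
implant_regulon <- function(pan, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  L <- config$motif_len
  cons <- strsplit(config$motif_consensus, "")[[1]]
  truth <- pan$truth
  genomes <- pan$genomes

  jobs <- list()
  for (f in config$target_family_ids) {
    for (gid in truth$presence[[f]]) {
      jobs[[length(jobs) + 1L]] <- list(family = f, genome = gid, decoy = FALSE)
    }
  }
  if (config$autoregulate) {
    for (gid in truth$presence[[config$tf_family_id]])
      jobs[[length(jobs) + 1L]] <- list(family = config$tf_family_id,
                                        genome = gid, decoy = FALSE)
  }
  for (f in config$decoy_family_ids) {
    gid <- sprintf("G%02d", config$decoy_genome)
    jobs[[length(jobs) + 1L]] <- list(family = f, genome = gid, decoy = TRUE)
  }

  operons <- lapply(genomes, call_operons)
  sites <- list()
  for (job in jobs) {
    gid <- job$genome
    locus <- truth$partition$locus_tag[truth$partition$family_id == job$family &
                                         truth$partition$genome_id == gid]
    gnm <- genomes[[gid]]
    ops <- operons[[gid]]
    op_row <- which(vapply(ops$members, function(m) locus %in% m, TRUE))
    op <- ops[op_row, ]
    region <- extract_upstream(gnm, op)
    if (region$empty || region$length < L)
      stop(sprintf("upstream region of operon %s too short for the motif",
                   op$operon_id), call. = FALSE)
    offset <- sample(0:(region$length - L), 1L)
    site <- cons
    n_mut <- sample(0:config$site_mutations_max, 1L)
    if (n_mut > 0L) {
      mpos <- sample(L, n_mut)
      for (p in mpos) site[p] <- sample(setdiff(DNA_BASES, site[p]), 1L)
    }
    site_str <- paste(site, collapse = "")
    # map the region-local offset to genomic coordinates; the oriented
    # region sequence of a '-' operon is the reverse complement of the
    # genomic slice
    if (region$strand == "+") {
      gstart <- region$start + offset
      written <- site_str
    } else {
      gstart <- region$end - offset - L
      written <- revcomp(site_str)
    }
    substr(gnm$sequence, gstart + 1L, gstart + L) <- written
    genomes[[gid]] <- gnm
    sites[[length(sites) + 1L]] <- data.frame(
      genome_id = gid, start = gstart, end = gstart + L,
      strand = region$strand, family_id = job$family,
      operon_id = op$operon_id, sequence = site_str, n_mut = n_mut,
      decoy = job$decoy, stringsAsFactors = FALSE)
  }
  truth$sites <- do.call(rbind, sites)
  real <- truth$sites$sequence[!truth$sites$decoy]
  truth$motif_counts <- site_counts(real)
  list(genomes = genomes, truth = truth)
}

#' Generate a two-block correlated expression matrix
#'
#' Each block of genes shares a latent standard-normal condition profile;
#' each gene adds independent Gaussian noise, so the expected within-block
#' Pearson correlation is `1 / (1 + sd^2)` and the expected between-block
#' correlation is 0. With `expr_corr = r` the noise standard deviation
#' defaults to `sqrt(1/r - 1)`.
#'
#' @param truth Truth list from [generate_pangenome()] (block membership
#'   comes from `truth$expr_blocks`; rows are the model genome's loci).
#' @param config The same [sim_config]; `expr_n_conditions` must be >= 3.
#' @return Numeric matrix (block genes x conditions) with locus_tag
#'   rownames; attribute `"blocks"` maps locus_tag to true block label.
#' @export
generate_expression <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  nc <- config$expr_n_conditions
  if (nc < 3) stop("expr_n_conditions must be >= 3", call. = FALSE)
  sd <- if (!is.null(config$expr_noise_sd)) config$expr_noise_sd
        else sqrt(1 / config$expr_corr - 1)
  set.seed(config$seed + 2000L)
  model <- sort(unique(truth$partition$genome_id))[1]
  rows <- list(); labels <- character(0)
  for (b in names(truth$expr_blocks)) {
    latent <- stats::rnorm(nc)
    for (f in truth$expr_blocks[[b]]) {
      locus <- truth$partition$locus_tag[truth$partition$family_id == f &
                                           truth$partition$genome_id == model]
      if (length(locus) == 0L)
        stop(sprintf("expression block family %s absent from model genome", f),
             call. = FALSE)
      rows[[locus]] <- latent + stats::rnorm(nc, sd = sd)
      labels[locus] <- b
    }
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- sprintf("cond%03d", seq_len(nc))
  attr(mat, "blocks") <- labels
  mat
}

#' Write a simulated pangenome to disk
#'
#' Emits per-genome FASTA + GFF3 (re-readable by [read_genome()]), the
#' truth site table as BED6 plus family/decoy columns, the ortholog-family
#' partition as TSV, and the configuration as a flat YAML-syntax key-value
#' file.
#'
#' @param pan List `(genomes, truth)`.
#' @param config The [sim_config] used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_pangenome <- function(pan, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in pan$genomes) {
    write_genome(g, file.path(dir, paste0(g$genome_id, ".fna")),
                 file.path(dir, paste0(g$genome_id, ".gff3")))
  }
  utils::write.table(pan$truth$partition,
                     file.path(dir, "ortholog_families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pan$truth$sites)) {
    s <- pan$truth$sites
    bed <- data.frame(chrom = s$genome_id, chromStart = s$start,
                      chromEnd = s$end,
                      name = paste0(s$family_id, ifelse(s$decoy, "_decoy", "")),
                      score = 0L, strand = s$strand)
    utils::write.table(bed, file.path(dir, "true_sites.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  scal <- Filter(function(x) is.atomic(x) && length(x) <= 2, unclass(config))
  writeLines(vapply(names(scal), function(k)
    sprintf("%s: %s", k, paste(scal[[k]], collapse = ",")), ""),
    file.path(dir, "config.yaml"))
  invisible(dir)
}
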