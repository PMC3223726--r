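---
title: "Comparative regulon reconstruction: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative regulon reconstruction: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(panregulon)
```

`panregulon` reconstructs bacterial transcriptional regulons by
comparative genomics: it detects orthologs across a set of related
genomes, learns a transcription-factor binding motif from the upstream
regions of a training set of operons, scans all genomes for further
sites, and keeps only candidates whose orthologs in other genomes carry
sites too. This vignette is the package's account of the underlying
models, every parameter that matters, the numerical conventions, and the
places where the design was genuinely open.

## 1. Coordinate and sequence model

Internally every interval is 0-based half-open on the forward strand;
GFF3 files are converted from their 1-based inclusive convention at the
I/O boundary only, and BED output is written 0-based half-open as the
format requires. A `genome` couples one replicon sequence (A/C/G/T/N)
with a gene table (`locus_tag`, interval, strand, optional protein,
product and TF-family label). Multi-replicon organisms are processed one
replicon at a time.

Operons are called as maximal runs of co-directional genes whose
intergenic gaps are at most `max_gap_bp` (default 200 bp, a common
distance threshold for bacterial operon prediction; the choice only
needs to be consistent between training and scanning). Every gene
belongs to exactly one operon, and the operon's lead gene is its 5'-most
member in transcription order.

Upstream regions are taken per **operon lead gene** (not per gene): the
intergenic segment immediately 5' of the lead gene, truncated at
`max_len = 350` bp or at the nearest annotated gene boundary. Minus-strand
regions are reverse-complemented so position 0 is always farthest from
the start codon. Divergently transcribed operon pairs share their
intergenic segment and the region is reported for both — divergent
TF/target arrangements are common in bacterial regulons, so neither side
may be discarded. A per-gene variant is available by calling
`extract_upstream()` on single-gene operons. Zero-length regions (lead
gene at a contig edge) are flagged and excluded from training sets.

## 2. The recognition model

A motif of even length $L$ is a position weight matrix derived from the
counts $n_{bj}$ of base $b$ at column $j$ over $N$ aligned sites:

$$f_{bj} = \frac{n_{bj} + 0.5}{N + 2}, \qquad
  w_{bj} = \log_2 \frac{f_{bj}}{0.25}, \qquad
  \mathrm{score}(s) = \sum_j w_{s_j j}.$$

The pseudocount of 0.5 per cell keeps weights finite at $N$ as small as
a handful of training sites; the uniform 25% background matches the
simulator's background composition exactly, which makes the log-odds
calibration of recovery tests exact rather than approximate. Information
content is $\mathrm{IC} = \sum_j \sum_b f_{bj} \log_2 (f_{bj}/0.25)$
bits; a uniform column contributes 0 and a fully conserved column
approaches 2 bits. The consensus takes the per-column argmax with
alphabetical tie-breaking, so it is deterministic.

Because the targeted motifs are palindromic (homodimeric TFs),
`symmetrize()` folds each count cell with its reverse-complement mirror:
$n'_{bj} = n_{bj} + n_{\bar b, L-1-j}$. After symmetrization a window and
its reverse complement score identically (to floating precision; the
package treats differences below $10^{-9}$ as ties), so scanning one
strand suffices and each palindromic site is reported once, on the
forward strand. Symmetrization is on by default in discovery and can be
disabled for non-palindromic profiles, in which case both strands are
scanned and duplicate intervals with equal scores keep the forward
record.

## 3. Iterative palindrome-seeded discovery

`discover_motif()` assumes each training region harbors at most one
binding box. Its parameters:

* `motif_len` (L, bp): fixed per run; TF families differ in box length,
  so no automatic width search is attempted.
* `max_mismatched_pairs` (m): a *weak palindrome* is a window with at
  most m of its L/2 complementary position pairs broken. Default
  `ceiling(L/4)` — half of the pairs may be imperfect, which admits real
  boxes carrying a couple of mutations while still thinning the
  candidate set roughly six-fold relative to all windows.
* `max_ignored` (d): number of lowest-scoring regions dropped from the
  profile, i.e. training sequences allowed to be ignored. Default
  `floor(n/5)` for ab initio runs, where training sets are noisy; **0
  for propagation**, where the training set consists of orthologs of
  already-known targets. The latter is forced by the threshold rule: the
  scan threshold is the training minimum, so dropping d true regions
  would raise the threshold above their own sites and cap recall at
  (n−d)/n by construction.
* `max_seeds`: each weak palindrome can seed the iteration, but seeds
  are explored strongest-palindrome-first (fewest mismatched pairs, then
  input order) and capped at 100 distinct seed sequences. Real boxes are
  near-palindromic and sort to the front; the cap removes a quadratic
  blow-up on large training sets without affecting which profile wins in
  practice.
* `max_iter` (default 30): each iteration scores all weak palindromes,
  keeps the best window per region (ties to the smaller offset), drops
  the d lowest regions (ties drop the later region), and rebuilds the
  profile. The iteration stops when the selected window set repeats —
  the selection sequence over a finite set is eventually periodic, so
  termination is guaranteed; hitting `max_iter` first returns the last
  profile with `converged = FALSE`.

Among all converged profiles the one with the largest information
content wins; exact IC ties (compared at $10^{-12}$) go to the
lexicographically smallest consensus, making the whole procedure
deterministic for a fixed input.

`compare_motifs()` calls a column of the reference motif *conserved*
when its per-column IC is at least 1 bit (configurable), counts
consensus mismatches at those columns only, and bins them as
conserved (0), slightly (1–2), moderately (3–4) or completely (≥ 5)
different. Motifs of unequal length are aligned at the ungapped offset
of their consensi with the most matches; conserved columns left outside
the overlap count as mismatches.

## 4. Scanning and the training-minimum threshold

The scan threshold is the lowest score observed in the training set, and
the comparison is `>=`, so every training site is re-detected by
construction (self-consistency). The default scan space is the set of
upstream regions; genome-wide scanning is available, with hits assigned
to operons by containment in upstream regions afterwards (a hit in a
shared divergent segment yields one record per flanking operon). Windows
containing N are skipped everywhere. No p-value calibration is applied:
the cross-genome consistency filter, not the score, is the specificity
mechanism.

## 5. Orthology

Proteins are compared by Smith–Waterman local alignment (BLOSUM62, gap
open 11, extension 1, a gap of length k costing `open + k·ext`),
implemented as a compiled Gotoh kernel in `src/sw.cpp`; a test asserts
score equality against `Biostrings::pairwiseAlignment()` and an
independent plain-R dynamic program. Identity is matches over aligned
columns *including* gap columns — conventions differ, so the choice is
stated explicitly. A pair is a BBH ortholog when each protein is the
other's highest-scoring hit (score ties broken by lexicographic
locus_tag), identity is ≥ 0.30 and the raw alignment score is ≥ 50.

The score floor is a deliberate addition to the classic
BBH-plus-identity rule: two proteins that both lack a homolog in the
partner genome are still each other's mutual best hit by chance, and the
short local alignments involved (observed raw scores ≈ 30) routinely
exceed 30% identity, so an identity cutoff cannot remove them. Any
genuine ortholog at the divergences the pipeline targets (≤ 10% per
residue over ≥ 30 aa) scores far above 50. Ortholog groups are connected
components of the BBH graph; tree-based refinement of dubious groups is
out of scope. Groups are named by their member in the model genome (the
first genome supplied), and classified core (all genomes), variable
(≥ 2, < all) or strain-specific (exactly one), with summary percentages
rounded to integers.

## 6. Regulon propagation and ab initio inference

`propagate_regulon()` composes the stages: locate the regulator's
ortholog group; collect the model genome's known targets; pull the
upstream regions of the targets' orthologous operons in every
regulator-encoding genome (training on lead-gene upstreams only);
rediscover the motif; scan all upstream regions of those genomes at the
pooled training-minimum threshold (one threshold per regulon); apply the
consistency filter (`min_other_genomes = 2`). If the filtered membership
differs from the training set, the procedure repeats once from the
training-collection step with the enlarged target list — a single repeat
bounds runtime and is configurable. The rediscovered motif is compared
against the seed motif and the divergence class reported. A regulator
with no ortholog anywhere produces an explicit skip report rather than
an empty regulon.

`infer_novel_regulon()` runs discovery on a user-supplied training set
of putatively co-regulated operons (pathway- or cluster-derived), scans,
filters, and leaves the regulator unassigned; regulons whose motif
carries less than 1 bit per column on average are flagged `low_ic` — at
that level no column would qualify as conserved under the comparison
default, so the profile supports no confident regulon. TF-less regulons
remain representable. `attribute_tf()` then scores every TF-labelled
ortholog group on three boolean evidences — a group member within two
genes of a member operon, a site in the group's own upstream
(autoregulation), and exact identity of the group's genome-presence
pattern with the regulon's — and reports all top-scoring groups; ties
are reported, never broken, because the evidence types are not
commensurable.

Functional-relatedness retention in the consistency filter is an
explicit user-supplied list of operons, never inferred automatically;
automatic subsystem annotation is outside the package's scope.

## 7. The simulator: what it emulates, and what it does not

`sim_config()` defaults define the reference study conditions: 16
genomes; 18 core families of which 12 are regulon targets, 1 is the
regulator (labelled `LacI`) and 5 host decoys; 4 variable families
(present in 2–15 genomes) and 1 strain-specific family per genome;
protein ancestors mutated i.i.d. at 5% per residue (no indels, keeping
alignment identity analytically predictable); background intergenic DNA
i.i.d. uniform over ACGT (25% per base, matching the PWM background);
an 18-bp palindromic consensus `ATTGACAATATTGTCAAT` implanted once per
target upstream at a uniform random offset with 0–2 point mutations;
5 decoy sites sharing the *same* consensus but confined to one genome,
so that only the consistency filter — never the score — can remove them;
and a two-block expression design over the target families
(50 conditions, within-block Pearson r = 0.8 via a shared latent profile
plus Gaussian noise of sd $\sqrt{1/r - 1}$, between-block r = 0).
Everything is a pure function of the seed.

Genes default to the forward strand (`strand_policy = "plus"`). With
random strands, a divergent neighbor pair shares its intergenic segment
in every genome (synteny is fixed), so an implanted site is legitimately
assigned to both flanking operons and the non-target neighbor becomes a
*consistent* cross-genome member — a property of divergent promoters,
not an error, but one that makes exact member-level truth comparison
ill-posed. The forward-strand default keeps each promoter private;
divergent arrangements and minus-strand extraction are exercised by
dedicated fixtures instead. Protein length (default 60 aa) is decoupled
from gene length so the all-vs-all alignment stays fast at simulation
scale.

The simulator does **not** model phylogenetically correlated sequence
evolution, indels, horizontal transfer, operon rearrangement, GC skew
(an option exists but defaults off via uniform background), multiple
boxes per promoter, or condition-structured expression beyond the
two-block design. Passing recovery tests therefore demonstrates the
pipeline's correctness under clean, calibrated conditions — not its
performance on real genomes, where motif information content, background
composition and annotation quality all degrade the signal.

## 8. Numerical conventions and degenerate inputs

* Score/threshold comparisons are `>=`; strand-duplicate suppression and
  palindromic-tie detection use an absolute tolerance of $10^{-9}$; IC
  ties in model selection use $10^{-12}$.
* Regions shorter than L yield empty window sets (not errors); fewer
  than 3 regions with weak palindromes is a discovery error; `max_ignored`
  may not leave fewer than 3 regions.
* Constant expression profiles are excluded from correlation matrices
  with a warning instead of propagating `NaN`; fewer than 3 conditions
  is an error.
* Empty scan results, empty BBH pair sets and empty attributions are
  valid values, not errors; a regulator without orthologs is a skip
  report.
* All randomness in the simulator derives from the config seed; the
  discovery/scanning/orthology stages are fully deterministic.

## 9. Test and verification scale

The test suite verifies each operation against independent oracles
(hand dynamic programs, exhaustive enumerations, closed-form arithmetic)
and runs recovery checks at two scales chosen to keep a laptop run
comfortable: a compact 6-genome configuration (10-bp motif, 5 target
families) for per-module checks, and the full 16-genome default (18-bp
motif, 12 target families, ~190 implanted sites) for motif recovery,
consistency-filter discrimination, orthology recovery and end-to-end
propagation, the latter replicated across seeds with 9/10 success
required. `scripts/acceptance.R` re-runs the same analyses from scratch
and writes the resulting rates and indices as JSON.

## 10. Known limitations

* One motif per regulon run: regulators whose binding specificity
  differs across subclades are not split automatically.
* Connected-component orthology merges families linked by any single
  spurious BBH edge; the score floor makes this rare at simulation
  scale, but real proteomes with large paralogous families would need
  tree-aware refinement.
* The consistency filter counts genomes with hit-bearing orthologs; it
  does not require positional conservation of the site within the
  upstream region.
* Riboswitch/attenuator (RNA-element) regulons, TF-family HMM
  assignment, and genome annotation itself are out of scope; `tf_family`
  labels are consumed as input.
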