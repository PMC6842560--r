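---
title: "Characterizing a gene family genome-wide: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a gene family genome-wide: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genefamkit)
```

## The problem

A genome-wide gene family survey answers a fixed set of questions about a
transcription-factor family in a newly sequenced genome: which proteins
carry the family's diagnostic domain, how the members split into
subfamilies, where they sit on the chromosomes, which arose by duplication,
which have orthologs in related species, how their exon–intron structures
differ, and where they are expressed. `genefamkit` implements this survey
as a set of composable, individually tested operations, using the MADS-box
family in willow as its running example: a family defined by a compact
(~60-residue) DNA-binding domain, split into M-type subfamilies
(Mα, Mβ, Mγ; domain-only proteins with 0–1 introns) and MIKC-type
subfamilies (MIKCc, MIKC*; carrying an additional keratin-like K domain
and a multi-intron structure).

The package ships a transcription of a published 60-gene family census as
`inst/extdata/willow_family_table.tsv`; every census statistic the package
reports (placement counts, subfamily sizes, orthologue row counts, intron
statistics, length ranges) is recomputed from this table by
`summarize_family()`, not hard-coded.

## Identification by two evidence sources

Membership calling mirrors the standard HMMER + BLAST protocol, with both
steps implemented locally:

* **Profile evidence.** `build_pssm()` turns a Stockholm seed alignment
  into a position-specific scoring matrix over its match columns (columns
  with < 50 % gaps). The estimate for residue $a$ in column $c$ is
  $\hat p = (n_{c,a} + \beta q_a)/(n_c + \beta)$ with pseudocount weight
  $\beta$ (default 1) and background $q$ (default uniform); the score is
  $\log_2 (\hat p / q_a)$ bits. `scan_protein()` slides the profile
  gaplessly, scores `X` as 0, and merges overlapping windows keeping the
  best of each chain. A gapless scan rather than a full profile HMM is a
  deliberate simplification: the discriminative signal is a single compact
  domain, and truncations are caught by the completeness filter below.
  The default threshold is half the maximal attainable profile score —
  far above anything background sequence reaches, yet comfortably below
  the score of a genuine domain, and overridable.

* **Alignment evidence.** `local_align()` computes Smith–Waterman local
  alignments with affine gaps (opening costs `gap_open + gap_extend`,
  default BLOSUM62 11/1) and reports raw score, bit score (via the frozen
  gapped Karlin–Altschul constants λ = 0.267, K = 0.041 for BLOSUM62
  11/1), identity, positive-substitution similarity, and the fraction of
  the longer sequence covered. `evalue()` converts bit scores to
  E-values, $E = mn\,2^{-S'}$, honoring the conventional thresholds
  (identification 1e-3, orthology 1e-20).

`identify_family()` takes the **intersection**: a candidate needs a profile
hit *and* an alignment to a reference family protein at E ≤ 1e-3. A
candidate then survives only if its alignment to its best reference covers
at least 80 % of that reference's own domain window — the "entire domain"
filter. We chose the reference-side footprint deliberately: a full-width
gapless window always covers 100 % of the profile by construction, so the
only quantity that can reveal a truncated domain is how much of a known
complete domain the candidate manages to align. A protein carrying half a
domain covers ~50 % and is removed even when its window score clears the
threshold.

Members are renamed by chromosomal position (`rename_by_position()`):
chromosomes in natural numeric order (`chr2` before `chr10`), start
ascending, unplaced genes after all placed ones ordered by original id,
numbered from 1 without gaps.

## Classification into subfamilies

The survey protocol builds a neighbor-joining tree of family and reference
proteins and reads subfamily membership off the tree. We reproduce this
with three operations:

* `pairwise_distances()` computes all-pairs global (Needleman–Wunsch)
  alignments and defines distance as one minus identity over the aligned
  columns — columns holding a residue in *both* sequences. Gap columns are
  excluded because affine-gap optima are not unique at domain boundaries:
  two equal-scoring alignments can place the same residues against a
  terminal or an internal gap, and counting gap columns would make the
  distance depend on that arbitrary choice. All-pairs alignment replaces a
  progressive multiple alignment; it preserves the distance-matrix
  contract of the tree step without importing an MSA heuristic.
* `nj_tree()` is a direct implementation of Saitou–Nei neighbor joining
  (minimize $Q(i,j) = (n-2)d_{ij} - r_i - r_j$, two-point branch lengths,
  three-taxon closure). Negative branch-length estimates are clamped to
  zero with a warning, matching common tree-software behavior. On additive
  matrices the generating tree is recovered exactly (this is tested, with
  `ape::nj` as an independent cross-check on non-additive input).
* `classify_subfamilies()` assigns each query the class of its nearest
  labeled reference under patristic distance. Exact ties go to a majority
  vote among the three nearest references; a persisting tie falls back to
  the lexicographically smallest tied reference and is flagged
  `ambiguous`. Nearest-reference assignment is our operationalization of
  "read the clade off the figure": the published trees interleave clades,
  so clade membership is not well-defined without labeled anchors, whereas
  nearest-reference is deterministic and auditable.

## Duplication, clusters, orthology

* **65/65 rule.** `duplication_pairs()` keeps a pair when the alignment
  covers *more than* 65 % of the longer gene and the aligned region is
  *more than* 65 % similar ("similarity" = positive-substitution fraction,
  BLAST's "positives", since identity is reported separately). Both
  inequalities are strict — a pair at exactly 0.65 is rejected.
* **Categories.** Pairs on different chromosomes are segmental. Same
  chromosome and adjacent — start-to-start ≤ 200 kb with at most one
  intervening family gene — is tandem. Same chromosome but distant is
  reported as *proximal* rather than silently folded into segmental,
  because the published dichotomy (adjacent vs different-chromosome) is
  not exhaustive. An unplaced gene makes the category unknowable: error.
* **Clusters.** `detect_clusters()` chains genes per chromosome by
  single linkage on start-to-start distance ≤ 200 kb and emits maximal
  chains with ≥ 2 genes. Chaining means a cluster's total span may exceed
  200 kb; the alternative reading (total span ≤ 200 kb) would make
  cluster membership order-dependent, so we chose chaining and document
  it.
* **Orthology.** `bbh_orthologs()` implements reciprocal best hits at
  E ≤ 1e-20 in both directions. Equal-score best-hit ties disqualify the
  gene (returned in the `ties` attribute) rather than letting an
  arbitrary ordering pick a winner.

## Gene structure, motifs, physicochemistry

Intron counts are exon counts minus one on a single transcript per gene;
when a GFF3 gene has several mRNAs, `read_gff3()` keeps the one with the
greatest summed exonic length, since a census reports one intron count per
gene. Fixed motifs (activation LXXLL, inhibitory LXLXLX) are scanned with
all overlapping occurrences reported. The basic leucine zipper is reduced
to a deterministic rule — a maximal run of ≥ 4 leucines at exact 7-residue
periodicity preceded within 15 residues by ≥ 3 K/R — standing in for
coiled-coil prediction; outputs are labeled with this definition. K-domain
presence reuses the profile scanner with a second seed alignment.

Molecular weight is the sum of average residue masses plus one water;
isoelectric point is the root of the Henderson–Hasselbalch net charge
found by bisection on [0, 14] to |charge| < 1e-4, with the Bjellqvist pKa
set (the ExPASy-compatible choice) stored as a swappable table. Because
charge is strictly decreasing in pH the root is unique; the test suite
checks bisection against a dense grid search.

## Expression

RPKM is computed as $10^9 c_{g,t} / (N_t L_g)$ and standardized as
$\log_2(\mathrm{RPKM} + 1)$. The pseudocount is our choice: the log of
zero RPKM is undefined while published heat maps show "no expression"
cells, so zero maps to zero on the log scale. qPCR fold changes follow
2^−ΔΔCt with technical replicates averaged first, ΔCt taken against the
reference gene per biological replicate, and the calibrator baseline
defined as the mean ΔCt of the calibrator tissue across its biological
replicates; means and standard deviations are reported over biological
replicates.

## The synthetic-data generator

Real survey inputs (a proteome, an annotation, counts) cannot ship with
the package, so `generate_family_data()` builds a study whose ground truth
is recorded in a manifest. Its defaults are fixed study conditions, not
tuning knobs:

* subfamily sizes 11/7/4/32/6 — the census sizes — plus 60 background
  decoys and 2 truncated-domain plants;
* a 60-column core-domain seed alignment (8 rows at 10 % mutation) and a
  92-column K-domain seed; subfamily centroids at 8 % divergence from the
  consensus, members at 2 % from their centroid. These rates emulate a
  strongly conserved domain, the regime in which a single-profile scan is
  the right tool; families with weakly conserved domains would need a
  true profile HMM and are outside what passing tests demonstrate;
* M-type members are flank + domain + flank with 0–1 introns; MIKC-type
  members add a linker, a K-domain sample, optionally a planted basic
  leucine zipper, and carry 4–13 introns. C-terminal flanks are long
  (350–450 residues): same-subfamily members share a highly conserved
  domain(+K) block, and the flanks keep that shared block well below the
  65 % coverage rule, so that non-duplicate members are unambiguously
  non-duplicates under the generator's own ground truth — for proteins
  much shorter than ~500 residues the coverage and similarity thresholds
  can be crossed simultaneously by a marginal alignment extension;
* duplicate pairs are mutated copies at 80 % whole-protein identity with
  the domain regions protected (so the copy stays identifiable); the
  identity is alignment-verified to ±2 points. Tandem pairs are placed
  ≤ 200 kb apart, segmental pairs on different chromosomes, planted
  clusters use 60–150 kb start-to-start gaps, and unrelated placement
  units are separated by ≥ 300 kb so no accidental clusters arise;
* the second species holds orthologs at 90 % identity for half the
  members plus its own decoys;
* five-tissue counts are negative binomial (dispersion 5) around
  log-normal base means scaled by per-tissue multipliers, with the root
  multiplier fixed at 0.4 — the planted depletion; Ct tables are
  `base − log2(multiplier) + N(0, 0.1)` in 3 biological × 3 technical
  replicates with a constant-expression reference gene.

All randomness derives from one seed through fixed per-stream offsets, so
adding a stream never perturbs earlier ones and a fixed seed regenerates
byte-identical files (hash-tested). A self-audit pass checks the manifest
against the emitted objects before anything is returned.

Synthetic proteins are i.i.d. outside the planted domains; they lack
compositional bias, repeats, paralog families at intermediate identity,
alternative transcripts, and assembly artifacts. Perfect recovery on this
generator therefore demonstrates correctness of the algorithms under the
stated conditions, not robustness to the full messiness of real
proteomes.

## Problem sizes and numerical choices

The shipped tests run the full default family (60 members + 62 non-members)
for identification across 20 seeds and for one classification tree, and a
reduced family (9 members + 9 non-members) for the 20-seed duplication and
qPCR recovery loops — all-pairs alignment grows quadratically and the
reduced family exercises the same code paths. qPCR recovery is asserted on
the mean relative fold error (< 15 %): individual replicate folds carry
~5 % multiplicative noise from the planted Ct noise, so a per-fold bound
would measure noise, not correctness.

Ties are broken deterministically everywhere (first minimum in row-major
order in NJ; lexicographic reference in classification), distances are
validated symmetric to 1e-12, and degenerate inputs (empty sets, sequences
shorter than the profile, header-only tables) return empty results or
informative errors rather than being silently dropped.

## Known limitations

* The profile scan has no insert/delete states; domains with indels
  relative to the seed lose score linearly.
* Segmental duplication is called from chromosome placement only; no
  collinearity or Ka/Ks evidence is used.
* The distance is an uncorrected p-distance; no Poisson/JTT correction is
  applied before NJ, matching the protocol it reproduces.
* The zipper rule is a stand-in for coiled-coil prediction and will not
  match tools built on helical-wheel statistics.
* Amplification efficiency is fixed at 2 in the qPCR model.
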