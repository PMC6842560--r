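# genefamkit

Genome-wide identification and characterization of a gene family, as an R
package. `genefamkit` implements the full survey protocol used for plant
transcription-factor families — here exercised on the willow MADS-box
family — as composable, individually tested operations:

* **Identification** — a position-specific scoring matrix built from a
  Stockholm seed alignment (log-odds with pseudocounts,
  `score = log2(((n_a + βq_a)/(n_c + β))/q_a)` bits), scanned gaplessly
  over the proteome, intersected with Smith–Waterman/BLOSUM62 alignment
  evidence against reference family proteins (Karlin–Altschul E-values,
  `E = mn·2^−S'`), plus an entire-domain completeness filter and
  positional renaming along the chromosomes.
* **Classification** — all-pairs global-alignment distances, Saitou–Nei
  neighbor joining (`Q(i,j) = (n−2)d(i,j) − Σd(i,·) − Σd(j,·)`), and
  nearest-labeled-reference subfamily calls under patristic distance, into
  the five subfamilies Mα, Mβ, Mγ, MIKCc, MIKC*.
* **Duplication & synteny-free homology** — the 65/65 rule (coverage of
  the longer gene > 65 % and similarity of the aligned region > 65 %),
  tandem/segmental/proximal categorization, 200-kb gene-cluster chaining,
  and reciprocal-best-hit orthology at E ≤ 1e-20.
* **Structure & motifs** — exon–intron statistics from GFF3 (longest
  transcript per gene), LXXLL / LXLXLX scanning, leucine-zipper heptad
  detection with a basic flank, K-domain presence via a second profile.
* **Physicochemistry** — molecular weight from average residue masses and
  isoelectric point by bisection with the Bjellqvist pKa set.
* **Expression** — RPKM (`10^9·c/(N_t·L_g)`), log2(RPKM+1)
  standardization, tissue totals, and 2^−ΔΔCt qPCR quantification with
  technical-then-biological replicate aggregation.
* **Synthetic data** — a seeded generator that emits a proteome with
  planted domains, an annotated genome with planted duplications and
  clusters, a second species, count matrices and Ct tables, together with
  a ground-truth manifest, so the whole pipeline is testable offline.

The package ships a 60-gene family census table
(`inst/extdata/willow_family_table.tsv`); all census statistics are
recomputed from it at run time.

## A worked example

```r
library(genefamkit)

# a fully synthetic study with recorded ground truth
g <- generate_family_data(generator_config(seed = 1))

# identify family members: profile scan ∩ alignment evidence
pssm <- build_pssm(g$seed_mads)
print(pssm)
#> <pssm> width 60, max attainable score 240.0 bits
#> consensus: PNWELWFQPTTDFWPMNLMFDYKDYPAFGCSYNSQTMIVREHYVVECSILLEYMPQHGRS

res <- identify_family(g$proteins, pssm, g$refs)
length(res$ids)
#> [1] 60
setequal(res$ids, g$manifest$members$id)
#> [1] TRUE

# census statistics from the packaged family table
tab <- read_family_table(system.file("extdata", "willow_family_table.tsv",
                                     package = "genefamkit"))
summarize_family(tab)
#> <family_summary> 60 genes, 56 placed on 19 chromosomes
#> classes: Mα 11, Mβ 7, Mγ 4, MIKCc 32, MIKC* 6
#> introns: max 13; 34 MIKC-type rows with >= 4; M-type zero-intron 77%
```

The identification run recovers exactly the 60 planted members among 122
proteins (sensitivity and specificity 1.0), and the census summary prints
the placement, subfamily and intron statistics of the packaged table —
56 of 60 genes on 19 chromosomes, subfamily sizes 11/7/4/32/6, at most 13
introns, 77 % of M-type genes intron-less.

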