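---
title: "Measuring codon usage bias: models, indices and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring codon usage bias: models, indices and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

## The problem

Synonymous codons are not used uniformly. In any genome the usage of a
codon family is pulled by two forces: *mutational pressure* (the genome-wide
nucleotide substitution bias, most visible at the third codon position,
which is largely silent) and *translational selection* (preference for
codons matched to the abundant tRNA pool, strongest in highly expressed
genes). Obligate symbioses — such as a parasitic fungus and its insect
host — make the question comparative: do the two partners' nuclear and
mitochondrial gene sets sit at different points on the mutation–selection
continuum?

`codonbias` implements the complete workflow used for such comparisons:
screening coding sequences, per-gene composition indices, the three
classical diagnostics (neutrality regression, ENC–GC3 analysis, PR2 parity
plot), correspondence analysis of the gene × RSCU matrix, and
optimal-codon identification. A synthetic CDS generator with known ground
truth makes every step testable without any sequence download.

## Screening

Raw CDS sets are filtered by four rules, applied in a fixed order; the
first failing rule is the recorded rejection reason:

1. the sequence begins with ATG;
2. length ≥ 300 nt (`min_length_nt`, inclusive);
3. length divisible by 3, no internal stop codon under the sequence's
   genetic code, and a terminal stop codon; sequences in which more than
   5 % of codons contain N are also rejected here;
4. redundancy removal at 95 % identity (`identity_threshold`).

Identity is defined on a *global* alignment (match = 1, mismatch = 0, a gap
cost of 1 per gap column used for alignment only) as matching columns
divided by all alignment columns, end gaps included. Redundancy removal is
greedy longest-first (as in CD-HIT): sequences are visited by decreasing
length, ties broken by lexicographic id, and a sequence is dropped if it
reaches the threshold against any already-kept sequence. This is
deterministic and reproducible; it is not guaranteed to minimise the number
of removed sequences. A conservative shared-8-mer prefilter (only active
for thresholds ≥ 0.9, where the k-mer bound is informative) and a
length-ratio bound skip alignments that provably cannot reach the
threshold.

Genetic codes come from the NCBI tables via `Biostrings`; the default is
table 1 (standard), with tables 4 (mold mitochondrial) and 5 (invertebrate
mitochondrial) the usual choices for fungal and insect organelles. All
degeneracy-dependent indices recompute family structure from the active
code — under table 5, for example, Ser is an 8-fold family (AGA/AGG join
it) and Ile is 2-fold.

## Per-gene indices

For a gene with codon counts `n_c`:

- **GC, GC1, GC2, GC3** — G+C fractions overall and per codon position over
  sense codons; **GC12** is the mean of GC1 and GC2.
- **GC3s, A3s/T3s/C3s/G3s** — base composition restricted to third
  positions of synonymously *variable* codons (families of size ≥ 2;
  Met/Trp-like families and stops excluded). GC3 and GC3s are distinct
  quantities and both are always reported; published tables often conflate
  them.
- **RSCU** — for codon `c` in a family of size `k` with family total `N`:
  `RSCU(c) = n_c / (N/k)`. Unobserved families give missing values, not
  zeros, so that family means stay interpretable.
- **ENC (observed)** — Wright's estimator. Per amino acid with `n ≥ 2`
  codons observed, the homozygosity is `F = (n Σ p² − 1)/(n − 1)`;
  estimates are averaged within degeneracy classes, and
  `ENC = N₁ + Σ_k N_k / F̄_k` over the classes of the active code
  (`2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆` for the standard code). Families with
  `F ≤ 0` (possible at very small `n` with near-uniform usage) are excluded
  as inestimable, since their reciprocal contribution is unbounded. A
  missing 3-fold class is imputed as `(F̄₂ + F̄₄)/2`; any other missing
  class, or fewer than two estimable classes, yields `NA`. The result is
  capped to the theoretical range — 20 (one codon per amino acid) to 61
  (uniform usage) for the standard code; the bounds are recomputed for
  other codes.
- **ENC (expected)** — the null curve `2 + s + 29/(s² + (1 − s)²)` at
  silent GC content `s`, i.e. the ENC of a gene whose only source of bias is
  composition. Note the curve is *not* symmetric (31 at `s = 0`, 32 at
  `s = 1`, maximum 60.5 at `s = 0.5`). The **ENC ratio**
  `(ENCexp − ENCobs)/ENCobs` is positive when a gene is more biased than
  composition alone predicts.
- **CAI** — geometric mean of relative-adaptiveness weights
  `w(c) = RSCU(c)/max RSCU in family` derived from a reference set,
  excluding single-codon families and stops. Because no expression data
  accompany a plain CDS set, the default reference is the 5 % of genes with
  the lowest observed ENC — a reproducible proxy for "highly expressed";
  with it, CAI values are comparable within a dataset but not across
  differently chosen references. Codons unobserved in the reference are
  floored at `w = 0.01` so genes using them are penalised rather than
  undefined.
- **Gravy / Aromo** — mean Kyte–Doolittle hydropathy of the translated
  protein, and the fraction of aromatic residues (Phe, Tyr, Trp).

```{r indices-example}
d <- generate_dataset(sim_config(n_genes = 12, length_codons = 120L,
                                 s = c(0.3, 0.7), seed = 1))
m <- gene_metrics(d$cds)
round(head(m[, c("gc3", "gc3s", "enc_obs", "enc_exp", "enc_ratio", "cai")]), 3)
```

## The three diagnostics

**Neutrality regression.** Ordinary least squares of GC12 on GC3 (GC3s
optionally). When a single mutational process drives all three codon
positions, GC12 tracks GC3 and the slope approaches 1; when selection pins
the first two (amino-acid-changing) positions while the third drifts, the
slope approaches 0. The regression is descriptive: it does not partition
variance formally, and with narrow GC3 ranges the slope is poorly
determined even when `r` is significant.

**ENC–GC3 analysis.** Observed ENC is plotted against GC3s over the
expected curve; per-gene ENC ratios are histogrammed in left-closed,
right-open bins of width 0.05 aligned to multiples of the width. Genes on
the curve are explained by composition; genes below it (positive ratio)
carry additional bias, the signature of selection.

**PR2 parity plot.** Per gene, `x = G3/(G3+C3)` and `y = A3/(A3+T3)` over
third positions. Under strand-symmetric mutation with no selection, parity
predicts (0.5, 0.5). Two scopes are offered: third positions of all
synonymously variable codons (`synonymous_third`, the default, matching
common usage) and fourfold-degenerate families only (`fourfold_only`, the
classical choice). The parity prediction is *exact only for the fourfold
scope*: in the full synonymous scope the standard code offers 16 C-ending
but only 13 G-ending synonymous codons (and 16 T vs 14 A), so even a
perfectly symmetric mutation process leaves the mean point below and left
of centre (about (0.44, 0.47) at balanced composition). A pyrimidine excess
at the third position is therefore not by itself evidence of asymmetric
pressure; comparisons should be made within the fourfold scope or against
the code-structure baseline.

## Correspondence analysis

The gene × codon RSCU matrix (59 synonymously variable codons under the
standard code; genes' unobserved families imputed at the no-preference
value 1 for the ordination only) is decomposed by the chi-square metric:
standardized residuals `D_r^{-1/2} (P − r c') D_c^{-1/2}` are factored by
SVD and *principal* coordinates returned, axes ordered by inertia. The sign
of each axis is fixed by making its largest-magnitude codon loading
positive; signs are otherwise arbitrary and not comparable across software.
Mass-weighted row and column coordinates are centered at zero on every axis,
and chi-square distances between gene profiles equal Euclidean distances in
the full-dimensional coordinates — both properties are enforced by tests.

Pairwise correlation tables between indices (Pearson by default, Spearman
optional) report raw two-sided p-values with stars at 0.05 and 0.01,
matching the conventional presentation; a Holm adjustment is available but
off by default since published codon-usage tables almost universally print
unadjusted stars.

## Optimal codons

Two published procedures are implemented, and neither is privileged:

- **max-RSCU**: the codon(s) with maximal RSCU per family in a pooled count
  table; ties are reported as co-optimal.
- **ΔRSCU**: genes are split into "high-expression" and "low-expression"
  groups — by default the 10 % ENC tails, low ENC serving as the expression
  proxy — counts are pooled per group (pooling, rather than averaging
  per-gene RSCU, stabilises sparse mitochondrial families), and a codon is
  optimal when `ΔRSCU = RSCU_high − RSCU_low ≥ 0.08` with `RSCU_high > 1`.
  The 0.08 cutoff and the high-preference requirement are the
  field-standard convention.

```{r optimal-example}
res <- optimal_codons(generate_dataset(
  sim_config(n_genes = 60, length_codons = 150L, s = c(0.55, 0.9),
             regime = "mutation", seed = 2))$cds)
res$endings
```

## The synthetic generator

`sim_config()`/`generate_dataset()` draw genes under an explicit
mutation–selection model. The third-position mutational weight gives G and C
probability `s/2` each and A and T `(1 − s)/2` each. The selection weight
multiplies a family's preferred codon by `exp(beta)`. Two regimes control
the coupling that the neutrality analysis measures:

- **mutation**: every codon is drawn with probability proportional to the
  product of its three positions' base weights (restricted to sense
  codons), so first/second-position composition tracks `s` and a sweep of
  `s` across genes traces a neutrality slope near 1 (theoretical value
  0.987 for a sweep over `s ∈ [0.2, 0.8]`; the small deficit comes from the
  code's constraint structure).
- **selection**: amino acids are drawn iid from fixed frequencies (uniform
  by default) and only the third position follows `s`, so GC12 is flat in
  GC3 and the slope is near 0.

Defaults — 500 genes, lengths uniform on 150–300 codons, `s` swept
uniformly on (0.2, 0.8), `beta = 0` — were chosen once as a realistic
mid-size gene set spanning the compositional range over which the
diagnostics are informative, and are the conditions under which the
package's recovery tests run. Every generated gene passes the default
screening by construction (ATG start, sense codons only, terminal stop,
≥ 306 nt). Generation is fully determined by the integer seed; per-gene
streams are derived from it so that individual genes are reproducible in
isolation.

What the generator deliberately does **not** emulate: amino-acid
composition differences between genes (beyond the mutation-regime
coupling), within-gene heterogeneity, context-dependent mutation (e.g. CpG
effects), strand asymmetry, indels, and any phylogenetic structure. Passing
the recovery tests therefore shows the estimators are correct under the
stated model, not that real genomes satisfy it.

## Numerical and degenerate-input choices

- `enc_observed` returns `NA` (rather than a guess) when fewer than two
  degeneracy classes are estimable; `gene_metrics` propagates the `NA` and
  downstream analyses exclude and count such genes.
- `silent_composition` is undefined (all `NA`, with a warning) for genes
  using only single-codon families.
- Codons containing N are skipped from counts; sequences with more than 5 %
  such codons are rejected at screening.
- RSCU of unobserved families is missing, never 0; the COA imputes 1 there,
  only for the ordination.
- Expression-group selection breaks ENC ties by gene id, so reruns are
  stable.
- The histogram of ENC ratios uses left-closed bins aligned to multiples of
  the bin width starting at the floor of the minimum, so bin membership is
  unambiguous at bin edges.

## Limitations

- CAI depends entirely on the reference set; with the ENC-tail proxy the
  absolute values are not comparable to CAI computed against an
  expression-defined reference (as in CodonW), only the within-dataset
  ordering is meaningful.
- The neutrality slope conflates selection on codon usage with any other
  force that decouples GC12 from GC3 (e.g. selection on protein
  composition).
- Redundancy screening at 95 % identity on large gene sets is quadratic in
  the worst case; the prefilter mitigates but does not remove this.
- GenBank parsing covers the feature constructs found in organellar
  records (`join`, `complement`, `/transl_table`); `order()` locations and
  cross-record references are skipped with warnings.
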