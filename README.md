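# codonbias

Codon usage bias analysis for nuclear and mitochondrial coding-sequence
sets, in R.

Synonymous codons are used unevenly, and the pattern of that unevenness
separates two evolutionary forces: **mutational pressure** (genome-wide
substitution bias, most visible at the largely silent third codon position)
and **translational selection** (preference for codons matched to the tRNA
pool, strongest in highly expressed genes). `codonbias` is for molecular
evolution work that asks where a gene set — a fungal nuclear genome, an
insect mitochondrion, the two partners of an obligate parasitism — sits on
that mutation–selection continuum.

## What it computes

Given CDS sets from FASTA or GenBank flat files (alternative genetic codes
supported, e.g. NCBI tables 4 and 5 for fungal and invertebrate
mitochondria):

- **Screening** — ATG start, minimum length (300 nt), reading-frame and
  internal-stop checks, terminal stop, redundancy removal at 95 %
  global-alignment identity (greedy longest-first), with a full rejection
  report.
- **Per-gene indices** — GC, GC1/GC2/GC3/GC12; silent-site composition
  (GC3s, A3s/T3s/C3s/G3s); RSCU; Wright's effective number of codons
  `ENC = N₁ + Σ N_k / F̄_k` with `F = (nΣp² − 1)/(n − 1)`; the expected-ENC
  null curve `2 + s + 29/(s² + (1−s)²)`; the deviation ratio
  `(ENCexp − ENCobs)/ENCobs`; CAI (geometric mean of `w = RSCU/RSCUmax`
  weights from a low-ENC reference); Gravy and Aromo.
- **Diagnostics** — neutrality regression of GC12 on GC3 (slope ≈ 1:
  mutation-dominated; ≈ 0: selection-dominated); ENC–GC3 plots with the
  expected curve and an ENC-ratio histogram; PR2 parity coordinates
  `(G3/(G3+C3), A3/(A3+T3))`.
- **Multivariate** — correspondence analysis of the gene × RSCU matrix
  (chi-square-metric SVD, principal coordinates) and all-pairs correlation
  tables with significance stars.
- **Optimal codons** — per-family maximum RSCU, and the ΔRSCU contrast
  between pooled low-ENC ("high expression") and high-ENC gene sets,
  calling a codon optimal when `ΔRSCU ≥ 0.08` and `RSCU_high > 1`, with
  third-position ending summaries.
- **Synthetic data** — a CDS generator with tunable third-position GC bias
  `s`, selection strength `beta` on planted preferred codons, and
  mutation/selection regimes that couple or decouple GC12 from GC3, so
  every analysis is testable against known ground truth.

## Worked example

```r
library(codonbias)

# 50 synthetic genes under a mutation-dominated regime, GC3 bias swept
# across genes
d <- generate_dataset(sim_config(n_genes = 50, length_codons = c(120L, 200L),
                                 s = c(0.25, 0.75), regime = "mutation",
                                 seed = 42))
res <- codon_usage_pipeline(d$cds)

res$screening
#> <screening_report> input: 50  kept: 50
res$neutrality
#> <neutrality_fit> gc12 ~ gc3  (n = 50)
#>   slope = 0.9367  intercept = 0.0257  r = 0.9562  p = 2.92e-27
round(res$coa$inertia, 3)
#> [1] 0.230 0.066 0.057 0.055
res$optimal$endings
#>  A  T  G  C
#>  9 14  1  0
```

Reading the output: every generated gene passes screening by construction.
The neutrality slope of 0.94 correctly identifies the mutation-dominated
regime the data were generated under (all three codon positions share one
GC process, so GC12 tracks GC3 nearly 1:1). The first correspondence-
analysis axis carries 23 % of the inertia — the compositional sweep — and
the remaining axes fall off sharply. Because the ENC-extreme "high
expression" group in this sweep is the most AT-biased tail, the ΔRSCU call
flags mostly A/T-ending codons (23 of 24), the direction mitochondrial
gene sets typically show; re-running with `s = c(0.55, 0.9)` flips the
endings to G/C, the typical nuclear direction.

Plot helpers (`plot_neutrality`, `plot_enc_gc3`, `plot_enc_ratio_hist`,
`plot_pr2`, `plot_rscu_heatmap`) return ggplot objects for the standard
figures, and a thin CLI wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/codonbias-cli.R", package="codonbias"))')" \
    simulate --n 500 --len 300 --s 0.7 --beta 1.0 --regime mutation --seed 42 --out-dir sim/
```

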