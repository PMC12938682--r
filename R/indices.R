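# Per-gene codon-usage indices: codon counting, positional GC content,
# silent-site composition, RSCU, Wright's effective number of codons (with
# the expected-ENC curve and ENC ratio), CAI, Gravy and Aromo.

#' Count frame-0 codons of a CDS
#'
#' Codons containing N are skipped from the counts. The terminal stop codon
#' (if present) is recorded separately and excluded from `n_codons`, which
#' counts sense codons only.
#'
#' @param sequence A DNA string with length divisible by 3, or a single-row
#'   [cds_set()].
#' @param transl_table NCBI genetic-code number (ignored if `sequence` is a
#'   cds_set row, which carries its own).
#' @return A `codon_counts` object: integer counts over the 64 codons plus
#'   `transl_table`, `n_codons` and `stop_counts`.
#' @export
count_codons <- function(sequence, transl_table = 1L) {
  if (is.data.frame(sequence)) {
    transl_table <- sequence$transl_table[1]
    sequence <- sequence$sequence[1]
  }
  cods <- split_codons(sequence)
  cods <- cods[!grepl("N", cods, fixed = TRUE)]
  counts <- table(factor(cods, levels = all_codons()))
  counts <- stats::setNames(as.integer(counts), all_codons())
  codon_counts(counts, transl_table)
}

#' Build a codon_counts object from a named count vector
#'
#' @param counts Named non-negative integer vector; names are codons (any
#'   subset of the 64; missing codons are zero-filled).
#' @param transl_table NCBI genetic-code number.
#' @return A `codon_counts` object.
#' @export
codon_counts <- function(counts, transl_table = 1L) {
  full <- stats::setNames(integer(64), all_codons())
  if (any(!names(counts) %in% all_codons())) {
    stop("unknown codon name(s): ",
         paste(setdiff(names(counts), all_codons()), collapse = ", "))
  }
  if (any(counts < 0)) stop("codon counts must be non-negative")
  full[names(counts)] <- as.integer(counts)
  code <- genetic_code(transl_table)
  sense <- names(code)[code != "*"]
  structure(list(
    counts = full,
    transl_table = as.integer(transl_table),
    n_codons = sum(full[sense]),
    stop_counts = full[names(code)[code == "*"]]
  ), class = "codon_counts")
}

#' Pool several codon count tables
#' @param ... `codon_counts` objects (or a single list of them) sharing one
#'   genetic code.
#' @return A pooled `codon_counts`.
#' @export
pool_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "codon_counts")) xs <- xs[[1]]
  stopifnot(length(xs) >= 1L)
  tts <- unique(vapply(xs, function(x) x$transl_table, integer(1)))
  if (length(tts) != 1L) stop("cannot pool counts under different genetic codes")
  total <- Reduce(`+`, lapply(xs, function(x) x$counts))
  codon_counts(total, tts)
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("<codon_counts> transl_table:", x$transl_table,
      " sense codons:", x$n_codons, "\n")
  invisible(x)
}

#' Positional GC content of a codon count table
#'
#' @param t A `codon_counts` object.
#' @return Named vector `gc`, `gc1`, `gc2`, `gc3`, `gc12` — G+C fractions
#'   overall and at each codon position over sense codons; `gc12` is the mean
#'   of `gc1` and `gc2`.
#' @export
base_composition <- function(t) {
  stopifnot(inherits(t, "codon_counts"))
  if (t$n_codons < 1L) stop("empty codon count table")
  code <- genetic_code(t$transl_table)
  sense <- names(code)[code != "*"]
  cnt <- t$counts[sense]
  pos_gc <- vapply(1:3, function(p) {
    b <- substr(sense, p, p)
    sum(cnt[b %in% c("G", "C")]) / sum(cnt)
  }, numeric(1))
  c(gc = mean(pos_gc), gc1 = pos_gc[1], gc2 = pos_gc[2], gc3 = pos_gc[3],
    gc12 = (pos_gc[1] + pos_gc[2]) / 2)
}

#' Silent-site base composition (third positions of synonymous codons)
#'
#' Restricted to third positions of synonymously variable sense codons
#' (families with degeneracy >= 2 under the active code; Met/Trp-like
#' single-codon families and stops are excluded).
#'
#' @param t A `codon_counts` object.
#' @return Named vector `gc3s`, `a3s`, `t3s`, `c3s`, `g3s`; all `NA` (with a
#'   warning) if the gene contains only single-codon families.
#' @export
silent_composition <- function(t) {
  stopifnot(inherits(t, "codon_counts"))
  fam <- codon_families(t$transl_table)
  syn <- fam$codon[fam$family_size >= 2L]
  cnt <- t$counts[syn]
  tot <- sum(cnt)
  if (tot == 0L) {
    warning("no synonymously variable codons observed; silent composition undefined")
    return(c(gc3s = NA_real_, a3s = NA_real_, t3s = NA_real_,
             c3s = NA_real_, g3s = NA_real_))
  }
  third <- substr(syn, 3L, 3L)
  frac <- vapply(BASES, function(b) sum(cnt[third == b]) / tot, numeric(1))
  c(gc3s = frac[["G"]] + frac[["C"]], a3s = frac[["A"]], t3s = frac[["T"]],
    c3s = frac[["C"]], g3s = frac[["G"]])
}

#' Relative synonymous codon usage
#'
#' For codon `c` in a family of size `k` with family total `N`:
#' `RSCU(c) = count(c) / (N / k)`. Families with no observations yield `NA`
#' (missing), not zero. Single-codon families have RSCU 1 by definition.
#'
#' @param t A `codon_counts` object.
#' @return An `rscu_table`: data.frame with `codon`, `aa`, `family_size`,
#'   `count`, `rscu`.
#' @export
rscu <- function(t) {
  stopifnot(inherits(t, "codon_counts"))
  fam <- codon_families(t$transl_table)
  fam$count <- as.integer(t$counts[fam$codon])
  fam_tot <- tapply(fam$count, fam$aa, sum)
  N <- as.numeric(fam_tot[fam$aa])
  fam$rscu <- ifelse(N > 0, fam$count / (N / fam$family_size), NA_real_)
  class(fam) <- c("rscu_table", "data.frame")
  fam
}

#' Wright's observed effective number of codons (ENC)
#'
#' Per amino acid observed `n >= 2` times, the codon homozygosity is
#' estimated as `F = (n * sum(p^2) - 1) / (n - 1)` (families with `F <= 0`,
#' possible at very small `n`, are excluded as inestimable); `F` is averaged
#' within
#' degeneracy classes of the active genetic code and ENC is the sum over
#' classes of (number of families in class) / (mean F of class), plus the
#' number of single-codon families. A missing 3-fold class is imputed as the
#' mean of the 2- and 4-fold class homozygosities; if any other class is
#' missing (or fewer than two classes are estimable) the result is `NA`.
#' The result is capped to the theoretical range (20 to 61 for the standard
#' code; bounds derived from the active code otherwise).
#'
#' @param t A `codon_counts` object.
#' @return ENC value, or `NA` if too sparse to estimate.
#' @export
enc_observed <- function(t) {
  stopifnot(inherits(t, "codon_counts"))
  if (t$n_codons < 1L) stop("empty codon count table")
  fam <- codon_families(t$transl_table)
  fams <- split(fam, fam$aa)

  f_hat <- list()  # per family: degeneracy class and F estimate
  for (aa in names(fams)) {
    k <- fams[[aa]]$family_size[1]
    if (k == 1L) next
    cnt <- t$counts[fams[[aa]]$codon]
    n <- sum(cnt)
    if (n < 2L) next
    p <- cnt / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    # F <= 0 (possible at tiny n near-uniform usage) is inestimable: its
    # reciprocal contribution is unbounded, so the family is excluded
    if (f <= 0) next
    f_hat[[aa]] <- c(k = k, f = f)
  }

  n_single <- sum(tapply(fam$family_size, fam$aa, unique) == 1L)
  class_sizes <- table(tapply(fam$family_size, fam$aa, unique))
  class_sizes <- class_sizes[names(class_sizes) != "1"]

  if (length(f_hat) == 0L) return(NA_real_)
  est <- do.call(rbind, f_hat)
  fbar <- tapply(est[, "f"], est[, "k"], mean)

  needed <- names(class_sizes)
  missing <- setdiff(needed, names(fbar))
  if ("3" %in% missing && all(c("2", "4") %in% names(fbar))) {
    fbar <- c(fbar, "3" = unname((fbar[["2"]] + fbar[["4"]]) / 2))
    missing <- setdiff(missing, "3")
  }
  if (length(missing) > 0L || length(fbar) < 2L) return(NA_real_)

  enc <- n_single + sum(as.numeric(class_sizes[needed]) / unlist(fbar[needed]))
  n_sense <- sum(tapply(fam$family_size, fam$aa, unique))
  n_aa <- length(fams)
  max(n_aa, min(enc, n_sense))
}

#' Expected ENC under mutation-drift balance at a given silent GC content
#'
#' The standard null curve `ENCexp = 2 + s + 29 / (s^2 + (1 - s)^2)`, where
#' `s` is the silent-site (third-position) GC fraction. The curve attains its
#' maximum of 60.5 at `s = 0.5` and falls to 31 / 32 at the compositional
#' extremes.
#'
#' @param gc3s Silent-site GC fraction(s) in \[0, 1\].
#' @return Expected ENC value(s).
#' @export
enc_expected <- function(gc3s) {
  if (any(!is.na(gc3s) & (gc3s < 0 | gc3s > 1))) {
    stop("gc3s must lie in [0, 1]")
  }
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC deviation ratio
#'
#' `(ENCexp - ENCobs) / ENCobs`: positive when a gene uses fewer effective
#' codons than its silent GC content predicts (i.e. extra bias beyond
#' composition).
#'
#' @param enc_exp Expected ENC value(s).
#' @param enc_obs Observed ENC value(s) (> 0).
#' @return Ratio value(s); may be negative.
#' @export
enc_ratio <- function(enc_exp, enc_obs) {
  stopifnot(all(is.na(enc_obs) | enc_obs > 0))
  (enc_exp - enc_obs) / enc_obs
}

#' Relative-adaptiveness weights for CAI from a reference gene set
#'
#' Reference counts are pooled; each codon's weight is its RSCU divided by
#' the maximum RSCU in its family. Codons unobserved in the reference are
#' floored at 0.01 so that genes using them are penalized rather than
#' undefined.
#'
#' @param reference A list of `codon_counts` (or one pooled `codon_counts`).
#' @param description Free-text provenance of the reference set.
#' @return A `cai_weights` object: named weight vector over sense codons of
#'   multi-codon families, plus the description.
#' @export
derive_cai_weights <- function(reference, description = "pooled reference set") {
  pooled <- if (inherits(reference, "codon_counts")) reference
            else pool_counts(reference)
  if (pooled$n_codons == 0L) stop("reference set contains no sense codons")
  rs <- rscu(pooled)
  rs <- rs[rs$family_size >= 2L, ]
  fam_max <- tapply(rs$rscu, rs$aa, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  })
  w <- rs$rscu / as.numeric(fam_max[rs$aa])
  w[is.na(w) | w < 0.01] <- 0.01
  structure(list(
    w = stats::setNames(w, rs$codon),
    transl_table = pooled$transl_table,
    description = description
  ), class = "cai_weights")
}

#' Codon adaptation index
#'
#' Geometric mean of relative-adaptiveness weights over a gene's sense
#' codons, excluding single-codon families (Met/Trp under the standard code)
#' and stops.
#'
#' @param t A `codon_counts` object.
#' @param weights A [derive_cai_weights()] result.
#' @return CAI in (0, 1\], or `NA` (with a warning) if the gene has no
#'   eligible codons.
#' @export
cai <- function(t, weights) {
  stopifnot(inherits(t, "codon_counts"), inherits(weights, "cai_weights"))
  cnt <- t$counts[names(weights$w)]
  n <- sum(cnt)
  if (n == 0L) {
    warning("no CAI-eligible codons in gene")
    return(NA_real_)
  }
  exp(sum(cnt * log(weights$w)) / n)
}

#' Protein-level indices: Gravy and Aromo
#'
#' Gravy is the mean Kyte-Doolittle hydropathy of the translated protein
#' (terminal stop excluded); Aromo is the fraction of aromatic residues
#' (Phe, Tyr, Trp). Codons containing N are skipped.
#'
#' @param sequence A DNA string (length divisible by 3) or single-row
#'   [cds_set()].
#' @param transl_table NCBI genetic-code number.
#' @return Named vector `gravy`, `aromo`.
#' @export
protein_indices <- function(sequence, transl_table = 1L) {
  if (is.data.frame(sequence)) {
    transl_table <- sequence$transl_table[1]
    sequence <- sequence$sequence[1]
  }
  code <- genetic_code(transl_table)
  cods <- split_codons(sequence)
  cods <- cods[!grepl("N", cods, fixed = TRUE)]
  aa <- code[cods]
  aa <- aa[!is.na(aa) & aa != "*"]
  if (length(aa) == 0L) return(c(gravy = NA_real_, aromo = NA_real_))
  c(gravy = mean(KYTE_DOOLITTLE[aa]), aromo = mean(aa %in% AROMATIC_AA))
}

#' Per-gene metrics table
#'
#' Computes the full index vector for every gene of a CDS set: length in
#' codons, positional GC content, silent-site composition, observed and
#' expected ENC with the deviation ratio, CAI, Gravy and Aromo.
#'
#' If no CAI weights are supplied they are derived from the pooled counts of
#' the `cai_reference_fraction` of genes with the lowest observed ENC (a
#' reproducible proxy for a highly expressed reference set); with fewer than
#' 10 genes the whole set is pooled.
#'
#' @param seqs A [cds_set()] of screened sequences.
#' @param cai_weights Optional [derive_cai_weights()] result.
#' @param cai_reference_fraction Fraction of lowest-ENC genes used as the
#'   CAI reference when `cai_weights` is `NULL`.
#' @return A `gene_metrics` data.frame, one row per gene.
#' @export
gene_metrics <- function(seqs, cai_weights = NULL, cai_reference_fraction = 0.05) {
  stopifnot(nrow(seqs) >= 1L)
  counts <- lapply(seq_len(nrow(seqs)), function(i) count_codons(seqs[i, ]))
  comp <- t(vapply(counts, base_composition, numeric(5)))
  sil <- t(vapply(counts, silent_composition, numeric(5)))
  enc <- vapply(counts, enc_observed, numeric(1))
  prot <- t(vapply(seq_len(nrow(seqs)), function(i) {
    protein_indices(seqs[i, ])
  }, numeric(2)))

  if (is.null(cai_weights)) {
    ord <- order(enc, seqs$id)
    n_ref <- if (nrow(seqs) < 10L) nrow(seqs)
             else max(2L, ceiling(cai_reference_fraction * nrow(seqs)))
    ref <- ord[seq_len(n_ref)]
    ref <- ref[!is.na(enc[ref])]
    if (length(ref) == 0L) ref <- seq_len(nrow(seqs))
    cai_weights <- derive_cai_weights(
      counts[ref],
      description = sprintf("lowest-ENC %d/%d genes", length(ref), nrow(seqs)))
  }
  cai_v <- vapply(counts, cai, numeric(1), weights = cai_weights)

  out <- data.frame(
    id = seqs$id,
    organism = seqs$organism,
    compartment = seqs$compartment,
    length_codons = vapply(counts, function(x) x$n_codons, integer(1)),
    gc = comp[, "gc"], gc1 = comp[, "gc1"], gc2 = comp[, "gc2"],
    gc3 = comp[, "gc3"], gc12 = comp[, "gc12"],
    gc3s = sil[, "gc3s"], a3s = sil[, "a3s"], t3s = sil[, "t3s"],
    c3s = sil[, "c3s"], g3s = sil[, "g3s"],
    enc_obs = enc,
    enc_exp = enc_expected(sil[, "gc3s"]),
    gravy = prot[, "gravy"], aromo = prot[, "aromo"],
    cai = cai_v,
    stringsAsFactors = FALSE
  )
  out$enc_ratio <- enc_ratio(out$enc_exp, out$enc_obs)
  attr(out, "cai_weights") <- cai_weights
  class(out) <- c("gene_metrics", "data.frame")
  out
}

#' Write gene metrics as a TSV with the conventional column set
#'
#' @param metrics A [gene_metrics()] table.
#' @param path Output TSV path.
#' @export
write_gene_metrics <- function(metrics, path) {
  cols <- c("id", "length_codons", "gc", "gc1", "gc2", "gc3", "gc12", "gc3s",
            "t3s", "c3s", "a3s", "g3s", "gravy", "aromo", "enc_obs",
            "enc_exp", "enc_ratio", "cai")
  utils::write.table(metrics[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
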