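# Optimal-codon identification: the per-amino-acid maximum-RSCU rule and the
# delta-RSCU contrast between pooled high- and low-expression gene sets
# (observed ENC serving as the expression proxy).

#' Split genes into high/low expression groups by an ENC proxy
#'
#' High expression = the `fraction` of genes with the *lowest* observed ENC
#' (strong codon bias), low expression = the `fraction` with the highest.
#' Ties are broken deterministically by gene id.
#'
#' @param metrics A [gene_metrics()] table with at least 10 genes.
#' @param fraction Tail fraction per group (default 0.10).
#' @return An `expression_groups` list: `high`, `low` (gene id vectors),
#'   `criterion`, `fraction`.
#' @export
select_expression_groups <- function(metrics, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 0.5)
  ok <- !is.na(metrics$enc_obs)
  m <- metrics[ok, ]
  if (nrow(m) < 10L) stop("need at least 10 genes with defined ENC")
  if (stats::sd(m$enc_obs) == 0) {
    warning("all genes have equal ENC; groups filled by id order")
  }
  n_tail <- max(1L, floor(fraction * nrow(m)))
  ord <- order(m$enc_obs, m$id)
  structure(list(
    high = m$id[ord[seq_len(n_tail)]],
    low = m$id[rev(ord)[seq_len(n_tail)]],
    criterion = "observed ENC extremes (low ENC = high expression proxy)",
    fraction = fraction
  ), class = "expression_groups")
}

#' Optimal codons by the delta-RSCU contrast
#'
#' RSCU is computed on the pooled counts of the high- and low-expression
#' groups; `delta_rscu = rscu_high - rscu_low`. A codon is flagged optimal
#' when `delta_rscu >= min_delta` and (if `require_high_pref`)
#' `rscu_high > 1`. Families absent from either pool are marked
#' non-evaluable and never flagged.
#'
#' @param high_counts Pooled `codon_counts` of the high-expression group.
#' @param low_counts Pooled `codon_counts` of the low-expression group.
#' @param min_delta Minimum delta-RSCU to call a codon optimal
#'   (default 0.08).
#' @param require_high_pref Additionally require `rscu_high > 1`
#'   (default `TRUE`).
#' @return An `optimal_codon_report` data.frame: `aa`, `codon`,
#'   `rscu_high`, `rscu_low`, `delta_rscu`, `evaluable`, `optimal`.
#' @export
delta_rscu_call <- function(high_counts, low_counts, min_delta = 0.08,
                            require_high_pref = TRUE) {
  stopifnot(inherits(high_counts, "codon_counts"),
            inherits(low_counts, "codon_counts"),
            high_counts$n_codons > 0, low_counts$n_codons > 0,
            high_counts$transl_table == low_counts$transl_table)
  hi <- rscu(high_counts)
  lo <- rscu(low_counts)
  out <- data.frame(
    aa = hi$aa, codon = hi$codon, family_size = hi$family_size,
    rscu_high = hi$rscu, rscu_low = lo$rscu,
    stringsAsFactors = FALSE
  )
  out <- out[out$family_size >= 2L, ]
  out$delta_rscu <- out$rscu_high - out$rscu_low
  out$evaluable <- !is.na(out$delta_rscu)
  out$optimal <- out$evaluable & out$delta_rscu >= min_delta &
    (!require_high_pref | out$rscu_high > 1)
  out <- out[order(out$aa, out$codon), ]
  rownames(out) <- NULL
  class(out) <- c("optimal_codon_report", "data.frame")
  attr(out, "min_delta") <- min_delta
  out
}

#' Optimal codons by maximum RSCU within each family
#'
#' For every observed multi-codon family the codon(s) with maximal RSCU are
#' flagged; exact ties are reported as co-optimal. Single-codon families are
#' excluded.
#'
#' @param pooled A pooled `codon_counts` object.
#' @return data.frame `aa`, `codon`, `rscu`, `optimal`, `tie`.
#' @export
max_rscu_call <- function(pooled) {
  stopifnot(inherits(pooled, "codon_counts"), pooled$n_codons > 0)
  rs <- rscu(pooled)
  rs <- rs[rs$family_size >= 2L & !is.na(rs$rscu), ]
  out <- do.call(rbind, lapply(split(rs, rs$aa), function(f) {
    mx <- max(f$rscu)
    f$optimal <- f$rscu == mx
    f$tie <- sum(f$rscu == mx) > 1L
    f
  }))
  out <- out[order(out$aa, out$codon), c("aa", "codon", "rscu", "optimal", "tie")]
  rownames(out) <- NULL
  out
}

#' Third-position base composition of the optimal codons
#'
#' @param report An [delta_rscu_call()] or [max_rscu_call()] result (any
#'   data.frame with `codon` and a logical `optimal` column).
#' @return Named integer vector of counts of optimal codons ending in
#'   A, T, G, C (total = number of optimal codons).
#' @export
summarize_endings <- function(report) {
  stopifnot(is.data.frame(report), all(c("codon", "optimal") %in% names(report)))
  opt <- report$codon[report$optimal %in% TRUE]
  third <- substr(opt, 3L, 3L)
  vapply(c(A = "A", T = "T", G = "G", C = "C"),
         function(b) sum(third == b), integer(1))
}

#' End-to-end optimal-codon identification for a CDS set
#'
#' Computes gene metrics (unless supplied), selects ENC-extreme expression
#' groups, pools counts per group, and runs both the delta-RSCU and the
#' maximum-RSCU calls.
#'
#' @param seqs A [cds_set()].
#' @param metrics Optional precomputed [gene_metrics()].
#' @param fraction Tail fraction per expression group.
#' @param min_delta Delta-RSCU optimality threshold.
#' @param require_high_pref Require `rscu_high > 1`.
#' @return List with `groups`, `delta_report`, `max_report`, `endings`
#'   (third-base counts of delta-RSCU optimal codons).
#' @export
optimal_codons <- function(seqs, metrics = NULL, fraction = 0.10,
                           min_delta = 0.08, require_high_pref = TRUE) {
  if (is.null(metrics)) metrics <- gene_metrics(seqs)
  groups <- select_expression_groups(metrics, fraction)
  hi <- pool_counts(lapply(which(seqs$id %in% groups$high),
                           function(i) count_codons(seqs[i, ])))
  lo <- pool_counts(lapply(which(seqs$id %in% groups$low),
                           function(i) count_codons(seqs[i, ])))
  delta <- delta_rscu_call(hi, lo, min_delta = min_delta,
                           require_high_pref = require_high_pref)
  all_pool <- pool_counts(lapply(seq_len(nrow(seqs)),
                                 function(i) count_codons(seqs[i, ])))
  list(
    groups = groups,
    delta_report = delta,
    max_report = max_rscu_call(all_pool),
    endings = summarize_endings(delta)
  )
}
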