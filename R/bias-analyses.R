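# The three diagnostic analyses: neutrality regression (GC12 on GC3),
# ENC-GC3 analysis with the deviation-ratio histogram, and the PR2 parity
# plot coordinates.

#' Neutrality regression of GC12 on third-position GC
#'
#' Ordinary least squares of `gc12` on `gc3` (or `gc3s`). A slope near 1 is
#' read as mutation-dominated codon usage (all three positions share one
#' compositional process); a slope near 0 as selection-dominated (third
#' position varies while the first two are constrained).
#'
#' @param metrics A [gene_metrics()] table.
#' @param x_choice Abscissa: `"gc3"` (default) or `"gc3s"`.
#' @return A `neutrality_fit`: list with `slope`, `intercept`, `r`, `p`,
#'   `n`, `x_choice`, and the fitted points (`data`).
#' @export
neutrality_regression <- function(metrics, x_choice = c("gc3", "gc3s")) {
  x_choice <- match.arg(x_choice)
  x <- metrics[[x_choice]]
  y <- metrics$gc12
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete (x, gc12) pairs")
  if (stats::sd(x) == 0) {
    warning("zero variance in ", x_choice, "; slope undefined")
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r = NA_real_, p = NA_real_, n = length(x),
                          x_choice = x_choice,
                          data = data.frame(x = x, gc12 = y)),
                     class = "neutrality_fit"))
  }
  fit <- stats::lm(y ~ x)
  ct <- if (stats::sd(y) == 0) list(estimate = 0, p.value = NA_real_)
        else stats::cor.test(x, y)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = unname(ct$estimate),
    p = ct$p.value,
    n = length(x),
    x_choice = x_choice,
    data = data.frame(x = x, gc12 = y)
  ), class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat("<neutrality_fit> gc12 ~ ", x$x_choice, "  (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  slope = %.4f  intercept = %.4f  r = %.4f  p = %.3g\n",
              x$slope, x$intercept, x$r, x$p))
  invisible(x)
}

#' ENC-GC3 analysis with deviation-ratio histogram
#'
#' For every gene with a defined observed ENC, computes the expected ENC from
#' its silent GC content, the deviation ratio `(ENCexp - ENCobs) / ENCobs`,
#' and a fixed-width histogram of the ratios (left-closed, right-open bins
#' aligned to multiples of `bin_width`, starting at the floor of the
#' minimum).
#'
#' @param metrics A [gene_metrics()] table.
#' @param bin_width Histogram bin width (default 0.05).
#' @return List with `genes` (id, gc3s, enc_obs, enc_exp, enc_ratio),
#'   `histogram` (bin_left, bin_right, count) and `n_excluded` (genes with
#'   undefined ENC or silent composition).
#' @export
enc_gc3_analysis <- function(metrics, bin_width = 0.05) {
  stopifnot(bin_width > 0)
  keep <- stats::complete.cases(metrics$gc3s, metrics$enc_obs)
  genes <- data.frame(
    id = metrics$id[keep],
    gc3s = metrics$gc3s[keep],
    enc_obs = metrics$enc_obs[keep],
    stringsAsFactors = FALSE
  )
  genes$enc_exp <- enc_expected(genes$gc3s)
  genes$enc_ratio <- enc_ratio(genes$enc_exp, genes$enc_obs)

  if (nrow(genes) == 0L) {
    hist <- data.frame(bin_left = numeric(0), bin_right = numeric(0),
                       count = integer(0))
  } else {
    lo <- floor(min(genes$enc_ratio) / bin_width) * bin_width
    hi <- max(genes$enc_ratio)
    edges <- seq(lo, hi + bin_width, by = bin_width)
    idx <- findInterval(genes$enc_ratio, edges, rightmost.closed = FALSE)
    hist <- data.frame(
      bin_left = edges[seq_len(length(edges) - 1L)],
      bin_right = edges[-1L],
      count = as.integer(tabulate(idx, nbins = length(edges) - 1L))
    )
  }
  list(genes = genes, histogram = hist, n_excluded = sum(!keep))
}

#' PR2 parity-plot coordinates for one gene
#'
#' Third-position base counts are restricted to the selected scope and the
#' parity coordinates returned: `x = G3 / (G3 + C3)`,
#' `y = A3 / (A3 + T3)`. Under strand-symmetric mutation with no selection
#' both coordinates centre on 0.5.
#'
#' @param t A `codon_counts` object.
#' @param scope `"synonymous_third"` (third positions of all synonymously
#'   variable codons; default) or `"fourfold_only"` (codons of 4-fold
#'   degenerate families only, the classical choice).
#' @return Named vector `x`, `y`; a coordinate is `NA` if its denominator
#'   is zero.
#' @export
pr2_coordinates <- function(t, scope = c("synonymous_third", "fourfold_only")) {
  scope <- match.arg(scope)
  stopifnot(inherits(t, "codon_counts"))
  fam <- codon_families(t$transl_table)
  sel <- if (scope == "fourfold_only") fam$family_size == 4L
         else fam$family_size >= 2L
  cods <- fam$codon[sel]
  cnt <- t$counts[cods]
  third <- substr(cods, 3L, 3L)
  b <- vapply(BASES, function(x) sum(cnt[third == x]), numeric(1))
  x <- if (b[["G"]] + b[["C"]] > 0) b[["G"]] / (b[["G"]] + b[["C"]]) else NA_real_
  y <- if (b[["A"]] + b[["T"]] > 0) b[["A"]] / (b[["A"]] + b[["T"]]) else NA_real_
  c(x = x, y = y)
}

#' PR2 coordinates for every gene of a CDS set
#'
#' @param seqs A [cds_set()].
#' @inheritParams pr2_coordinates
#' @return data.frame with `id`, `x`, `y`.
#' @export
pr2_table <- function(seqs, scope = c("synonymous_third", "fourfold_only")) {
  scope <- match.arg(scope)
  xy <- t(vapply(seq_len(nrow(seqs)), function(i) {
    pr2_coordinates(count_codons(seqs[i, ]), scope = scope)
  }, numeric(2)))
  data.frame(id = seqs$id, x = xy[, "x"], y = xy[, "y"],
             stringsAsFactors = FALSE)
}
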