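# Correspondence analysis of the gene x codon RSCU (or count) matrix, and
# the all-pairs correlation matrix with significance stars.

#' Gene-by-codon RSCU matrix for correspondence analysis
#'
#' Rows are genes, columns the synonymously variable sense codons of the
#' active code (59 under the standard code). Families a gene never uses have
#' undefined RSCU; for ordination those entries are imputed at the no-bias
#' value 1 (optionally left `NA`).
#'
#' @param seqs A [cds_set()].
#' @param impute Impute unobserved-family RSCU at 1 (default `TRUE`).
#' @return Numeric matrix, rownames gene ids, colnames codons.
#' @export
rscu_matrix <- function(seqs, impute = TRUE) {
  stopifnot(nrow(seqs) >= 1L)
  tt <- seqs$transl_table[1]
  fam <- codon_families(tt)
  syn <- fam$codon[fam$family_size >= 2L]
  m <- t(vapply(seq_len(nrow(seqs)), function(i) {
    rs <- rscu(count_codons(seqs[i, ]))
    stats::setNames(rs$rscu, rs$codon)[syn]
  }, numeric(length(syn))))
  rownames(m) <- seqs$id
  colnames(m) <- syn
  if (impute) m[is.na(m)] <- 1
  m
}

#' Correspondence analysis of a non-negative matrix
#'
#' Chi-square-metric ordination: the matrix of standardized residuals
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` (with `P` the matrix scaled to unit
#' total, `r`, `c` its margins) is decomposed by singular values, and row and
#' column *principal* coordinates are returned. Axes are ordered by
#' decreasing inertia; each axis's sign is fixed so that the largest-
#' magnitude column loading is positive.
#'
#' @param m Numeric matrix, all entries >= 0, at least 2 rows and columns,
#'   no all-zero row or column.
#' @param n_axes Number of axes to return (default all).
#' @return A `coa` object: `row_coords`, `col_coords` (matrices),
#'   `singular_values`, `inertia` (per-axis fractions), `row_mass`,
#'   `col_mass`.
#' @export
correspondence_analysis <- function(m, n_axes = NULL) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 2L, ncol(m) >= 2L, all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("matrix has an all-zero row or column; filter before ordination")
  }
  P <- m / sum(m)
  r <- rowSums(P)
  c_ <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, c_)) %*% diag(1 / sqrt(c_))
  sv <- svd(S)
  pos <- sv$d > max(sv$d[1], 1) * 1e-12
  if (!any(pos)) {
    k <- 0L
  } else {
    k <- sum(pos)
  }
  if (!is.null(n_axes)) k <- min(k, n_axes)
  if (k == 0L) {
    return(structure(list(
      row_coords = matrix(0, nrow(m), 0, dimnames = list(rownames(m), NULL)),
      col_coords = matrix(0, ncol(m), 0, dimnames = list(colnames(m), NULL)),
      singular_values = numeric(0), inertia = numeric(0),
      row_mass = r, col_mass = c_), class = "coa"))
  }
  d <- sv$d[seq_len(k)]
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|.| column loading positive on each axis
  for (a in seq_len(k)) {
    top <- which.max(abs(V[, a]))
    if (V[top, a] < 0) {
      V[, a] <- -V[, a]
      U[, a] <- -U[, a]
    }
  }
  F_ <- diag(1 / sqrt(r)) %*% U %*% diag(d, k, k)
  G_ <- diag(1 / sqrt(c_)) %*% V %*% diag(d, k, k)
  dimnames(F_) <- list(rownames(m), paste0("Axis", seq_len(k)))
  dimnames(G_) <- list(colnames(m), paste0("Axis", seq_len(k)))
  structure(list(
    row_coords = F_,
    col_coords = G_,
    singular_values = d,
    inertia = d^2 / sum(sv$d^2),
    row_mass = r,
    col_mass = c_
  ), class = "coa")
}

#' @export
print.coa <- function(x, ...) {
  cat("<coa> ", nrow(x$row_coords), " rows x ", nrow(x$col_coords),
      " columns, ", length(x$singular_values), " axes\n", sep = "")
  if (length(x$inertia)) {
    cat("  inertia fractions:",
        paste(sprintf("%.3f", utils::head(x$inertia, 5)), collapse = " "), "\n")
  }
  invisible(x)
}

#' All-pairs correlation matrix with significance stars
#'
#' Pairwise correlations (Pearson by default) between the chosen metric
#' columns, with two-sided p-values and star flags at 0.05 (`*`) and 0.01
#' (`**`). Missing values are handled pairwise-complete. Constant variables
#' yield `NA` correlations with a warning.
#'
#' @param metrics A [gene_metrics()] table (or any data.frame).
#' @param variables Column names to correlate.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param adjust P-value adjustment method (`"none"` default, or any
#'   [stats::p.adjust()] method such as `"holm"`), applied to the
#'   lower-triangle p-values.
#' @return A `correlation_matrix`: list with `r`, `p`, `stars` matrices and
#'   `method`.
#' @export
correlation_matrix <- function(metrics, variables,
                               method = c("pearson", "spearman"),
                               adjust = "none") {
  method <- match.arg(method)
  stopifnot(all(variables %in% names(metrics)))
  x <- as.data.frame(metrics)[, variables, drop = FALSE]
  k <- length(variables)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(x[[i]], x[[j]])
      if (sum(ok) < 3L) next
      xi <- x[[i]][ok]; xj <- x[[j]][ok]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
        warning("constant variable in pair (", variables[i], ", ",
                variables[j], "); correlation undefined")
        next
      }
      ct <- suppressWarnings(stats::cor.test(xi, xj, method = method))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  if (adjust != "none") {
    lower <- lower.tri(p)
    p[lower] <- stats::p.adjust(p[lower], method = adjust)
    p[upper.tri(p)] <- t(p)[upper.tri(p)]
  }
  stars <- matrix("", k, k, dimnames = list(variables, variables))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  diag(stars) <- ""
  structure(list(r = r, p = p, stars = stars, method = method),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  k <- ncol(x$r)
  vars <- colnames(x$r)
  cat("<correlation_matrix> method:", x$method, "\n")
  body <- matrix("", k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j >= i) next
    body[i, j] <- if (is.na(x$r[i, j])) "NA"
                  else paste0(format(round(x$r[i, j], digits), nsmall = digits),
                              " ", x$stars[i, j])
  }
  print(as.data.frame(body[-1, -k, drop = FALSE]), right = TRUE)
  cat("**: p < 0.01  *: p < 0.05\n")
  invisible(x)
}

#' Write a correlation matrix as TSV in lower-triangle table form
#' @param x A [correlation_matrix()] result.
#' @param path Output TSV path.
#' @export
write_correlation_matrix <- function(x, path) {
  k <- ncol(x$r)
  vars <- colnames(x$r)
  body <- matrix("", k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j >= i) next
    body[i, j] <- if (is.na(x$r[i, j])) "NA"
                  else paste0(format(round(x$r[i, j], 3), nsmall = 3),
                              ifelse(x$stars[i, j] == "", "",
                                     paste0(" ", x$stars[i, j])))
  }
  df <- data.frame(variable = vars[-1], body[-1, -k, drop = FALSE],
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
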