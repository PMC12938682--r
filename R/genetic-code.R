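# Genetic-code helpers shared by every module. Codon tables come from
# Biostrings::getGeneticCode(); degeneracy structure is always recomputed
# from the active code so that mitochondrial codes (e.g. NCBI tables 4 and 5)
# get the correct family sizes rather than the standard-code 2/3/4/6 split.

BASES <- c("A", "C", "G", "T")

#' All 64 codons in fixed lexicographic order
#' @keywords internal
all_codons <- function() {
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
}

#' Codon-to-amino-acid map for an NCBI genetic code
#'
#' @param transl_table NCBI genetic-code number (1 = standard, 4 = mold
#'   mitochondrial, 5 = invertebrate mitochondrial, ...).
#' @return Named character vector over the 64 codons; stops are `"*"`.
#' @export
genetic_code <- function(transl_table = 1L) {
  code <- Biostrings::getGeneticCode(as.character(transl_table))
  code[sort(names(code))][all_codons()]
}

#' Synonymous-family table for a genetic code
#'
#' One row per sense codon with its amino acid and the size of its
#' synonymous family (degeneracy) under the active code.
#'
#' @inheritParams genetic_code
#' @return data.frame with columns `codon`, `aa`, `family_size`.
#' @export
codon_families <- function(transl_table = 1L) {
  code <- genetic_code(transl_table)
  sense <- code[code != "*"]
  fam_size <- table(sense)
  data.frame(
    codon = names(sense),
    aa = unname(sense),
    family_size = as.integer(fam_size[sense]),
    stringsAsFactors = FALSE
  )
}

#' Stop codons of a genetic code
#' @inheritParams genetic_code
#' @return Character vector of stop codons.
#' @export
stop_codons <- function(transl_table = 1L) {
  code <- genetic_code(transl_table)
  names(code)[code == "*"]
}

# Kyte-Doolittle hydropathy values, one per amino acid (one-letter code).
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

AROMATIC_AA <- c("F", "Y", "W")

#' Reverse complement of a DNA string
#' @keywords internal
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Split a CDS string into frame-0 codons
#' @keywords internal
split_codons <- function(sequence) {
  n <- nchar(sequence)
  if (n %% 3L != 0L) {
    stop("sequence length (", n, ") is not a multiple of 3")
  }
  if (n == 0L) return(character(0))
  substring(sequence, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}
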