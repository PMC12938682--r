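# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Build a CDS string from sense codons, with ATG start and TAA stop.
make_cds <- function(codons, start = TRUE, stop_codon = "TAA") {
  paste0(if (start) "ATG" else "", paste(codons, collapse = ""), stop_codon)
}

# A screening-clean CDS of n_codons sense codons (>= 100 for the default
# length rule), built from a repeated codon block free of stops.
clean_cds <- function(n_codons = 100, block = c("AAA", "TTT", "GGC", "CTC")) {
  make_cds(rep(block, length.out = n_codons))
}

# Write a small multi-feature GenBank flat file and return its path.
# Record: 60 bp; three CDS (forward, complement, join), /transl_table=5 on
# the second.
toy_genbank <- function(path = tempfile(fileext = ".gb")) {
  genome <- paste0(
    "ATGAAATTTGGGTAA",           # 1..15   forward CDS
    "TTACCCAAATTTCAT",           # 16..30  revcomp = ATGAAATTTGGGTAA
    "ATGCCCAAAGGGTAA",           # 31..45  join(31..36,37..45)
    "ACGTACGTACGTACG"            # filler to 60
  )
  stopifnot(nchar(genome) == 60)
  seq_lines <- paste0("        1 ", tolower(paste(
    substring(genome, seq(1, 51, 10), seq(10, 60, 10)), collapse = " ")))
  lines <- c(
    "LOCUS       TOYREC                 60 bp    DNA     circular     01-JAN-2026",
    "DEFINITION  synthetic toy record for parser tests.",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "                     /organism=\"Toyus exampleus\"",
    "     CDS             1..15",
    "                     /gene=\"fwd1\"",
    "     CDS             complement(16..30)",
    "                     /gene=\"rev1\"",
    "                     /transl_table=5",
    "     CDS             join(31..36,37..45)",
    "                     /gene=\"join1\"",
    "ORIGIN",
    seq_lines,
    "//"
  )
  writeLines(lines, path)
  path
}

# Random codon count table over the sense codons of a code.
random_count_table <- function(transl_table = 1, lambda = 4) {
  fam <- codon_families(transl_table)
  codon_counts(stats::setNames(stats::rpois(nrow(fam), lambda), fam$codon),
               transl_table)
}

# Independent brute-force of Wright's ENC, written against the formulas
# directly (data.frame aggregation path, no shared code with enc_observed).
enc_brute_force <- function(t) {
  code <- Biostrings::getGeneticCode(as.character(t$transl_table))
  df <- data.frame(codon = names(code), aa = unname(code))
  df <- df[df$aa != "*", ]
  df$n <- as.numeric(t$counts[df$codon])
  fam_sizes <- tapply(df$codon, df$aa, length)

  per_aa <- lapply(split(df, df$aa), function(f) {
    n <- sum(f$n)
    k <- nrow(f)
    if (k == 1 || n < 2) return(NULL)
    FF <- (n * sum((f$n / n)^2) - 1) / (n - 1)
    data.frame(k = k, FF = FF)
  })
  est <- do.call(rbind, per_aa)
  if (is.null(est)) return(NA_real_)
  est <- est[est$FF > 0, , drop = FALSE]
  fbar <- tapply(est$FF, est$k, mean)

  n_single <- sum(fam_sizes == 1)
  classes <- table(fam_sizes[fam_sizes > 1])
  need <- names(classes)
  if (!("3" %in% names(fbar)) && "3" %in% need &&
      all(c("2", "4") %in% names(fbar))) {
    fbar <- c(fbar, "3" = unname((fbar[["2"]] + fbar[["4"]]) / 2))
  }
  if (!all(need %in% names(fbar)) || length(fbar) < 2) return(NA_real_)
  enc <- n_single + sum(as.numeric(classes[need]) / unlist(fbar[need]))
  max(length(fam_sizes), min(enc, sum(fam_sizes)))
}
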