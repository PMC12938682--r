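# CDS screening: the four quality rules applied in fixed order, with the
# first failing rule recorded as a sequence's rejection reason, followed by
# greedy redundancy removal at a global-alignment identity threshold.

#' Screening configuration
#'
#' @param min_length_nt Minimum CDS length in nucleotides (inclusive).
#' @param identity_threshold Pairwise identity above which the shorter of two
#'   sequences is considered redundant; fraction in (0, 1].
#' @param require_atg Require the first codon to be ATG.
#' @param require_terminal_stop Require the final codon to be a stop codon of
#'   the active genetic code.
#' @param max_n_fraction Maximum tolerated fraction of codons containing N.
#' @return A `screening_config` list.
#' @export
screening_config <- function(min_length_nt = 300L, identity_threshold = 0.95,
                             require_atg = TRUE, require_terminal_stop = TRUE,
                             max_n_fraction = 0.05) {
  stopifnot(min_length_nt >= 3L,
            identity_threshold > 0, identity_threshold <= 1,
            max_n_fraction >= 0, max_n_fraction <= 1)
  structure(list(min_length_nt = as.integer(min_length_nt),
                 identity_threshold = identity_threshold,
                 require_atg = isTRUE(require_atg),
                 require_terminal_stop = isTRUE(require_terminal_stop),
                 max_n_fraction = max_n_fraction),
            class = "screening_config")
}

#' Global-alignment pairwise identity between two sequences
#'
#' Needleman-Wunsch global alignment with match = 1, mismatch = 0 and a gap
#' cost of 1 per gap column (used for alignment only); identity is the number
#' of matching columns divided by the total number of alignment columns.
#'
#' @param a,b DNA strings (or single-row [cds_set()]s).
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  a <- if (is.data.frame(a)) a$sequence[1] else a
  b <- if (is.data.frame(b)) b$sequence[1] else b
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 1)
  p <- as.character(Biostrings::pattern(aln))
  s <- as.character(Biostrings::subject(aln))
  # alignment columns = aligned region (with internal gaps) plus end-gap
  # columns, which the aligned views trim
  end_gaps <- (nchar(a) - nchar(gsub("-", "", p))) +
    (nchar(b) - nchar(gsub("-", "", s)))
  Biostrings::nmatch(aln) / (nchar(p) + end_gaps)
}

#' Greedy redundancy removal at an identity threshold
#'
#' Sequences are visited in decreasing length (ties broken by lexicographic
#' id); each is kept unless its identity with an already-kept sequence
#' reaches the threshold. A conservative k-mer prefilter (applied only when
#' the threshold is at least 0.9) and a length-ratio bound skip alignments
#' that provably cannot reach the threshold.
#'
#' @param seqs A [cds_set()].
#' @param threshold Identity threshold in (0, 1].
#' @return The kept subset of `seqs` in original row order; attribute
#'   `"removed"` lists dropped ids.
#' @export
remove_redundant <- function(seqs, threshold = 0.95) {
  stopifnot(threshold > 0, threshold <= 1)
  n <- nrow(seqs)
  if (n <= 1L) {
    attr(seqs, "removed") <- character(0)
    return(seqs)
  }
  ord <- order(-nchar(seqs$sequence), seqs$id)
  kmers <- if (threshold >= 0.9) {
    lapply(seqs$sequence, function(s) {
      L <- nchar(s)
      if (L < 8L) return(s)
      unique(substring(s, 1:(L - 7L), 8:L))
    })
  } else NULL
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (j in kept) {
      len_i <- nchar(seqs$sequence[i]); len_j <- nchar(seqs$sequence[j])
      if (min(len_i, len_j) / max(len_i, len_j) < threshold) next
      if (!is.null(kmers)) {
        contain <- length(intersect(kmers[[i]], kmers[[j]])) /
          min(length(kmers[[i]]), length(kmers[[j]]))
        # identity >= t destroys at most 8*(1-t) of the shorter's k-mers
        if (contain < 1 - 8 * (1 - threshold) - 0.05) next
      }
      if (pairwise_identity(seqs$sequence[i], seqs$sequence[j]) >= threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, i)
  }
  removed <- seqs$id[setdiff(seq_len(n), kept)]
  out <- seqs[sort(kept), , drop = FALSE]
  class(out) <- c("cds_set", "data.frame")
  attr(out, "removed") <- removed
  out
}

#' Screen a CDS set with the four quality rules
#'
#' Rules are applied in order and the first failure is the recorded reason:
#' (1) starts with ATG; (2) length at least `min_length_nt`; (3) length
#' divisible by 3, no internal stop codon under the sequence's genetic code,
#' final codon a stop codon; (3b) at most `max_n_fraction` of codons contain
#' N; (4) redundancy removal at `identity_threshold`.
#'
#' @param seqs A [cds_set()].
#' @param config A [screening_config()].
#' @return List with `kept` (a [cds_set()]) and `report`
#'   (a `screening_report`: counts plus a per-rejection table).
#' @export
screen_cds <- function(seqs, config = screening_config()) {
  stopifnot(inherits(config, "screening_config"))
  n <- nrow(seqs)
  reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    s <- seqs$sequence[i]
    stops <- stop_codons(seqs$transl_table[i])
    if (config$require_atg && substr(s, 1L, 3L) != "ATG") {
      reason[i] <- "no_atg_start"; next
    }
    if (nchar(s) < config$min_length_nt) {
      reason[i] <- "too_short"; next
    }
    if (nchar(s) %% 3L != 0L) {
      reason[i] <- "bad_frame"; next
    }
    cods <- split_codons(s)
    internal <- cods[-length(cods)]
    if (any(internal %in% stops)) {
      reason[i] <- "internal_stop"; next
    }
    if (config$require_terminal_stop && !(cods[length(cods)] %in% stops)) {
      reason[i] <- "no_terminal_stop"; next
    }
    if (mean(grepl("N", cods, fixed = TRUE)) > config$max_n_fraction) {
      reason[i] <- "excess_n"; next
    }
  }

  pass <- which(is.na(reason))
  surv <- seqs[pass, , drop = FALSE]
  class(surv) <- c("cds_set", "data.frame")
  surv <- remove_redundant(surv, config$identity_threshold)
  redundant <- attr(surv, "removed")
  reason[seqs$id %in% redundant] <- "redundant"

  rejected <- data.frame(
    id = seqs$id[!is.na(reason)],
    length_nt = nchar(seqs$sequence[!is.na(reason)]),
    reason = reason[!is.na(reason)],
    stringsAsFactors = FALSE
  )
  report <- structure(list(
    n_input = n,
    n_kept = nrow(surv),
    rejected_per_rule = table(factor(rejected$reason, levels = c(
      "no_atg_start", "too_short", "bad_frame", "internal_stop",
      "no_terminal_stop", "excess_n", "redundant"))),
    rejected = rejected,
    config = config
  ), class = "screening_report")

  list(kept = surv, report = report)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report> input:", x$n_input, " kept:", x$n_kept, "\n")
  tab <- x$rejected_per_rule[x$rejected_per_rule > 0]
  if (length(tab)) {
    for (nm in names(tab)) cat("  rejected ", nm, ": ", tab[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' Write screening outputs: screened FASTA, rejection TSV and JSON summary
#'
#' @param screened Result of [screen_cds()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_screening_output <- function(screened, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "screened.fasta")
  tsv <- file.path(out_dir, "screening_rejections.tsv")
  js <- file.path(out_dir, "screening_summary.json")
  write_cds_fasta(screened$kept, fa)
  utils::write.table(screened$report$rejected, tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts <- as.list(screened$report$rejected_per_rule)
  summary <- c(list(n_input = screened$report$n_input,
                    n_kept = screened$report$n_kept), counts)
  writeLines(to_json(summary), js)
  invisible(c(fa, tsv, js))
}

# tiny JSON writer for flat named lists of scalars (avoids a hard jsonlite
# dependency in the package itself)
to_json <- function(x) {
  fields <- vapply(names(x), function(nm) {
    v <- x[[nm]]
    val <- if (is.character(v)) paste0("\"", v, "\"") else format(v, digits = 15)
    paste0("\"", nm, "\": ", val)
  }, character(1))
  paste0("{", paste(fields, collapse = ", "), "}")
}
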