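# The cds_set container: one row per coding sequence, with the organism /
# compartment labels and genetic-code assignment the downstream indices need.

#' Construct a set of coding sequences
#'
#' The atomic analysis unit of the package: a data.frame with one row per
#' CDS carrying the nucleotide string, organism and compartment labels, and
#' the NCBI genetic-code number used for translation-dependent indices.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Upper-case DNA strings over `{A,C,G,T,N}`.
#' @param organism Organism label (recycled).
#' @param compartment `"nuclear"` or `"mitochondrial"` (recycled).
#' @param transl_table NCBI genetic-code number (recycled).
#' @return A `cds_set` (data.frame subclass).
#' @export
cds_set <- function(id, sequence, organism = "unknown",
                    compartment = c("nuclear", "mitochondrial"),
                    transl_table = 1L) {
  compartment <- match.arg(compartment)
  sequence <- toupper(sequence)
  sequence <- gsub("U", "T", sequence, fixed = TRUE)
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) {
    stop("sequences contain characters outside {A,C,G,T,N}: ",
         paste(utils::head(id[bad], 3), collapse = ", "))
  }
  if (any(nchar(sequence) < 3L)) {
    stop("all coding sequences must have length >= 3")
  }
  out <- data.frame(
    id = as.character(id),
    sequence = sequence,
    organism = rep_len(organism, length(id)),
    compartment = rep_len(compartment, length(id)),
    transl_table = rep_len(as.integer(transl_table), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cds_set", "data.frame")
  out
}

#' @export
print.cds_set <- function(x, ...) {
  cat("<cds_set> ", nrow(x), " sequence(s)\n", sep = "")
  if (nrow(x) > 0) {
    cat("  organisms:   ", paste(unique(x$organism), collapse = ", "), "\n")
    cat("  compartment: ", paste(unique(x$compartment), collapse = ", "), "\n")
    cat("  length range (nt): ", min(nchar(x$sequence)), "-",
        max(nchar(x$sequence)), "\n", sep = "")
  }
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' Records are upper-cased and RNA `U` mapped to `T`. Records containing
#' characters outside `{A,C,G,T,N}` are dropped with a warning and listed in
#' the `"invalid_records"` attribute of the result rather than silently kept.
#'
#' @param path FASTA file (one record per CDS).
#' @inheritParams cds_set
#' @return A [cds_set()]; attribute `"invalid_records"` holds ids of records
#'   rejected for bad characters.
#' @export
read_cds_fasta <- function(path, organism = "unknown",
                           compartment = c("nuclear", "mitochondrial"),
                           transl_table = 1L) {
  compartment <- match.arg(compartment)
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  has_records <- any(startsWith(readLines(path, warn = FALSE), ">"))
  recs <- if (has_records) {
    seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                       forceDNAtolower = FALSE)
  } else list()
  if (length(recs) == 0L) {
    warning("FASTA file contains no records: ", path)
    out <- cds_set(character(0), character(0), organism, compartment,
                   transl_table)
    attr(out, "invalid_records") <- character(0)
    return(out)
  }
  ids <- names(recs)
  seqs <- toupper(vapply(recs, as.character, character(1)))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  ok <- !grepl("[^ACGTN]", seqs) & nchar(seqs) >= 3L
  if (any(!ok)) {
    warning(sum(!ok), " record(s) rejected (non-ACGTN characters or length < 3): ",
            paste(utils::head(ids[!ok], 5), collapse = ", "))
  }
  out <- cds_set(ids[ok], seqs[ok], organism, compartment, transl_table)
  attr(out, "invalid_records") <- ids[!ok]
  out
}

#' Write a cds_set to FASTA
#' @param x A [cds_set()].
#' @param path Output file.
#' @export
write_cds_fasta <- function(x, path) {
  seqinr::write.fasta(as.list(x$sequence), names = x$id, file.out = path,
                      nbchar = 70)
  invisible(path)
}
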