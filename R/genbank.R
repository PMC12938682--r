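# Minimal GenBank flat-file CDS extraction. Only what annotated organellar
# records need: multi-record files, join()/complement() locations, the
# /transl_table, /gene, /locus_tag and /product qualifiers, and the ORIGIN
# sequence block. Locations referring to other records (accession:from..to)
# and order() constructs are skipped with a warning.

#' Extract CDS features from a GenBank flat file
#'
#' Reads every record in a GenBank flat file, resolves each CDS feature's
#' location (including `join(...)` and `complement(...)`), and returns the
#' spliced, strand-corrected coding sequences. The genetic code is taken
#' from the feature's `/transl_table` qualifier unless overridden.
#'
#' @param path GenBank flat file.
#' @param transl_table_override Optional integer forcing the genetic code
#'   for every extracted CDS.
#' @param organism Organism label; defaults to the record's ORGANISM line.
#' @param compartment Compartment label for the resulting [cds_set()].
#' @return A [cds_set()]; empty (with a warning) if no CDS features exist.
#' @export
extract_cds_from_genbank <- function(path, transl_table_override = NULL,
                                     organism = NULL,
                                     compartment = c("mitochondrial", "nuclear")) {
  compartment <- match.arg(compartment)
  if (!file.exists(path)) stop("cannot read GenBank file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec_breaks <- c(0L, which(trimws(lines) == "//"))
  if (length(rec_breaks) == 1L) rec_breaks <- c(0L, length(lines))

  ids <- character(0); seqs <- character(0); tables <- integer(0)
  orgs <- character(0)

  for (r in seq_len(length(rec_breaks) - 1L)) {
    rec <- lines[(rec_breaks[r] + 1L):(rec_breaks[r + 1L] - 1L)]
    if (length(rec) == 0L) next
    locus <- sub("^LOCUS\\s+(\\S+).*$", "\\1", grep("^LOCUS", rec, value = TRUE)[1])
    org_line <- grep("^\\s+ORGANISM", rec, value = TRUE)
    rec_org <- if (length(org_line)) trimws(sub("^\\s+ORGANISM\\s+", "", org_line[1])) else "unknown"

    origin_at <- grep("^ORIGIN", rec)
    if (length(origin_at) == 0L) next
    seq_lines <- rec[(origin_at[1] + 1L):length(rec)]
    genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    genome <- gsub("U", "T", genome, fixed = TRUE)

    feat_at <- grep("^FEATURES", rec)
    if (length(feat_at) == 0L) next
    feat <- rec[(feat_at[1] + 1L):(origin_at[1] - 1L)]

    # feature keys start at column 6; qualifiers/continuations at column 22
    is_key <- grepl("^ {5}\\S", feat)
    key_idx <- which(is_key)
    key_names <- sub("^ {5}(\\S+).*$", "\\1", feat[key_idx])
    cds_k <- which(key_names == "CDS")

    for (k in cds_k) {
      start_line <- key_idx[k]
      end_line <- if (k == length(key_idx) && is.na(key_idx[k + 1])) length(feat) else NA
      nxt <- key_idx[key_idx > start_line]
      end_line <- if (length(nxt)) nxt[1] - 1L else length(feat)
      block <- feat[start_line:end_line]

      # location spans from the key line until the first /qualifier line
      qual_at <- grep("^\\s+/", block)
      loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(block)
      loc <- paste(trimws(sub("^ {5}CDS\\s*", "", block[1:loc_end])), collapse = "")

      quals <- block[if (length(qual_at)) qual_at[1]:length(block) else integer(0)]
      get_qual <- function(name) {
        ln <- grep(paste0("^\\s+/", name, "="), quals, value = TRUE)
        if (!length(ln)) return(NA_character_)
        gsub("\"", "", sub(paste0("^/", name, "="), "", trimws(ln[1])))
      }
      tt <- get_qual("transl_table")
      tt <- if (!is.null(transl_table_override)) as.integer(transl_table_override)
            else if (!is.na(tt)) as.integer(tt) else 1L
      id <- get_qual("gene")
      if (is.na(id)) id <- get_qual("locus_tag")
      if (is.na(id)) id <- get_qual("product")
      if (is.na(id)) id <- paste0(locus, "_CDS", k)

      sq <- tryCatch(resolve_location(loc, genome),
                     error = function(e) {
                       warning("skipping CDS '", id, "' in ", locus,
                               ": unresolvable location (", conditionMessage(e), ")")
                       NULL
                     })
      if (is.null(sq) || nchar(sq) < 3L) next
      ids <- c(ids, id); seqs <- c(seqs, sq); tables <- c(tables, tt)
      orgs <- c(orgs, rec_org)
    }
  }

  if (length(ids) == 0L) {
    warning("no CDS features found in ", path)
    return(cds_set(character(0), character(0),
                   organism %||% "unknown", compartment, 1L))
  }
  ids <- make.unique(ids, sep = "_")
  cds_set(ids, seqs, organism %||% orgs, compartment, tables)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Resolve a GenBank location string against the record sequence.
# Supports n..m, complement(...), join(...), and their nesting; partial
# markers < and > are stripped. order() and cross-record refs are errors.
resolve_location <- function(loc, genome) {
  loc <- gsub("[<> ]", "", loc)
  if (grepl(":", loc, fixed = TRUE)) stop("cross-record reference")
  if (grepl("order\\(", loc)) stop("order() location")
  parse_one <- function(x) {
    if (grepl("^complement\\(", x)) {
      inner <- sub("^complement\\((.*)\\)$", "\\1", x)
      return(revcomp(parse_one(inner)))
    }
    if (grepl("^join\\(", x)) {
      inner <- sub("^join\\((.*)\\)$", "\\1", x)
      parts <- split_toplevel(inner)
      return(paste(vapply(parts, parse_one, character(1)), collapse = ""))
    }
    if (grepl("^\\d+\\.\\.\\d+$", x)) {
      ft <- as.integer(strsplit(x, "..", fixed = TRUE)[[1]])
      if (ft[1] > ft[2] || ft[2] > nchar(genome)) stop("span out of range")
      return(substr(genome, ft[1], ft[2]))
    }
    if (grepl("^\\d+$", x)) {
      p <- as.integer(x)
      if (p > nchar(genome)) stop("position out of range")
      return(substr(genome, p, p))
    }
    stop("unsupported location element: ", x)
  }
  parse_one(loc)
}

# split a comma-separated list at the top nesting level
split_toplevel <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  depth <- 0L; cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L); ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts), function(i) {
    paste(chars[starts[i]:ends[i]], collapse = "")
  }, character(1))
}
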