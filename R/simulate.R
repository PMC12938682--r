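# Synthetic CDS generator with known ground truth: a tunable third-position
# GC bias (mutational pressure), a tunable per-codon selection weight
# (translational selection), and a regime switch that couples or decouples
# first/second-position composition from the third position, so the
# neutrality, ENC-GC3, PR2 and optimal-codon analyses can all be validated
# against planted parameters.

#' Simulation configuration
#'
#' @param n_genes Number of genes to generate.
#' @param length_codons Gene length in sense codons (excluding the ATG start
#'   and the stop codon): a single value, or `c(min, max)` for a per-gene
#'   uniform draw. Must be at least 100.
#' @param s Third-position GC bias: the probability that a third-position
#'   draw is G or C (split evenly). A single value, or `c(min, max)` for a
#'   per-gene uniform draw (the sweep used to trace the neutrality trend).
#' @param beta Translational selection strength (>= 0); the preferred codon
#'   of each family receives weight `exp(beta)` relative to its mutational
#'   weight.
#' @param preferred_codons Named character vector (amino acid -> codon)
#'   marking the selectively preferred codon per family; required when
#'   `beta > 0`. See [random_preferred_codons()].
#' @param regime `"mutation"`: codons are drawn from a whole-codon mutational
#'   distribution, so first/second-position GC tracks `s` and the neutrality
#'   slope approaches 1. `"selection"`: amino acids are drawn from fixed
#'   `aa_freqs` while only the third position follows `s`, decoupling GC12
#'   from GC3 (slope near 0).
#' @param aa_freqs Named amino-acid frequencies (selection regime only);
#'   default uniform over the amino acids of the code.
#' @param transl_table NCBI genetic-code number.
#' @param seed Integer seed fixing the complete output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 500L, length_codons = c(150L, 300L),
                       s = c(0.2, 0.8), beta = 0,
                       preferred_codons = NULL,
                       regime = c("mutation", "selection"),
                       aa_freqs = NULL, transl_table = 1L, seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_genes >= 1L, beta >= 0,
            all(s > 0), all(s < 1), length(s) %in% 1:2,
            length(length_codons) %in% 1:2, all(length_codons >= 100L))
  if (beta > 0 && is.null(preferred_codons)) {
    stop("beta > 0 requires preferred_codons (see random_preferred_codons())")
  }
  fam <- codon_families(transl_table)
  aas <- sort(unique(fam$aa))
  if (is.null(aa_freqs)) {
    aa_freqs <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  }
  stopifnot(all(names(aa_freqs) %in% aas), all(aa_freqs >= 0),
            abs(sum(aa_freqs) - 1) < 1e-8)
  if (!is.null(preferred_codons)) {
    stopifnot(all(preferred_codons %in% fam$codon),
              all(names(preferred_codons) %in% aas))
  }
  structure(list(
    n_genes = as.integer(n_genes),
    length_codons = as.integer(length_codons),
    s = s, beta = beta,
    preferred_codons = preferred_codons,
    regime = regime, aa_freqs = aa_freqs,
    transl_table = as.integer(transl_table),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' One random preferred codon per multi-codon family
#'
#' @param transl_table NCBI genetic-code number.
#' @param seed Integer seed.
#' @return Named character vector, amino acid -> codon.
#' @export
random_preferred_codons <- function(transl_table = 1L, seed = 1L) {
  fam <- codon_families(transl_table)
  fam <- fam[fam$family_size >= 2L, ]
  set.seed(seed)
  vapply(split(fam$codon, fam$aa), function(cods) {
    cods[sample.int(length(cods), 1L)]
  }, character(1))
}

# third-position mutational base weights: G,C get s/2; A,T get (1-s)/2
.base_weights <- function(s) c(A = (1 - s) / 2, C = s / 2,
                               G = s / 2, T = (1 - s) / 2)

# per-codon sampling probabilities for a gene at bias s
.codon_probs <- function(cfg, s) {
  fam <- codon_families(cfg$transl_table)
  w <- .base_weights(s)
  sel <- rep(1, nrow(fam))
  if (!is.null(cfg$preferred_codons)) {
    sel[fam$codon %in% cfg$preferred_codons] <- exp(cfg$beta)
  }
  if (cfg$regime == "mutation") {
    # whole-codon mutational weight couples all three positions to s
    p <- vapply(fam$codon, function(cd) {
      prod(w[strsplit(cd, "", fixed = TRUE)[[1]]])
    }, numeric(1)) * sel
    list(fam = fam, p = p / sum(p))
  } else {
    # third position only; positions 1-2 are set by the amino-acid draw
    third <- substr(fam$codon, 3L, 3L)
    p <- w[third] * sel
    # normalize within family: p(codon | aa)
    fam_tot <- tapply(p, fam$aa, sum)
    list(fam = fam, p = p / as.numeric(fam_tot[fam$aa]))
  }
}

# derived per-gene seed, kept below 2^31
.gene_seed <- function(seed, index) {
  (abs(seed) %% 65011L) * 32749L + (index %% 32749L)
}

#' Generate one synthetic coding sequence
#'
#' @param cfg A [sim_config()].
#' @param index Gene index (drives the per-gene seed and identifier).
#' @return Single-row [cds_set()]; attribute `"truth"` records the realized
#'   per-gene `s`, `beta` and regime.
#' @export
generate_gene <- function(cfg, index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.gene_seed(cfg$seed, index))
  s <- if (length(cfg$s) == 2L) stats::runif(1, cfg$s[1], cfg$s[2]) else cfg$s
  L <- if (length(cfg$length_codons) == 2L) {
    sample(cfg$length_codons[1]:cfg$length_codons[2], 1L)
  } else cfg$length_codons

  cp <- .codon_probs(cfg, s)
  if (cfg$regime == "mutation") {
    cods <- sample(cp$fam$codon, L, replace = TRUE, prob = cp$p)
  } else {
    aas <- sample(names(cfg$aa_freqs), L, replace = TRUE,
                  prob = cfg$aa_freqs)
    cods <- character(L)
    for (aa in unique(aas)) {
      at <- which(aas == aa)
      members <- which(cp$fam$aa == aa)
      cods[at] <- if (length(members) == 1L) cp$fam$codon[members]
        else sample(cp$fam$codon[members], length(at), replace = TRUE,
                    prob = cp$p[members])
    }
  }
  stops <- stop_codons(cfg$transl_table)
  stop_c <- if ("TAA" %in% stops) "TAA" else stops[1]
  seq <- paste0("ATG", paste(cods, collapse = ""), stop_c)
  out <- cds_set(sprintf("sim_gene_%04d", index), seq,
                 organism = "synthetic", compartment = "nuclear",
                 transl_table = cfg$transl_table)
  attr(out, "truth") <- list(s = s, beta = cfg$beta, regime = cfg$regime,
                             length_codons = L)
  out
}

#' Generate a synthetic CDS dataset with its ground-truth manifest
#'
#' Every generated gene passes the default screening rules by construction
#' (ATG start, terminal stop, no internal stops, length >= 306 nt).
#'
#' @param cfg A [sim_config()].
#' @return List with `cds` (a [cds_set()]), `manifest` (per-gene realized
#'   `s`, `beta`, regime, length) and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- lapply(seq_len(cfg$n_genes), function(i) generate_gene(cfg, i))
  cds <- do.call(rbind, genes)
  class(cds) <- c("cds_set", "data.frame")
  truth <- lapply(genes, attr, "truth")
  manifest <- data.frame(
    id = cds$id,
    s = vapply(truth, `[[`, numeric(1), "s"),
    beta = cfg$beta,
    regime = cfg$regime,
    length_codons = vapply(truth, `[[`, numeric(1), "length_codons"),
    stringsAsFactors = FALSE
  )
  if (!is.null(cfg$preferred_codons)) {
    manifest$preferred <- paste(cfg$preferred_codons, collapse = ",")
  }
  list(cds = cds, manifest = manifest, config = cfg)
}

#' Write a simulated dataset: FASTA, manifest TSV and config echo JSON
#'
#' @param dataset A [generate_dataset()] result.
#' @param out_dir Output directory (created if missing).
#' @export
write_simulation <- function(dataset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cds_fasta(dataset$cds, file.path(out_dir, "simulated.fasta"))
  utils::write.table(dataset$manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  echo <- list(n_genes = cfg$n_genes,
               length_codons = paste(cfg$length_codons, collapse = "-"),
               s = paste(cfg$s, collapse = "-"),
               beta = cfg$beta, regime = cfg$regime,
               transl_table = cfg$transl_table, seed = cfg$seed)
  writeLines(to_json(echo), file.path(out_dir, "config.json"))
  invisible(out_dir)
}
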