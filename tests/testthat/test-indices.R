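# Codon counting and every per-gene index: positional GC, silent-site
# composition, RSCU, ENC (observed / expected / ratio), CAI, Gravy, Aromo.

test_that("codon counting handles stops, N codons and frame errors", {
  t <- count_codons("ATGAAATAA")
  expect_equal(unname(t$counts[c("ATG", "AAA", "TAA")]), c(1L, 1L, 1L))
  expect_equal(t$n_codons, 2L)          # terminal stop excluded
  expect_equal(unname(t$stop_counts["TAA"]), 1L)

  expect_equal(count_codons("ATGTAA")$n_codons, 1L)
  expect_error(count_codons("ATGAA"), "multiple of 3")

  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  t <- count_codons(s)
  expect_equal(sum(t$counts), 100L)     # length / 3, sense + stops

  tn <- count_codons("ATGANATAA")
  expect_equal(sum(tn$counts), 2L)      # N codon skipped
})

test_that("positional GC content matches hand counts", {
  all_acc <- count_codons(paste(rep("ACC", 10), collapse = ""))
  bc <- base_composition(all_acc)
  expect_equal(unname(bc[c("gc1", "gc2", "gc3", "gc12")]), c(0, 1, 1, 0.5))
  all_gcc <- count_codons(paste(rep("GCC", 10), collapse = ""))
  expect_equal(unname(base_composition(all_gcc)[c("gc1", "gc2", "gc3")]),
               c(1, 1, 1))

  sym <- codon_counts(c(AAA = 1L, GGG = 1L))
  expect_equal(unname(base_composition(sym)[c("gc", "gc1", "gc2", "gc3")]),
               rep(0.5, 4))

  # hand count: first positions A,A; second T,A; third G,A
  mix <- codon_counts(c(ATG = 1L, AAA = 1L))
  bc <- base_composition(mix)
  expect_equal(unname(bc[c("gc1", "gc2", "gc3", "gc12")]),
               c(0, 0, 0.5, 0))
  expect_error(base_composition(codon_counts(c(TAA = 1L))), "empty")
})

test_that("silent-site composition is restricted to synonymous codons", {
  expect_warning(s <- silent_composition(codon_counts(c(ATG = 5L))),
                 "undefined")
  expect_true(all(is.na(s)))

  lys <- silent_composition(codon_counts(c(AAA = 2L, AAG = 2L)))
  expect_equal(unname(lys[c("a3s", "g3s", "gc3s")]), c(0.5, 0.5, 0.5))

  phe <- silent_composition(codon_counts(c(TTT = 3L, TTC = 1L)))
  expect_equal(unname(phe[c("t3s", "c3s", "gc3s")]), c(0.75, 0.25, 0.25))
  expect_equal(sum(phe[c("a3s", "t3s", "c3s", "g3s")]), 1)
})

test_that("RSCU matches the defining formula and normalization invariant", {
  eq <- rscu(codon_counts(c(TTT = 2L, TTC = 2L)))
  expect_equal(eq$rscu[eq$codon %in% c("TTT", "TTC")], c(1, 1))

  phe <- rscu(codon_counts(c(TTT = 3L, TTC = 1L)))
  expect_equal(phe$rscu[phe$codon == "TTT"], 1.5)  # 3 / (4/2)
  expect_equal(phe$rscu[phe$codon == "TTC"], 0.5)
  expect_true(all(is.na(phe$rscu[phe$aa == "K"])))  # absent family: missing

  # family sums equal family size on random tables
  set.seed(7)
  for (i in 1:100) {
    rs <- rscu(random_count_table())
    sums <- tapply(rs$rscu, rs$aa, sum)
    sizes <- tapply(rs$family_size, rs$aa, unique)
    obs <- !is.na(sums)
    expect_equal(as.numeric(sums[obs]), as.numeric(sizes[obs]), tolerance = 1e-9)
  }
})

test_that("observed ENC attains the analytic limits", {
  fam <- codon_families(1)
  one_per_aa <- vapply(split(fam$codon, fam$aa), `[`, character(1), 1)
  t20 <- codon_counts(stats::setNames(rep(10L, length(one_per_aa)), one_per_aa))
  expect_equal(enc_observed(t20), 20)

  t61 <- codon_counts(stats::setNames(rep(10L, nrow(fam)), fam$codon))
  expect_equal(enc_observed(t61), 61)  # cap applied
})

test_that("observed ENC matches an independent brute force on random tables", {
  set.seed(11)
  for (i in 1:100) {
    t <- random_count_table(lambda = stats::runif(1, 0.5, 8))
    expect_equal(enc_observed(t), enc_brute_force(t), tolerance = 1e-9)
  }
  # and under a mitochondrial code with its own degeneracy structure
  set.seed(12)
  for (i in 1:20) {
    t <- random_count_table(transl_table = 5, lambda = 5)
    expect_equal(enc_observed(t), enc_brute_force(t), tolerance = 1e-9)
  }
})

test_that("observed ENC is bounded and NA when inestimable", {
  set.seed(13)
  for (i in 1:50) {
    e <- enc_observed(random_count_table(lambda = 3))
    if (!is.na(e)) {
      expect_gte(e, 20)
      expect_lte(e, 61)
    }
  }
  # only one estimable degeneracy class -> flagged missing
  expect_true(is.na(enc_observed(codon_counts(c(AAA = 3L, AAG = 1L)))))
})

test_that("degeneracy classes follow the active genetic code", {
  fam5 <- codon_families(5)
  expect_equal(fam5$family_size[fam5$codon == "AGA"], 8L)  # Ser 8-fold
  expect_equal(fam5$family_size[fam5$codon == "ATT"], 2L)  # Ile 2-fold
  expect_equal(fam5$family_size[fam5$codon == "TGA"], 2L)  # Trp 2-fold
  fam1 <- codon_families(1)
  expect_equal(fam1$family_size[fam1$codon == "ATA"], 3L)  # Ile 3-fold
})

test_that("expected ENC curve matches its closed form with maximum at 0.5", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(1), 32.0)
  expect_equal(enc_expected(0), 31.0)
  s <- seq(0, 1, by = 0.01)
  expect_true(all(enc_expected(s) <= enc_expected(0.5)))
  expect_error(enc_expected(1.2), "0, 1")
})

test_that("ENC ratio follows its formula with signs preserved", {
  expect_equal(enc_ratio(55, 55), 0)
  expect_equal(enc_ratio(60.5, 55), 0.1)
  expect_lt(enc_ratio(50, 55), 0)
})

test_that("CAI weights and CAI follow the geometric-mean definition", {
  w <- derive_cai_weights(codon_counts(c(TTT = 3L, TTC = 1L)))
  expect_equal(unname(w$w[c("TTT", "TTC")]), c(1, 1 / 3))
  # codons of families absent from the reference get the floor
  expect_equal(unname(w$w["AAA"]), 0.01)

  fam <- codon_families(1)
  uniform <- derive_cai_weights(
    codon_counts(stats::setNames(rep(5L, nrow(fam)), fam$codon)))
  expect_true(all(uniform$w == 1))

  # two eligible codons with weights 1 and 0.25 -> sqrt(0.25)
  ref <- codon_counts(c(TTT = 4L, TTC = 1L, AAA = 4L, AAG = 1L))
  w2 <- derive_cai_weights(ref)
  g <- codon_counts(c(TTT = 1L, AAG = 1L))
  expect_equal(cai(g, w2), sqrt(1 * 0.25))

  # all-maximal usage gives CAI = 1; CAI <= 1 always
  gmax <- codon_counts(c(TTT = 3L, AAA = 2L))
  expect_equal(cai(gmax, w2), 1)
  set.seed(21)
  for (i in 1:25) {
    t <- random_count_table(lambda = 2)
    v <- suppressWarnings(cai(t, w2))
    if (!is.na(v)) expect_lte(v, 1)
  }
})

test_that("protein indices reproduce the hydropathy table values", {
  polyF <- paste(rep("TTT", 20), collapse = "")
  pi <- protein_indices(polyF)
  expect_equal(unname(pi["gravy"]), 2.8)   # Kyte-Doolittle F
  expect_equal(unname(pi["aromo"]), 1.0)

  feala <- paste(rep(c("TTT", "GCT"), 10), collapse = "")
  expect_equal(unname(protein_indices(feala)["aromo"]), 0.5)
})

test_that("gene_metrics assembles a consistent per-gene table", {
  d <- generate_dataset(sim_config(n_genes = 20, length_codons = 120L,
                                   s = 0.5, seed = 6))
  m <- gene_metrics(d$cds)
  expect_equal(nrow(m), 20L)
  expect_equal(m$gc12, (m$gc1 + m$gc2) / 2)
  expect_true(all(m$enc_obs >= 20 & m$enc_obs <= 61, na.rm = TRUE))
  expect_true(all(m$cai > 0 & m$cai <= 1, na.rm = TRUE))
  expect_equal(m$enc_ratio, (m$enc_exp - m$enc_obs) / m$enc_obs)
  expect_equal(rowSums(m[, c("a3s", "t3s", "c3s", "g3s")]),
               rep(1, 20), tolerance = 1e-12, ignore_attr = TRUE)

  path <- tempfile(fileext = ".tsv")
  write_gene_metrics(m, path)
  back <- utils::read.delim(path)
  expect_equal(back$enc_obs, m$enc_obs, tolerance = 1e-6)
})

test_that("codon counting agrees with an independent library on a real-shaped gene", {
  d <- generate_dataset(sim_config(n_genes = 1, length_codons = 200L,
                                   s = 0.6, seed = 10))
  s <- d$cds$sequence[1]
  mine <- count_codons(s)
  ext <- seqinr::uco(strsplit(tolower(s), "")[[1]], index = "eff")
  names(ext) <- toupper(names(ext))
  expect_equal(unname(mine$counts[names(ext)]), unname(as.numeric(ext)))
})
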