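# Sequence ingestion and the four screening rules.

test_that("FASTA reading preserves order, canonicalizes case and U, and reports bad records", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">g1", "atgaaatttgggtaa",
               ">g2", "ATGCCCGGGUAA",
               ">g3", "ATGXXXTAA"), fa)
  expect_warning(cds <- read_cds_fasta(fa), "rejected")
  expect_equal(cds$id, c("g1", "g2"))
  expect_equal(cds$sequence[1], "ATGAAATTTGGGTAA")
  expect_equal(cds$sequence[2], "ATGCCCGGGTAA")  # U -> T
  expect_equal(attr(cds, "invalid_records"), "g3")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_warning(e <- read_cds_fasta(empty), "no records")
  expect_equal(nrow(e), 0L)
})

test_that("screening applies rules in order and records the first failing reason", {
  seqs <- cds_set(
    id = c("short", "gtg_start", "internal", "badframe", "nostop", "ok"),
    sequence = c(
      "ATGAAATTTTAG",                                    # 12 nt, too short
      paste0("GTG", substr(clean_cds(), 4, nchar(clean_cds()))),
      make_cds(c(rep("AAA", 49), "TAA", rep("AAA", 50))), # stop at codon 50/101
      paste0(clean_cds(), "AC"),                          # not multiple of 3
      make_cds(rep("AAA", 100), stop_codon = "AAA"),      # no terminal stop
      clean_cds()
    )
  )
  res <- screen_cds(seqs, screening_config(min_length_nt = 300))
  rej <- res$report$rejected
  expect_equal(rej$reason[rej$id == "short"], "too_short")
  expect_equal(rej$reason[rej$id == "gtg_start"], "no_atg_start")
  expect_equal(rej$reason[rej$id == "internal"], "internal_stop")
  expect_equal(rej$reason[rej$id == "badframe"], "bad_frame")
  expect_equal(rej$reason[rej$id == "nostop"], "no_terminal_stop")
  expect_equal(res$kept$id, "ok")

  # report conservation: input = kept + sum(rejections)
  expect_equal(res$report$n_input,
               res$report$n_kept + nrow(res$report$rejected))
})

test_that("internal-stop checks honour the sequence's genetic code", {
  # TGA is a stop under the standard code but Trp under tables 4/5
  s <- make_cds(c(rep("AAA", 50), "TGA", rep("AAA", 50)))
  std <- cds_set("g", s, transl_table = 1L)
  mito <- cds_set("g", s, compartment = "mitochondrial", transl_table = 4L)
  expect_equal(screen_cds(std)$report$rejected$reason, "internal_stop")
  expect_equal(screen_cds(mito)$kept$id, "g")
})

test_that("sequences with excess ambiguous codons are rejected", {
  many_n <- make_cds(c(rep("AAN", 10), rep("AAA", 90)))
  few_n <- make_cds(c(rep("AAN", 2), rep("AAA", 98)))
  seqs <- cds_set(c("manyN", "fewN"), c(many_n, few_n))
  res <- screen_cds(seqs)
  expect_equal(res$report$rejected$reason[res$report$rejected$id == "manyN"],
               "excess_n")
  expect_true("fewN" %in% res$kept$id)
})

test_that("pairwise identity matches hand-counted values", {
  a <- "ACGTACGTACGTACGTACGT"
  expect_equal(pairwise_identity(a, a), 1.0)
  b <- paste0(substr(a, 1, 19), "A")  # one mismatch of 20, no gaps
  expect_equal(pairwise_identity(a, b), 0.95)
})

test_that("redundancy removal follows the greedy longest-first rule", {
  # two identical sequences: first by lexicographic id kept
  s <- clean_cds()
  two <- cds_set(c("b", "a"), c(s, s))
  kept <- remove_redundant(two, 0.95)
  expect_equal(kept$id, "a")

  # chain: A~B >= .95, B~C >= .95, A~C < .95, lengths A > B > C
  # oracle (hand trace of the greedy rule): A kept, B dropped, C kept
  set.seed(99)  # aperiodic base sequence so the aligner cannot shift frames
  base <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                collapse = "")
  A <- base
  B <- substr(A, 1, 98)                       # identity(A,B) = 98/100
  C <- substr(B, 1, 96)
  substr(C, 10, 10) <- "T"; substr(C, 20, 20) <- "A"  # 2 mismatches
  # identity(B,C) = 94/98 = 0.959; identity(A,C) = 94/100 = 0.94
  expect_gte(pairwise_identity(A, B), 0.95)
  expect_gte(pairwise_identity(B, C), 0.95)
  expect_lt(pairwise_identity(A, C), 0.95)
  chain <- cds_set(c("A", "B", "C"), c(A, B, C))
  kept <- remove_redundant(chain, 0.95)
  expect_setequal(kept$id, c("A", "C"))

  # mutually dissimilar sequences all survive
  set.seed(1)
  three <- cds_set(paste0("r", 1:3), vapply(1:3, function(i) {
    paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  }, character(1)))
  expect_equal(nrow(remove_redundant(three, 0.95)), 3L)
})

test_that("redundancy-removal output never contains a pair at or above threshold", {
  set.seed(42)
  pool <- generate_dataset(sim_config(n_genes = 6, length_codons = 100L,
                                      s = 0.5, seed = 5))$cds
  # add near-duplicates of two genes
  dup <- pool[c(1, 2), ]
  dup$id <- paste0(dup$id, "_dup")
  substr(dup$sequence[1], 10, 10) <- "A"
  seqs <- rbind(pool, dup)
  class(seqs) <- c("cds_set", "data.frame")
  kept <- remove_redundant(seqs, 0.95)
  ids <- kept$id
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      expect_lt(pairwise_identity(kept$sequence[i], kept$sequence[j]), 0.95)
    }
  }
})

test_that("screening is idempotent", {
  set.seed(3)
  pool <- generate_dataset(sim_config(n_genes = 8, length_codons = 100L,
                                      s = 0.4, seed = 8))$cds
  bad <- cds_set("bad", "ATGAAATTTTAG")
  seqs <- rbind(pool, bad)
  class(seqs) <- c("cds_set", "data.frame")
  once <- screen_cds(seqs)
  twice <- screen_cds(once$kept)
  expect_equal(twice$kept$id, once$kept$id)
  expect_equal(twice$report$n_kept, once$report$n_kept)
  # every kept sequence translates without internal stops under its code
  for (i in seq_len(nrow(once$kept))) {
    cods <- substring(once$kept$sequence[i],
                      seq(1, nchar(once$kept$sequence[i]) - 2, 3),
                      seq(3, nchar(once$kept$sequence[i]), 3))
    aa <- genetic_code(once$kept$transl_table[i])[cods]
    expect_false(any(aa[-length(aa)] == "*"))
  }
})

test_that("screening outputs round-trip through files", {
  pool <- generate_dataset(sim_config(n_genes = 5, length_codons = 100L,
                                      seed = 2))$cds
  res <- screen_cds(pool)
  dir <- tempfile()
  paths <- write_screening_output(res, dir)
  expect_true(all(file.exists(paths)))
  back <- read_cds_fasta(file.path(dir, "screened.fasta"))
  expect_equal(back$sequence, res$kept$sequence)
})
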