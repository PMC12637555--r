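test_that("exact and diverged planted fragments align with correct identity", {
  set.seed(51)
  mrna <- oracle_random_dna(1200)
  frag <- substr(mrna, 101, 400)
  cluster <- paste0(oracle_random_dna(800), frag, oracle_random_dna(600))
  ch <- align_cluster_to_mrna(cluster, mrna)
  expect_identical(ch$orientation, "same")
  expect_equal(ch$identity, 1.0)
  expect_equal(ch$blocks$s_start, 100L)
  expect_equal(ch$blocks$s_end, 400L)

  # antisense fragment with 5% planted substitutions
  frag2 <- substr(mrna, 201, 800)
  pos <- which(stats::runif(nchar(frag2)) < 0.05)
  frag2m <- frag2
  for (p in pos) substr(frag2m, p, p) <-
    setdiff(c("A", "C", "G", "T"), substr(frag2, p, p))[1]
  planted_id <- 1 - length(pos) / nchar(frag2)
  cluster2 <- paste0(oracle_random_dna(700), oracle_revcomp(frag2m),
                     oracle_random_dna(500))
  ch2 <- align_cluster_to_mrna(cluster2, mrna)
  expect_identical(ch2$orientation, "antisense")
  expect_lt(abs(ch2$identity - planted_id), 0.02)

  # unrelated random sequences give no qualifying chain
  expect_null(align_cluster_to_mrna(oracle_random_dna(2000),
                                    oracle_random_dna(2000)))
})

test_that("alignment identity is symmetric and strand-consistent", {
  set.seed(52)
  base <- oracle_random_dna(900)
  mut <- base
  pos <- which(stats::runif(900) < 0.06)
  for (p in pos) substr(mut, p, p) <-
    setdiff(c("A", "C", "G", "T"), substr(base, p, p))[1]
  ab <- pairwise_cluster_identity(base, mut)
  ba <- pairwise_cluster_identity(mut, base)
  expect_equal(ab$identity, ba$identity, tolerance = 1e-9)
  # a planted antisense fragment reports antisense from either strand view
  mrna <- oracle_random_dna(1000)
  ins <- oracle_revcomp(substr(mrna, 101, 700))
  clA <- paste0(oracle_random_dna(400), ins, oracle_random_dna(400))
  chA <- align_cluster_to_mrna(clA, mrna)
  chB <- align_cluster_to_mrna(revcomp(clA), mrna)
  expect_identical(chA$orientation, "antisense")
  expect_identical(chB$orientation, "same")
})

test_that("identity recovery holds across the divergence ladder", {
  set.seed(53)
  mrna <- oracle_random_dna(1500)
  for (d in c(0, 0.02, 0.05, 0.10)) {
    frag <- substr(mrna, 301, 1300)
    pos <- which(stats::runif(nchar(frag)) < d)
    for (p in pos) substr(frag, p, p) <-
      setdiff(c("A", "C", "G", "T"), substr(mrna, 300 + p, 300 + p))[1]
    cluster <- paste0(oracle_random_dna(500), oracle_revcomp(frag),
                      oracle_random_dna(500))
    ch <- align_cluster_to_mrna(cluster, mrna)
    expect_gte(ch$identity, 1 - d - 0.02)
    expect_lte(ch$identity, 1 - d + 0.02)
  }
})

test_that("pgf calls recover planted anatomy including processing status", {
  cfg <- simulation_config(
    seed = 54, genome_size = 200000L, n_genes = 8L, n_clusters = 3L,
    exons_per_gene = c(3L, 6L), exon_len = c(150L, 400L),
    pgf_plans = list(
      pgf_plan(1L, 1L, divergence = 0.05, truncation = 80L, tsd_len = 12L),
      pgf_plan(2L, 2L, divergence = 0.04, truncation = 60L, tsd_len = 10L,
               include_intron = TRUE)),
    n_species = 500L, depth = 10000L)
  sim <- simulate_genome(cfg)
  mods <- select_representative_transcripts(sim$models)
  calls <- call_pgfs(sim$genome, sim$clusters, mods)
  expect_equal(nrow(calls), 2L)
  for (p in sim$manifest$pgfs) {
    row <- calls[calls$gene_id == p$gene_id, ]
    expect_equal(nrow(row), 1L)
    expect_identical(row$cluster_id, p$cluster_id)
    expect_identical(row$exons, paste(p$exons, collapse = ","))
    expect_identical(row$processed, !p$include_intron)
    expect_true(row$five_prime_truncated)
    expect_true(row$pirna_antisense)
    expect_identical(row$tsd_seq, p$tsd_seq)
  }
  # a cluster without a planted fragment yields no call
  expect_false("piC03" %in% calls$cluster_id)
})

test_that("TSD detection recovers planted duplications and stays off random flanks", {
  set.seed(55)
  mk_site <- function(tsd, insert) {
    paste0(oracle_random_dna(120), tsd, insert, tsd, oracle_random_dna(120))
  }
  insert <- oracle_random_dna(400)
  tsd <- "ACGTTGCAGGTA"                  # 12 nt
  chrom <- mk_site(tsd, insert)
  call <- detect_tsd(chrom, 132L, 532L)
  expect_identical(call$seq, tsd)
  expect_equal(call$left_end, 132L)
  expect_equal(call$right_start, 532L)
  expect_equal(call$mismatches, 0L)
  # copies never overlap the insertion interval
  expect_lte(call$left_end, 132L)
  expect_gte(call$right_start, 532L)

  # 14-nt duplication with one central mismatch is tolerated
  tsd14 <- "ACGTTGCAGGTAAC"
  tsd14mm <- tsd14
  substr(tsd14mm, 7, 7) <- "T"           # central mismatch (was "C")
  chrom2 <- paste0(oracle_random_dna(120), tsd14, insert, tsd14mm,
                   oracle_random_dna(120))
  call2 <- detect_tsd(chrom2, 134L, 534L)
  expect_equal(call2$length, 14L)
  expect_equal(call2$mismatches, 1L)

  expect_warning(detect_tsd(oracle_random_dna(120), 10L, 60L),
                 "insufficient flank")

  # false-positive rate on random flanks stays below 5%
  fp <- 0L
  for (i in 1:200) {
    chromR <- oracle_random_dna(520)
    if (!is.null(detect_tsd(chromR, 130L, 390L))) fp <- fp + 1L
  }
  expect_lt(fp / 200, 0.05)
})

test_that("pairwise cluster identity reports coverage alongside identity", {
  set.seed(56)
  a <- oracle_random_dna(1500)
  same <- pairwise_cluster_identity(a, a)
  expect_equal(same$identity, 1.0)
  expect_equal(same$coverage_a, 1.0)
  expect_equal(same$coverage_b, 1.0)
  b <- a
  pos <- which(stats::runif(1500) < 0.10)
  for (p in pos) substr(b, p, p) <-
    setdiff(c("A", "C", "G", "T"), substr(a, p, p))[1]
  div <- pairwise_cluster_identity(a, b)
  expect_lt(abs(div$identity - (1 - length(pos) / 1500)), 0.015)
  unrel <- pairwise_cluster_identity(oracle_random_dna(1500),
                                     oracle_random_dna(1500))
  expect_true(is.na(unrel$identity))
  expect_equal(unrel$coverage_a, 0)
})
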