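test_that("guide core extraction obeys the nt 2-21 window", {
  p30 <- strrep("ACGTA", 6)
  expect_identical(extract_guide_core(p30), substr(p30, 2, 21))
  expect_identical(nchar(extract_guide_core(p30)), 20L)
  p21 <- substr(p30, 1, 21)
  expect_identical(extract_guide_core(p21), substr(p21, 2, 21))
  expect_error(extract_guide_core(substr(p30, 1, 20)), "too short")
})

test_that("a constructed perfect antisense complement yields exactly one hit", {
  mrna <- "AAAACCCCGGGGTTTTACGTACGT"
  win <- substr(mrna, 3, 22)            # window [2, 22)
  pirna <- paste0("T", revcomp(win), "CGA")
  h <- scan_transcript(pirna, mrna)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 2L)
  expect_equal(h$end, 22L)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$cleavage_site, 12L)    # start + 10

  # one substitution inside the core: still a hit, with the mismatch
  # position mapped back into the nt 2-21 frame
  core <- extract_guide_core(pirna)
  mut_q_pos <- 5L                        # 5th position of the mRNA window
  qc <- revcomp(core)
  old <- substr(qc, mut_q_pos, mut_q_pos)
  mrna1 <- mrna
  substr(mrna1, 2L + mut_q_pos, 2L + mut_q_pos) <-
    setdiff(c("A", "C", "G", "T"), old)[1]
  h1 <- scan_transcript(pirna, mrna1)
  h1 <- h1[h1$start == 2L, ]
  expect_equal(h1$mismatches, 1L)
  expect_equal(h1$mismatch_core_pos, 21L - mut_q_pos)

  # two substitutions: no hit at that window
  mrna2 <- mrna1
  substr(mrna2, 12, 12) <- setdiff(c("A", "C", "G", "T"),
                                   substr(mrna1, 12, 12))[1]
  h2 <- scan_transcript(pirna, mrna2)
  expect_false(2L %in% h2$start)
})

test_that("indexed scan equals the exhaustive Hamming oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    genome <- c(chr1 = oracle_random_dna(12000))
    models <- lapply(1:6, function(i) simple_model(
      sprintf("g%02d", i), "chr1", (i - 1L) * 2000L,
      (i - 1L) * 2000L + sample(500:900, 1), genome))
    names(models) <- vapply(models, `[[`, "", "transcript_id")
    # random guides plus planted exact / 1-mm / 2-mm guides
    rand <- vapply(1:150, function(i) oracle_random_dna(28), "")
    planted <- unlist(lapply(models[1:3], function(m) {
      p <- sample(0:(tx_length(m) - 20L), 1)
      win <- substr(m$mature_seq, p + 1, p + 20)
      exact <- paste0("T", revcomp(win), oracle_random_dna(7))
      mm1 <- exact; substr(mm1, 10, 10) <-
        setdiff(c("A", "C", "G", "T"), substr(mm1, 10, 10))[1]
      mm2 <- mm1; substr(mm2, 15, 15) <-
        setdiff(c("A", "C", "G", "T"), substr(mm2, 15, 15))[1]
      c(exact, mm1, mm2)
    }))
    lib <- tiny_lib(unique(c(rand, planted)))
    hits <- scan_targets(lib, models)
    expect_identical(hit_key(hits), hit_key(oracle_scan_lib(lib, models)))
    # monotonicity: the 0-mm hit set is a subset of the 1-mm set
    hits0 <- scan_targets(lib, models, max_mm = 0L)
    k0 <- do.call(paste, hit_key(hits0))
    k1 <- do.call(paste, hit_key(hits)[hit_key(hits)$mismatches == 0L, ])
    expect_setequal(k0, k1)
  }
})

test_that("target ranking arithmetic and the multi-gene convention hold", {
  a <- strrep("ACGTAAG", 4); b <- strrep("CGTTAGC", 4); c <- strrep("GTACCTA", 4)
  lib <- tiny_lib(c(a, b, c), counts = c(70L, 20L, 10L))
  hits <- data.frame(pirna = c(a, b, c), gene_id = c("gene1", "gene2", "gene1"),
                     start = 0L, end = 20L, mismatches = 0L,
                     mismatch_core_pos = NA_integer_, cleavage_site = 10L)
  rk <- rank_targets(hits, lib, mass_threshold = 0.70)
  tab <- rk$table
  expect_equal(tab$fraction[tab$gene_id == "gene1"], 0.8)
  expect_equal(tab$fraction[tab$gene_id == "gene2"], 0.2)
  expect_identical(tab$gene_id[tab$in_top], "gene1")

  # one species hitting two genes contributes its full count to each
  hits2 <- data.frame(pirna = a, gene_id = c("gene1", "gene2"),
                      start = 0L, end = 20L, mismatches = c(0L, 1L),
                      mismatch_core_pos = NA_integer_, cleavage_site = 10L)
  lib2 <- tiny_lib(a, counts = 10L)
  rk2 <- rank_targets(hits2, lib2)
  expect_equal(rk2$table$fraction, c(1, 1))
  # single-best-target assignment restores exact normalization
  rk3 <- rank_targets(hits2, lib2, assign = "best")
  expect_equal(nrow(rk3$table), 1L)
  expect_identical(rk3$table$gene_id, "gene1")  # fewer mismatches wins
  expect_equal(sum(rk3$table$fraction), 1)
  expect_warning(rank_targets(hits[0, ], lib), "no mRNA-targeting")
})

test_that("coverage profiles add up and match the interval-union oracle", {
  set.seed(7)
  genome <- c(chr1 = oracle_random_dna(400))
  m <- simple_model("g1", "chr1", 0L, 30L, genome)
  s <- strrep("ACGTAAG", 4)
  lib <- tiny_lib(s, counts = 5L)
  h1 <- data.frame(pirna = s, gene_id = "g1", start = 2L, end = 22L,
                   mismatches = 0L, mismatch_core_pos = NA, cleavage_site = 12L)
  prof <- coverage_profile(h1, lib, m)
  expect_equal(prof$coverage, c(rep(0, 2), rep(5, 20), rep(0, 8)))
  expect_equal(prof$target_space, 20L)

  s2 <- strrep("TTGCAGA", 4)
  lib2 <- tiny_lib(c(s, s2), counts = c(1L, 2L))
  h2 <- data.frame(pirna = c(s, s2), gene_id = "g1", start = c(0L, 10L),
                   end = c(20L, 30L), mismatches = 0L,
                   mismatch_core_pos = NA, cleavage_site = c(10L, 20L))
  prof2 <- coverage_profile(h2, lib2, m)
  expect_equal(prof2$coverage, c(rep(1, 10), rep(3, 10), rep(2, 10)))
  expect_equal(prof2$target_space, 30L)

  # random windows vs a brute-force union
  mL <- simple_model("g2", "chr1", 0L, 400L, genome)
  starts <- sample(0:380, 25, replace = TRUE)
  seqs <- vapply(seq_along(starts), function(i) oracle_random_dna(28), "")
  libR <- tiny_lib(seqs)
  hR <- data.frame(pirna = seqs, gene_id = "g2", start = starts,
                   end = starts + 20L, mismatches = 0L,
                   mismatch_core_pos = NA, cleavage_site = starts + 10L)
  profR <- coverage_profile(hR, libR, mL)
  covered <- rep(FALSE, 400)
  for (p in starts) covered[(p + 1):(p + 20)] <- TRUE
  expect_equal(profR$target_space, sum(covered))
})

test_that("pool-fraction to molecules-per-cell conversion is plain arithmetic", {
  expect_equal(molecules_per_cell(0.016, 1e7), 160000)
  expect_equal(molecules_per_cell(0, 123), 0)
  expect_equal(molecules_per_cell(0.12, 160000), 19200)
  expect_error(molecules_per_cell(1.2, 10))
})
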