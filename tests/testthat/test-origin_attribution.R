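test_that("perfect origin mapping finds planted copies on both strands", {
  set.seed(21)
  pirna <- oracle_random_dna(28)
  left <- oracle_random_dna(300)
  mid <- oracle_random_dna(200)
  genome <- c(chr1 = paste0(left, pirna, mid, oracle_revcomp(pirna),
                            oracle_random_dna(150)))
  lib <- tiny_lib(pirna)
  org <- map_genomic_origins(lib, genome)
  expect_equal(nrow(org), 2L)
  plus <- org[org$strand == "+", ]
  expect_equal(plus$start, 300L)
  expect_equal(plus$end, 328L)
  minus <- org[org$strand == "-", ]
  expect_equal(minus$start, 528L)
  # an absent sequence is flagged unplaced
  lib2 <- tiny_lib(c(pirna, strrep("ACGTGGA", 4)))
  org2 <- map_genomic_origins(lib2, genome)
  expect_identical(attr(org2, "unplaced"), strrep("ACGTGGA", 4))
})

test_that("origin mapping equals a naive string-search oracle", {
  set.seed(22)
  genome <- c(chr1 = oracle_random_dna(30000), chr2 = oracle_random_dna(20000))
  # random species plus planted single- and multi-copy species
  seqs <- vapply(1:60, function(i) oracle_random_dna(sample(26:30, 1)), "")
  planted <- substring(genome[["chr1"]], c(101, 5001, 10001),
                       c(128, 5027, 10030))
  multi <- substring(genome[["chr2"]], 501, 528)
  genome[["chr2"]] <- paste0(genome[["chr2"]], oracle_revcomp(multi),
                             oracle_random_dna(50))
  lib <- tiny_lib(unique(c(seqs, planted, multi)))
  got <- map_genomic_origins(lib, genome)
  want <- do.call(rbind, lapply(lib$records$seq, oracle_find_exact,
                                genome = genome))
  key <- function(d) {
    d <- d[order(d$pirna, d$chrom, d$start, d$strand),
           c("pirna", "chrom", "start", "end", "strand")]
    rownames(d) <- NULL
    d
  }
  expect_identical(key(got), key(want))
})

test_that("cis/trans classification follows the any-overlap locus rule", {
  set.seed(23)
  gene_seq <- oracle_random_dna(1000)
  pir_cis <- oracle_revcomp(substr(gene_seq, 101, 128))
  pir_trans <- oracle_random_dna(28)
  pir_unplaced <- oracle_random_dna(28)
  genome <- c(chr1 = paste0(oracle_random_dna(200), gene_seq,
                            oracle_random_dna(300), pir_trans,
                            oracle_random_dna(100)))
  models <- list(t1 = simple_model("g1", "chr1", 200L, 1200L, genome))
  lib <- tiny_lib(c(pir_cis, pir_trans, pir_unplaced))
  hits <- data.frame(pirna = c(pir_cis, pir_trans, pir_unplaced),
                     gene_id = "g1", start = 0L, end = 20L, mismatches = 0L,
                     mismatch_core_pos = NA, cleavage_site = 10L)
  org <- map_genomic_origins(lib, genome)
  ct <- classify_cis_trans(hits, org, models)
  expect_identical(ct$status[match(c(pir_cis, pir_trans, pir_unplaced),
                                   ct$pirna)],
                   c("cis", "trans", "unplaced"))
  # mixed case: a second perfect copy far from the gene stays cis
  genome2 <- c(chr1 = paste0(genome[["chr1"]], pir_cis,
                             oracle_random_dna(60)))
  org2 <- map_genomic_origins(lib, genome2)
  ct2 <- classify_cis_trans(hits, org2, models)
  row <- ct2[ct2$pirna == pir_cis, ]
  expect_identical(row$status, "cis")
  expect_true(row$mixed)
})

test_that("cluster attribution apportions equally and conserves mass", {
  set.seed(24)
  s1 <- oracle_random_dna(28)
  s2 <- oracle_random_dna(28)
  genome <- c(chr1 = paste0(oracle_random_dna(100), s1,
                            oracle_random_dna(100), s2,
                            oracle_random_dna(500), s2,
                            oracle_random_dna(100)))
  clusters <- data.frame(cluster_id = "piC1", chrom = "chr1",
                         start = 50L, end = 300L, strand = "+")
  lib <- tiny_lib(c(s1, s2), counts = c(4L, 10L))
  org <- map_genomic_origins(lib, genome)
  w <- attribute_to_clusters(org, clusters, lib)
  expect_equal(w$weight[w$pirna == s1 & w$cluster_id == "piC1"], 1)
  expect_equal(w$weight[w$pirna == s2 & w$cluster_id == "piC1"], 0.5)
  expect_equal(w$weight[w$pirna == s2 & w$cluster_id == "unassigned"], 0.5)
  # per-species weights always sum to one, so total mass is conserved
  counts <- stats::setNames(lib$records$count, lib$records$seq)
  expect_equal(sum(w$weight * counts[w$pirna]), lib$total_reads)
  # overlapping annotations of different ids are a configuration error
  bad <- rbind(clusters,
               data.frame(cluster_id = "piC2", chrom = "chr1",
                          start = 200L, end = 600L, strand = "+"))
  expect_error(attribute_to_clusters(org, bad, lib), "configuration error")
})

test_that("attribution is invariant under renaming and translation", {
  cfg <- small_config(seed = 31)
  sim <- simulate_genome(cfg)
  pir <- simulate_pirna_library(sim)
  org <- map_genomic_origins(pir$lib, sim$genome)
  w1 <- attribute_to_clusters(org, sim$clusters, pir$lib)
  shift <- 5000L
  org2 <- org
  org2$chrom <- "contig_Z"; org2$start <- org2$start + shift
  org2$end <- org2$end + shift
  cl2 <- sim$clusters
  cl2$chrom <- "contig_Z"; cl2$start <- cl2$start + shift
  cl2$end <- cl2$end + shift
  w2 <- attribute_to_clusters(org2, cl2, pir$lib)
  o1 <- w1[order(w1$pirna, w1$cluster_id), ]
  o2 <- w2[order(w2$pirna, w2$cluster_id), ]
  expect_equal(o1$weight, o2$weight)
  expect_identical(o1$cluster_id, o2$cluster_id)
})

test_that("regulon calls report dominance, ties and thresholds", {
  mk_hit <- function(s, g) data.frame(pirna = s, gene_id = g, start = 0L,
                                      end = 20L, mismatches = 0L,
                                      mismatch_core_pos = NA,
                                      cleavage_site = 10L)
  set.seed(26)
  s <- vapply(1:3, function(i) oracle_random_dna(28), "")
  lib <- tiny_lib(s, counts = c(81L, 10L, 9L))
  hits <- do.call(rbind, lapply(s, mk_hit, g = "geneX"))
  w <- data.frame(pirna = s, cluster_id = c("piC1", "piC2", "unassigned"),
                  weight = 1)
  reg <- call_regulons(hits, w, lib)
  expect_identical(reg$dominant_cluster, "piC1")
  expect_equal(reg$dominant_fraction, 0.81)
  expect_true(reg$one_to_one)
  # exact tie: lexicographically smaller id wins, flag unset below 0.5
  lib2 <- tiny_lib(s, counts = c(40L, 40L, 20L))
  reg2 <- call_regulons(hits, w, lib2)
  expect_identical(reg2$dominant_cluster, "piC1")
  expect_equal(reg2$dominant_fraction, 0.40)
  expect_false(reg2$one_to_one)
})

test_that("tiled coverage matches a per-position tally and scales to rpm", {
  set.seed(25)
  s <- oracle_random_dna(28)
  filler <- oracle_random_dna(30)
  org <- data.frame(pirna = s, chrom = "chr1", start = 150L, end = 178L,
                    strand = "+")
  lib1k <- tiny_lib(c(s, filler), counts = c(10L, 990L))
  tc <- tiled_coverage(org, lib1k, tile = 100L)
  expect_equal(tc$tile_start, 100L)
  expect_equal(tc$rpm, 10 * 1e6 / 1000)
  expect_error(tiled_coverage(org, lib1k, tile = 0L), "parameter error")
  # random origin set vs a brute-force per-position tally
  seqs <- vapply(1:40, function(i) oracle_random_dna(28), "")
  libR <- tiny_lib(seqs, counts = sample(1:50, 40, replace = TRUE))
  starts <- sample(0:2000, 40, replace = TRUE)
  orgR <- data.frame(pirna = seqs, chrom = "chr1", start = starts,
                     end = starts + 28L,
                     strand = sample(c("+", "-"), 40, replace = TRUE))
  tcR <- tiled_coverage(orgR, libR, tile = 100L)
  counts <- stats::setNames(libR$records$count, libR$records$seq)
  for (i in seq_len(nrow(tcR))) {
    sel <- orgR$strand == tcR$strand[i] &
      orgR$start >= tcR$tile_start[i] & orgR$start < tcR$tile_end[i]
    expect_equal(tcR$rpm[i],
                 sum(counts[orgR$pirna[sel]]) * 1e6 / libR$total_reads)
  }
})

test_that("cluster expression ranks clusters and applies the percentile cut", {
  seqs <- vapply(1:10, function(i) oracle_random_dna(28), "")
  lib <- tiny_lib(seqs, counts = 1:10)
  w <- data.frame(pirna = seqs,
                  cluster_id = sprintf("piC%02d", 1:10), weight = 1)
  ce <- cluster_expression(w, lib, percentile = 0.90)
  expect_identical(ce$top, "piC10")
  expect_equal(ce$table$rpm[ce$table$cluster_id == "piC10"],
               10 * 1e6 / lib$total_reads)
  w0 <- data.frame(pirna = seqs, cluster_id = "unassigned", weight = 1)
  expect_warning(ce0 <- cluster_expression(w0, lib), "empty top-cluster")
  expect_length(ce0$top, 0L)
})
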