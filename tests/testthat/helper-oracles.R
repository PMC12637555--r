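# Independent brute-force oracles and tiny fixture builders. These are
# deliberately naive (character loops, gregexpr) so they share no code
# path with the package implementations they check.

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, NULL)[[1]]]), collapse = "")
}

oracle_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exhaustive windowed Hamming scan of one guide against one mRNA.
oracle_scan_one <- function(pirna, mrna, max_mm = 1) {
  if (nchar(pirna) < 21) return(NULL)
  q <- strsplit(oracle_revcomp(substr(pirna, 2, 21)), NULL)[[1]]
  L <- nchar(mrna)
  if (L < 20) return(NULL)
  ms <- strsplit(mrna, NULL)[[1]]
  rows <- list()
  for (p in 0:(L - 20)) {
    mm <- sum(ms[(p + 1):(p + 20)] != q)
    if (mm <= max_mm)
      rows[[length(rows) + 1]] <- data.frame(start = p, mismatches = mm)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# Exhaustive scan of a library against a set of models; returns the
# canonical (pirna, gene_id, start, mismatches) key table, sorted.
oracle_scan_lib <- function(lib, models, max_mm = 1) {
  rows <- list()
  for (i in seq_len(nrow(lib$records))) {
    s <- lib$records$seq[i]
    if (nchar(s) < 21) next
    for (m in models) {
      h <- oracle_scan_one(s, m$mature_seq, max_mm)
      if (!is.null(h))
        rows[[length(rows) + 1]] <- data.frame(
          pirna = s, gene_id = m$gene_id, start = h$start,
          mismatches = h$mismatches, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pirna = character(0), gene_id = character(0),
               start = integer(0), mismatches = integer(0))
  out[order(out$pirna, out$gene_id, out$start), , drop = FALSE]
}

hit_key <- function(hits) {
  h <- hits[order(hits$pirna, hits$gene_id, hits$start),
            c("pirna", "gene_id", "start", "mismatches"), drop = FALSE]
  rownames(h) <- NULL
  h
}

# All exact occurrences of seq in genome (both strands) via gregexpr.
oracle_find_exact <- function(seq, genome) {
  rows <- list()
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seq else oracle_revcomp(seq)
      m <- gregexpr(pat, genome[[chrom]], fixed = TRUE)[[1]]
      if (m[1] == -1) next
      for (p in as.integer(m))
        rows[[length(rows) + 1]] <- data.frame(
          pirna = seq, chrom = chrom, start = p - 1L,
          end = p - 1L + nchar(seq), strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# Single-exon model on a given chromosome slice.
simple_model <- function(gene, chrom, start, end, genome, strand = "+",
                         cds = NULL) {
  build_mature_transcript(
    genome, transcript_model(gene, paste0(gene, "_t1"), chrom, strand,
                             start, end, cds_span = cds))
}

# A tiny library straight from sequences/counts without length filtering
# surprises (window chosen to keep everything).
tiny_lib <- function(seqs, counts = NULL) {
  collapse_reads(seqs, counts, min_len = min(nchar(seqs)),
                 max_len = max(nchar(seqs)))
}

# A small but complete simulated dataset for integration-style tests.
small_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, genome_size = 150000L, n_genes = 10L,
         n_clusters = 3L,
         pgf_plans = list(pgf_plan(1L, 1L, divergence = 0.05)),
         n_species = 1200L, depth = 40000L),
    list(...))
  do.call(simulation_config, args)
}
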