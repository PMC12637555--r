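# Pseudogene-fragment discovery: iterative masked local alignment of
# cluster sequences against mature mRNAs, collinear chaining, fragment
# anatomy (exon composition, processing, 5' truncation) and target-site
# duplication detection; pairwise cluster identity for cross-species
# comparison.
#
# Scoring defaults (+2 match, -3 mismatch, gap open 5, gap extend 2) are
# tuned for high-identity fragment detection.

.pgf_submat <- function(match = 2, mismatch = -3) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- -1e6
  m[, "N"] <- -1e6
  m
}

# Iterative masked best-local-alignment block finder. Returns a data.table
# of blocks in pattern/subject coordinates (0-based half-open).
local_blocks <- function(pat, sub, min_block_identity = 0.8,
                         min_block_len = 50L, max_blocks = 8L,
                         match = 2, mismatch = -3,
                         gap_open = 5, gap_ext = 2) {
  sm <- .pgf_submat(match, mismatch)
  sub_d <- Biostrings::DNAString(sub)
  blocks <- list()
  for (iter in seq_len(max_blocks)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(pat), subject = sub_d,
      type = "local", substitutionMatrix = sm,
      gapOpening = gap_open, gapExtension = gap_ext)
    pa <- Biostrings::pattern(aln)
    sa <- Biostrings::subject(aln)
    alen <- nchar(as.character(pa))
    if (alen == 0L || Biostrings::score(aln) <= 0) break
    matches <- Biostrings::nmatch(aln)
    mism <- Biostrings::nmismatch(aln)
    if (alen < min_block_len || matches / alen < min_block_identity) break
    ps <- Biostrings::start(pa); pe <- Biostrings::end(pa)
    ss <- Biostrings::start(sa); se <- Biostrings::end(sa)
    blocks[[length(blocks) + 1L]] <- data.table::data.table(
      p_start = ps - 1L, p_end = pe,
      s_start = ss - 1L, s_end = se,
      matches = matches, mismatches = mism,
      aln_len = alen, gaps = alen - matches - mism,
      score = Biostrings::score(aln))
    substr(pat, ps, pe) <- strrep("N", pe - ps + 1L)
  }
  if (length(blocks) == 0L)
    return(data.table::data.table(p_start = integer(0), p_end = integer(0),
                                  s_start = integer(0), s_end = integer(0),
                                  matches = integer(0), mismatches = integer(0),
                                  aln_len = integer(0), gaps = integer(0),
                                  score = numeric(0)))
  data.table::rbindlist(blocks)
}

# Best strictly collinear chain (both coordinates increasing,
# non-overlapping) maximizing total matches. Returns row indices.
chain_blocks <- function(bl) {
  n <- nrow(bl)
  if (n == 0L) return(integer(0))
  o <- order(bl$p_start, bl$s_start)
  b <- bl[o]
  best <- b$matches
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (b$p_end[j] <= b$p_start[i] && b$s_end[j] <= b$s_start[i] &&
          best[j] + b$matches[i] > best[i]) {
        best[i] <- best[j] + b$matches[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  chain <- integer(0)
  while (i != 0L) {
    chain <- c(i, chain)
    i <- prev[i]
  }
  o[chain]
}

#' Align a cluster sequence to a mature mRNA
#'
#' Finds high-identity local alignment blocks on both cluster strands
#' against the mRNA, chains them collinearly, and reports the best chain
#' with its overall identity (total matches over total alignment columns).
#'
#' @param cluster_seq Cluster genomic sequence (plus strand).
#' @param mrna_seq Mature mRNA sequence.
#' @param min_block_identity,min_block_len Per-block acceptance thresholds.
#' @param max_blocks Maximum blocks recovered per orientation.
#' @param match,mismatch,gap_open,gap_ext Alignment scoring parameters.
#' @param orientations Orientations to scan (default both).
#' @return `NULL` when no qualifying block exists; otherwise a list with
#'   `orientation` (`"same"`: the mRNA sense sequence lies on the cluster
#'   plus strand; `"antisense"` otherwise), `blocks` (chained blocks,
#'   cluster coordinates always on the plus strand), `identity`,
#'   `matches`, `aln_len`, `mrna_aligned` (total aligned mRNA nt),
#'   `cluster_span` and `mrna_span`.
#' @export
align_cluster_to_mrna <- function(cluster_seq, mrna_seq,
                                  min_block_identity = 0.8,
                                  min_block_len = 50L, max_blocks = 8L,
                                  match = 2, mismatch = -3,
                                  gap_open = 5, gap_ext = 2,
                                  orientations = c("same", "antisense")) {
  stopifnot(nzchar(cluster_seq), nzchar(mrna_seq))
  L <- nchar(cluster_seq)
  best <- NULL
  for (orientation in orientations) {
    pat <- if (orientation == "same") cluster_seq else revcomp(cluster_seq)
    bl <- local_blocks(pat, mrna_seq, min_block_identity, min_block_len,
                       max_blocks, match, mismatch, gap_open, gap_ext)
    idx <- chain_blocks(bl)
    if (length(idx) == 0L) next
    ch <- bl[idx]
    if (orientation == "antisense") {
      tmp <- L - ch$p_end
      ch[, "p_end" := L - ch$p_start]
      ch[, "p_start" := tmp]
      data.table::setorderv(ch, "p_start")
    }
    cand <- list(orientation = orientation, blocks = as.data.frame(ch),
                 identity = sum(ch$matches) / sum(ch$aln_len),
                 matches = sum(ch$matches), aln_len = sum(ch$aln_len),
                 mrna_aligned = sum(ch$s_end - ch$s_start),
                 cluster_span = c(min(ch$p_start), max(ch$p_end)),
                 mrna_span = c(min(ch$s_start), max(ch$s_end)))
    if (is.null(best) || cand$matches > best$matches) best <- cand
  }
  best
}

#' Detect a target-site duplication flanking an insertion
#'
#' Searches for a pair of near-identical substrings, one ending within
#' `search_window` nt upstream of the insertion start and one beginning
#' within `search_window` nt downstream of the insertion end. Mismatches
#' (up to `max_mm`) are only permitted for candidates of at least
#' `mm_min_len` nt; shorter duplications must match exactly, which keeps
#' the false-positive rate on random flanks low. Candidates are ranked by
#' length minus `mm_penalty` nt per mismatch - a mismatch must therefore
#' buy more than `mm_penalty` extra nucleotides of duplication, which
#' prevents an exact duplication from being displaced by a marginally
#' longer, mismatched extension into flanking context - then by fewer
#' mismatches, then by proximity to the insertion boundaries. The
#' returned substrings never overlap the insertion interval.
#'
#' @param chrom_seq Chromosome sequence containing the insertion.
#' @param ins_start,ins_end Insertion interval (0-based half-open).
#' @param min_len,max_len TSD length bounds (defaults 8-25 nt, typical of
#'   LINE-mediated insertions).
#' @param max_mm Mismatch tolerance (default 1).
#' @param mm_min_len Minimum length at which mismatches are allowed
#'   (default 12).
#' @param mm_penalty Ranking penalty per mismatch, in nt (default 4).
#' @param search_window Flank width searched on each side (default 30).
#' @return `NULL` if no qualifying duplication; otherwise a list with
#'   `seq` (upstream copy), `left_start`, `left_end`, `right_start`,
#'   `right_end`, `length`, `mismatches`.
#' @export
detect_tsd <- function(chrom_seq, ins_start, ins_end,
                       min_len = 8L, max_len = 25L, max_mm = 1L,
                       mm_min_len = 12L, mm_penalty = 4L,
                       search_window = 30L) {
  L <- nchar(chrom_seq)
  if (ins_start - search_window - max_len < 0L ||
      ins_end + search_window + max_len > L) {
    warning("insufficient flank around insertion; no TSD call")
    return(NULL)
  }
  cands <- list()
  for (len in seq(max_len, min_len)) {
    left_end <- (ins_start - search_window):ins_start      # 0-based end (exclusive)
    right_start <- ins_end:(ins_end + search_window)       # 0-based start
    lefts <- substring(chrom_seq, left_end - len + 1L, left_end)
    rights <- substring(chrom_seq, right_start + 1L, right_start + len)
    mm <- hamming_cross(lefts, rights)
    budget <- if (len >= mm_min_len) max_mm else 0L
    hit <- which(mm <= budget, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    li <- hit[, 1L]; ri <- hit[, 2L]
    cands[[length(cands) + 1L]] <- data.frame(
      len = len, mm = mm[hit],
      left_end = left_end[li], right_start = right_start[ri],
      seq = lefts[li], stringsAsFactors = FALSE)
  }
  if (length(cands) == 0L) return(NULL)
  cd <- do.call(rbind, cands)
  cd$score <- cd$len - mm_penalty * cd$mm
  cd$prox <- (ins_start - cd$left_end) + (cd$right_start - ins_end)
  cd <- cd[order(-cd$score, cd$mm, cd$prox), , drop = FALSE]
  best <- cd[1L, ]
  list(seq = best$seq,
       left_start = best$left_end - best$len, left_end = best$left_end,
       right_start = best$right_start, right_end = best$right_start + best$len,
       length = best$len, mismatches = as.integer(best$mm))
}

# Count distinct shared k-mers between two sequences (either orientation
# of a); cheap prescreen before alignment.
shared_kmers <- function(a_kmers, b, k = 12L) {
  Lb <- nchar(b)
  if (Lb < k) return(0L)
  pos <- 0L:(Lb - k)
  bk <- unique(substring(b, pos + 1L, pos + k))
  sum(bk %in% a_kmers)
}

#' Call pseudogene fragments inside piRNA clusters
#'
#' For every cluster x gene pair passing a shared k-mer prescreen, aligns
#' the cluster (both strands) to the gene's mature mRNA, chains collinear
#' blocks, and promotes chains meeting identity and span thresholds to
#' pseudogene-fragment (PGF) calls with exon composition, processing
#' status, 5' truncation and TSD annotation.
#'
#' @param genome Named character vector from [read_genome()].
#' @param clusters Cluster data.frame from [read_cluster_bed()].
#' @param models Representative `transcript_model`s with mature sequences.
#' @param min_identity Minimum overall chain identity (default 0.80).
#' @param min_span Minimum total aligned mRNA length in nt (default 200).
#' @param truncation_margin mRNA 5' offset beyond which a fragment is
#'   flagged 5'-truncated (default 50 nt).
#' @param min_block_identity,min_block_len Per-block thresholds.
#' @param min_exon_overlap Minimum block overlap (nt) for an exon to count
#'   as covered (default 10).
#' @param intron_margin Minimum intronic alignment (nt) for the
#'   partly-processed call (default 30).
#' @param tsd_boundary_trim Shrink applied to the estimated insertion
#'   interval before the TSD search, absorbing local-alignment end wobble
#'   (default 3 nt).
#' @param prescreen_k,prescreen_min Shared k-mer prescreen parameters.
#' @param ... Further arguments passed to [align_cluster_to_mrna()].
#' @return data.frame with one row per PGF call: cluster and parental gene
#'   ids, genomic insertion interval, orientation, identity, block and
#'   exon composition, `processed`, `five_prime_truncated`,
#'   `pirna_antisense` (fragment antisense to the cluster's transcribed
#'   strand, hence piRNAs complementary to the mRNA), and TSD fields.
#' @export
call_pgfs <- function(genome, clusters, models,
                      min_identity = 0.80, min_span = 200L,
                      truncation_margin = 50L,
                      min_block_identity = 0.8, min_block_len = 50L,
                      min_exon_overlap = 10L, intron_margin = 30L,
                      tsd_boundary_trim = 3L,
                      prescreen_k = 12L, prescreen_min = 8L, ...) {
  merged <- merge_clusters(clusters)
  strands <- tapply(clusters$strand, clusters$cluster_id, function(s) s[1L])
  calls <- list()
  for (ci in seq_len(nrow(merged))) {
    cl_id <- merged$cluster_id[ci]
    cl_chrom <- merged$chrom[ci]
    cl_start <- merged$start[ci]; cl_end <- merged$end[ci]
    cl_seq <- substring(genome[[cl_chrom]], cl_start + 1L, cl_end)
    Lc <- nchar(cl_seq)
    pos <- 0L:(Lc - prescreen_k)
    k_fwd <- unique(substring(cl_seq, pos + 1L, pos + prescreen_k))
    k_rc <- unique(substring(revcomp(cl_seq), pos + 1L, pos + prescreen_k))
    for (m in models) {
      ors <- c("same", "antisense")[c(
        shared_kmers(k_fwd, m$mature_seq, prescreen_k) >= prescreen_min,
        shared_kmers(k_rc, m$mature_seq, prescreen_k) >= prescreen_min)]
      if (length(ors) == 0L) next
      ch <- align_cluster_to_mrna(cl_seq, m$mature_seq,
                                  min_block_identity = min_block_identity,
                                  min_block_len = min_block_len,
                                  orientations = ors, ...)
      if (is.null(ch)) next
      if (ch$identity < min_identity || ch$mrna_aligned < min_span) next
      # exon composition
      widths <- m$exon_ends - m$exon_starts
      if (m$strand == "-") widths <- rev(widths)
      cum <- cumsum(c(0L, widths))
      covered <- integer(0)
      for (e in seq_along(widths)) {
        ov <- sum(pmax(0L, pmin(ch$blocks$s_end, cum[e + 1L]) -
                         pmax(ch$blocks$s_start, cum[e])))
        if (ov >= min(min_exon_overlap, widths[e])) covered <- c(covered, e)
      }
      truncated <- ch$mrna_span[1L] > truncation_margin
      # processing status: re-align the insert region against the
      # unspliced parental locus and look for intronic alignment
      ins_lo <- max(0L, ch$cluster_span[1L] - 50L)
      ins_hi <- min(Lc, ch$cluster_span[2L] + 50L)
      insert_seq <- substring(cl_seq, ins_lo + 1L, ins_hi)
      gseq <- substring(genome[[m$chrom]], m$start + 1L, m$end)
      if (m$strand == "-") gseq <- revcomp(gseq)
      ug <- align_cluster_to_mrna(insert_seq, gseq,
                                  min_block_identity = min_block_identity,
                                  min_block_len = min(min_block_len, 40L), ...)
      processed <- TRUE
      if (!is.null(ug)) {
        # exon intervals on the sense-oriented unspliced locus
        glen <- m$end - m$start
        if (m$strand == "+") {
          ex_s <- m$exon_starts - m$start; ex_e <- m$exon_ends - m$start
        } else {
          ex_s <- glen - (m$exon_ends - m$start)
          ex_e <- glen - (m$exon_starts - m$start)
          o <- order(ex_s); ex_s <- ex_s[o]; ex_e <- ex_e[o]
        }
        n_ex <- length(ex_s)
        intron_ov <- 0L
        if (n_ex > 1L) {
          for (i in seq_len(n_ex - 1L)) {
            intron_ov <- intron_ov + sum(pmax(0L,
              pmin(ug$blocks$s_end, ex_s[i + 1L]) - pmax(ug$blocks$s_start, ex_e[i])))
          }
        }
        processed <- intron_ov < intron_margin
      }
      # genomic insertion interval and TSD
      g_ins_start <- cl_start + ch$cluster_span[1L]
      g_ins_end <- cl_start + ch$cluster_span[2L]
      tsd <- detect_tsd(genome[[cl_chrom]],
                        g_ins_start + tsd_boundary_trim,
                        g_ins_end - tsd_boundary_trim)
      cl_strand <- strands[[cl_id]]
      antisense <- if (cl_strand %in% c("+", "-")) {
        (cl_strand == "+") == (ch$orientation == "antisense")
      } else NA
      calls[[length(calls) + 1L]] <- data.frame(
        cluster_id = cl_id, gene_id = m$gene_id,
        chrom = cl_chrom, ins_start = g_ins_start, ins_end = g_ins_end,
        orientation = ch$orientation, identity = ch$identity,
        matches = ch$matches, aln_len = ch$aln_len,
        mrna_aligned = ch$mrna_aligned,
        mrna_start = ch$mrna_span[1L], mrna_end = ch$mrna_span[2L],
        n_blocks = nrow(ch$blocks),
        exons = paste(covered, collapse = ","),
        processed = processed, five_prime_truncated = truncated,
        pirna_antisense = antisense,
        tsd_seq = if (is.null(tsd)) NA_character_ else tsd$seq,
        tsd_len = if (is.null(tsd)) NA_integer_ else tsd$length,
        tsd_mismatches = if (is.null(tsd)) NA_integer_ else tsd$mismatches,
        tsd_left_start = if (is.null(tsd)) NA_integer_ else tsd$left_start,
        tsd_right_start = if (is.null(tsd)) NA_integer_ else tsd$right_start,
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0L) {
    return(data.frame(cluster_id = character(0), gene_id = character(0)))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Pairwise sequence identity over chained local blocks
#'
#' Identity is total matches over total alignment columns of the best
#' collinear chain; aligned coverage of each input is reported alongside
#' so that identity is interpretable. With no qualifying chain, identity
#' is `NA` and coverage 0.
#'
#' @param seq_a,seq_b Sequences to compare.
#' @param min_block_identity,min_block_len Block thresholds (defaults
#'   0.7 / 100, suited to cluster-scale comparisons).
#' @param ... Passed to [align_cluster_to_mrna()].
#' @return List with `identity` (in `[0, 1]` or NA), `coverage_a`,
#'   `coverage_b`, `orientation`, `matches`, `aln_len`.
#' @export
pairwise_cluster_identity <- function(seq_a, seq_b,
                                      min_block_identity = 0.7,
                                      min_block_len = 100L, ...) {
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  ch <- align_cluster_to_mrna(seq_a, seq_b,
                              min_block_identity = min_block_identity,
                              min_block_len = min_block_len, ...)
  if (is.null(ch)) {
    return(list(identity = NA_real_, coverage_a = 0, coverage_b = 0,
                orientation = NA_character_, matches = 0L, aln_len = 0L))
  }
  list(identity = ch$identity,
       coverage_a = sum(ch$blocks$p_end - ch$blocks$p_start) / nchar(seq_a),
       coverage_b = sum(ch$blocks$s_end - ch$blocks$s_start) / nchar(seq_b),
       orientation = ch$orientation, matches = ch$matches,
       aln_len = ch$aln_len)
}
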