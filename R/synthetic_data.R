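# Synthetic-data generator: genomes with genes and piRNA clusters,
# planted pseudogene fragments (spliced, 5'-truncated, TSD-flanked,
# antisense, with tunable divergence), cluster-emitted piRNA libraries
# with a 1U bias and power-law abundance, and negative-binomial KO/WT
# count matrices with derepression on true targets. Every planted
# feature is recorded in a machine-readable truth manifest.
#
# All randomness flows from the config seed; identical seeds give
# byte-identical outputs.

#' Plan one pseudogene-fragment insertion
#'
#' @param gene Index of the parental gene (into the simulated gene list).
#' @param cluster Index of the host cluster.
#' @param divergence Per-base substitution rate applied to the fragment
#'   (must be < 0.2).
#' @param truncation 5' truncation in nt.
#' @param tsd_len Target-site duplication length (8-20 nt).
#' @param exons Optional contiguous transcript-order exon indices; chosen
#'   automatically when NULL.
#' @param orientation `"antisense"` (default; the fragment yields
#'   mRNA-complementary piRNAs) or `"sense"`.
#' @param include_intron Retain the last intron of the chosen exon run,
#'   producing a partly processed fragment (default FALSE).
#' @return A `pgf_plan` list.
#' @export
pgf_plan <- function(gene, cluster, divergence = 0.05, truncation = 80L,
                     tsd_len = 12L, exons = NULL,
                     orientation = c("antisense", "sense"),
                     include_intron = FALSE) {
  orientation <- match.arg(orientation)
  stopifnot(divergence >= 0, divergence < 0.2,
            tsd_len >= 8L, tsd_len <= 20L, truncation >= 0L)
  structure(list(gene = as.integer(gene), cluster = as.integer(cluster),
                 divergence = divergence, truncation = as.integer(truncation),
                 tsd_len = as.integer(tsd_len), exons = exons,
                 orientation = orientation,
                 include_intron = isTRUE(include_intron)),
            class = "pgf_plan")
}

#' Simulation configuration
#'
#' Defaults describe the emulated regime: a compact genome carrying
#' protein-coding genes and piRNA clusters, three clusters each hosting an
#' antisense pseudogene fragment of a distinct gene, piRNA emission with a
#' 1U bias, 26-31 nt lengths and long-tailed species abundance, a small
#' background of non-cluster piRNAs, and 3-vs-3 negative-binomial KO/WT
#' counts with 3-fold derepression of true targets.
#'
#' @param seed Integer seed driving all stages.
#' @param genome_size,n_chrom Total genome size (bp) and chromosome count.
#' @param n_genes Number of genes.
#' @param exons_per_gene,exon_len,intron_len Ranges (min, max).
#' @param n_clusters,cluster_span Cluster count and span range (bp).
#' @param pgf_plans List of [pgf_plan()]s; default three antisense plans
#'   with divergences 0.05, 0.08 and 0.03.
#' @param cluster_weights Per-cluster emission weights (default equal).
#' @param pirna_len,pirna_len_prob piRNA length support and probabilities.
#' @param u1_bias Probability that a piRNA starts at a U (T) position.
#' @param powerlaw_exponent,powerlaw_cap Pareto tail exponent and cap for
#'   species abundance weights.
#' @param n_species,depth Unique species count and total library reads.
#' @param background_fraction Fraction of species from random non-cluster
#'   loci.
#' @param error_rate Per-base sequencing error rate applied per read.
#' @param nb_mean,nb_meanlog_sd,nb_dispersion Negative-binomial expression
#'   model: per-gene means are log-normal around `nb_mean`.
#' @param derepression_fc KO-condition fold change on true targets.
#' @param n_replicates Replicates per condition.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              genome_size = 500000L, n_chrom = 1L,
                              n_genes = 40L,
                              exons_per_gene = c(2L, 8L),
                              exon_len = c(80L, 400L),
                              intron_len = c(100L, 2000L),
                              n_clusters = 6L,
                              cluster_span = c(5000L, 30000L),
                              pgf_plans = NULL,
                              cluster_weights = NULL,
                              pirna_len = 26:31,
                              pirna_len_prob = c(0.05, 0.10, 0.20, 0.30, 0.25, 0.10),
                              u1_bias = 0.8,
                              powerlaw_exponent = 1.5,
                              powerlaw_cap = 500,
                              n_species = 4000L,
                              depth = 200000L,
                              background_fraction = 0.05,
                              error_rate = 0.001,
                              nb_mean = 200,
                              nb_meanlog_sd = 1,
                              nb_dispersion = 0.05,
                              derepression_fc = 3,
                              n_replicates = 3L) {
  if (is.null(pgf_plans)) {
    pgf_plans <- list(pgf_plan(1L, 1L, divergence = 0.05, truncation = 80L, tsd_len = 12L),
                      pgf_plan(2L, 2L, divergence = 0.08, truncation = 60L, tsd_len = 14L),
                      pgf_plan(3L, 3L, divergence = 0.03, truncation = 100L, tsd_len = 10L))
  }
  if (is.null(cluster_weights)) cluster_weights <- rep(1 / n_clusters, n_clusters)
  stopifnot(length(cluster_weights) == n_clusters,
            all(cluster_weights >= 0), sum(cluster_weights) > 0,
            u1_bias >= 0, u1_bias <= 1,
            background_fraction >= 0, background_fraction < 1,
            error_rate >= 0, error_rate < 1,
            length(pirna_len_prob) == length(pirna_len),
            n_chrom >= 1L)
  pg <- vapply(pgf_plans, `[[`, 0L, "gene")
  pc <- vapply(pgf_plans, `[[`, 0L, "cluster")
  if (anyDuplicated(pg) || anyDuplicated(pc))
    stop("pgf_plans must use distinct genes and distinct clusters")
  if (length(pg) && (max(pg) > n_genes || max(pc) > n_clusters))
    stop("pgf_plan indices out of range")
  structure(list(seed = as.integer(seed), genome_size = as.integer(genome_size),
                 n_chrom = as.integer(n_chrom), n_genes = as.integer(n_genes),
                 exons_per_gene = exons_per_gene, exon_len = exon_len,
                 intron_len = intron_len, n_clusters = as.integer(n_clusters),
                 cluster_span = cluster_span, pgf_plans = pgf_plans,
                 cluster_weights = cluster_weights / sum(cluster_weights),
                 pirna_len = pirna_len, pirna_len_prob = pirna_len_prob,
                 u1_bias = u1_bias, powerlaw_exponent = powerlaw_exponent,
                 powerlaw_cap = powerlaw_cap, n_species = as.integer(n_species),
                 depth = as.integer(depth),
                 background_fraction = background_fraction,
                 error_rate = error_rate, nb_mean = nb_mean,
                 nb_meanlog_sd = nb_meanlog_sd, nb_dispersion = nb_dispersion,
                 derepression_fc = derepression_fc,
                 n_replicates = as.integer(n_replicates)),
            class = "simulation_config")
}

# Sense-oriented intron between transcript-order exons k and k+1.
.sense_intron <- function(gseq, ex_s, ex_e, strand, k) {
  n <- length(ex_s)
  if (strand == "+") {
    substr(gseq, ex_e[k] + 1L, ex_s[k + 1L])
  } else {
    revcomp(substr(gseq, ex_e[n - k] + 1L, ex_s[n - k + 1L]))
  }
}

# Choose a contiguous transcript-order exon run for a PGF plan.
.choose_exon_run <- function(widths_tx, truncation, include_intron,
                             min_frag = 400L) {
  n <- length(widths_tx)
  lo <- if (include_intron) 2L else 1L
  runs <- list()
  for (k in lo:n) for (i in 1:(n - k + 1L)) runs[[length(runs) + 1L]] <- c(i, i + k - 1L)
  runs <- runs[sample.int(length(runs))]
  sizes <- vapply(runs, function(r) sum(widths_tx[r[1L]:r[2L]]), 0L)
  ok <- which(sizes - truncation >= min_frag)
  if (length(ok)) runs[[ok[1L]]] else runs[[which.max(sizes)]]
}

#' Simulate a genome with genes, clusters and planted pseudogene fragments
#'
#' Background sequence is i.i.d. uniform; genes and clusters are placed
#' without overlap, separated by random gaps. For each PGF plan the
#' parental mRNA is spliced, the exon subset taken, 5'-truncated,
#' substitutions applied at the planned rate, the fragment oriented and
#' inserted into its host cluster, and flanked by an exact copy of the
#' insertion-site sequence (the target-site duplication).
#'
#' @param config A [simulation_config()].
#' @return Object of class `pirna_sim`: `genome`, `models` (transcript
#'   models with mature sequences), `clusters`, `cluster_seqs`,
#'   `manifest` (structural truth), `config`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  cw <- config
  # --- genes -----------------------------------------------------------
  genes <- vector("list", cw$n_genes)
  for (g in seq_len(cw$n_genes)) {
    n_ex <- sample(cw$exons_per_gene[1L]:cw$exons_per_gene[2L], 1L)
    ex_w <- sample(cw$exon_len[1L]:cw$exon_len[2L], n_ex, replace = TRUE)
    in_w <- if (n_ex > 1L) sample(cw$intron_len[1L]:cw$intron_len[2L],
                                  n_ex - 1L, replace = TRUE) else integer(0)
    glen <- sum(ex_w) + sum(in_w)
    gseq <- random_dna(glen)
    ex_s <- cumsum(c(0L, utils::head(ex_w, -1L) + in_w))
    ex_e <- ex_s + ex_w
    strand <- sample(c("+", "-"), 1L)
    mature <- paste(substring(gseq, ex_s + 1L, ex_e), collapse = "")
    if (strand == "-") mature <- revcomp(mature)
    tlen <- nchar(mature)
    utr5 <- max(30L, round(0.15 * tlen)); utr3 <- max(50L, round(0.25 * tlen))
    if (tlen - utr5 - utr3 < 60L) { utr5 <- 10L; utr3 <- 10L }
    genes[[g]] <- list(gene_id = sprintf("gene%03d", g),
                       transcript_id = sprintf("tx%03d", g),
                       seq = gseq, strand = strand, len = glen,
                       ex_s = ex_s, ex_e = ex_e, mature = mature,
                       cds = c(utr5, tlen - utr3))
  }
  # --- clusters --------------------------------------------------------
  clus <- vector("list", cw$n_clusters)
  for (c in seq_len(cw$n_clusters)) {
    span <- sample(cw$cluster_span[1L]:cw$cluster_span[2L], 1L)
    clus[[c]] <- list(cluster_id = sprintf("piC%02d", c),
                      seq = random_dna(span),
                      strand = sample(c("+", "-"), 1L))
  }
  # --- plant PGFs ------------------------------------------------------
  pgfs <- list()
  for (plan in cw$pgf_plans) {
    gn <- genes[[plan$gene]]
    widths <- gn$ex_e - gn$ex_s
    widths_tx <- if (gn$strand == "+") widths else rev(widths)
    cum <- cumsum(c(0L, widths_tx))
    run <- if (is.null(plan$exons)) {
      .choose_exon_run(widths_tx, plan$truncation, plan$include_intron)
    } else c(min(plan$exons), max(plan$exons))
    e1 <- run[1L]; e2 <- run[2L]
    if (!plan$include_intron) {
      frag0 <- substr(gn$mature, cum[e1] + 1L, cum[e2 + 1L])
      segs <- data.frame(f_start = 0L, f_end = nchar(frag0), mrna_start = cum[e1])
    } else {
      part1 <- substr(gn$mature, cum[e1] + 1L, cum[e2])
      intr <- .sense_intron(gn$seq, gn$ex_s, gn$ex_e, gn$strand, e2 - 1L)
      part2 <- substr(gn$mature, cum[e2] + 1L, cum[e2 + 1L])
      frag0 <- paste0(part1, intr, part2)
      w1 <- nchar(part1); wi <- nchar(intr); w2 <- nchar(part2)
      segs <- data.frame(
        f_start = c(0L, w1, w1 + wi),
        f_end = c(w1, w1 + wi, w1 + wi + w2),
        mrna_start = c(cum[e1], NA_integer_, cum[e2]))
    }
    tr <- min(plan$truncation, nchar(frag0) - 200L)
    frag <- substr(frag0, tr + 1L, nchar(frag0))
    segs$f_start <- segs$f_start - tr; segs$f_end <- segs$f_end - tr
    segs$mrna_start <- ifelse(is.na(segs$mrna_start), NA_integer_,
                              segs$mrna_start + pmax(0L, -segs$f_start))
    segs$f_start <- pmax(0L, segs$f_start)
    segs <- segs[segs$f_end > segs$f_start, , drop = FALSE]
    nf <- nchar(frag)
    sub_pos <- which(stats::runif(nf) < plan$divergence)
    frag_m <- substitute_bases(frag, sub_pos)
    cl <- clus[[plan$cluster]]
    want_rc_on_plus <- (plan$orientation == "antisense")
    ginsert <- if (cl$strand == "+") {
      if (want_rc_on_plus) revcomp(frag_m) else frag_m
    } else {
      if (want_rc_on_plus) frag_m else revcomp(frag_m)
    }
    S0 <- nchar(cl$seq)
    tl <- plan$tsd_len
    ni <- nchar(ginsert)
    # choose an insertion site whose flanking context cannot extend the
    # duplication (the base before the duplicated site must differ from
    # the insert's last base, and the base after it from the insert's
    # first base), so the planted TSD is locally unambiguous
    i_first <- substr(ginsert, 1L, 1L)
    i_last <- substr(ginsert, ni, ni)
    p0 <- sample(500L:(S0 - 500L), 1L)
    for (try in 1:50) {
      if (substr(cl$seq, p0, p0) != i_last &&
          substr(cl$seq, p0 + tl + 1L, p0 + tl + 1L) != i_first) break
      p0 <- sample(500L:(S0 - 500L), 1L)
    }
    tsd_seq <- substr(cl$seq, p0 + 1L, p0 + tl)
    clus[[plan$cluster]]$seq <- paste0(
      substr(cl$seq, 1L, p0 + tl), ginsert, tsd_seq,
      substr(cl$seq, p0 + tl + 1L, S0))
    pgfs[[length(pgfs) + 1L]] <- list(
      cluster = plan$cluster, gene = plan$gene,
      cluster_id = cl$cluster_id, gene_id = gn$gene_id,
      exons = e1:e2, divergence = plan$divergence,
      truncation = tr, orientation = plan$orientation,
      include_intron = plan$include_intron,
      genomic_orientation = if (nzchar(ginsert) &&
                                identical(ginsert, revcomp(frag_m)))
        "antisense" else "same",
      frag_len = nf, n_subs = length(sub_pos), sub_pos = sub_pos,
      segments = segs, tsd_seq = tsd_seq, tsd_len = tl,
      ins_local = c(p0 + tl, p0 + tl + ni))
  }
  # --- placement -------------------------------------------------------
  feats <- c(lapply(genes, function(g)
    list(kind = "gene", id = g$gene_id, len = g$len)),
    lapply(clus, function(c)
      list(kind = "cluster", id = c$cluster_id, len = nchar(c$seq))))
  ord <- sample.int(length(feats))
  chrom_of <- rep(seq_len(cw$n_chrom), length.out = length(ord))
  per_chrom <- cw$genome_size %/% cw$n_chrom
  genome <- character(cw$n_chrom)
  names(genome) <- sprintf("chr%d", seq_len(cw$n_chrom))
  starts <- stats::setNames(integer(length(feats)),
                            vapply(feats, `[[`, "", "id"))
  chroms <- starts
  for (ch in seq_len(cw$n_chrom)) {
    idx <- ord[chrom_of == ch]
    lens <- vapply(feats[idx], `[[`, 0L, "len")
    gap_total <- per_chrom - sum(lens)
    if (gap_total < 100L * (length(idx) + 1L))
      stop("config error: genome too small for the requested features")
    gaps <- as.vector(stats::rmultinom(1L, gap_total,
                                       rep(1, length(idx) + 1L)))
    pieces <- character(2L * length(idx) + 1L)
    pos <- 0L
    pieces[1L] <- random_dna(gaps[1L]); pos <- gaps[1L]
    for (i in seq_along(idx)) {
      f <- feats[[idx[i]]]
      seq <- if (f$kind == "gene")
        genes[[which(vapply(genes, `[[`, "", "gene_id") == f$id)]]$seq
      else clus[[which(vapply(clus, `[[`, "", "cluster_id") == f$id)]]$seq
      starts[f$id] <- pos
      chroms[f$id] <- ch
      pieces[2L * i] <- seq
      pieces[2L * i + 1L] <- random_dna(gaps[i + 1L])
      pos <- pos + f$len + gaps[i + 1L]
    }
    genome[ch] <- paste(pieces, collapse = "")
  }
  chrom_names <- names(genome)
  # --- assemble models, clusters, manifest -----------------------------
  models <- list()
  man_genes <- list()
  for (g in genes) {
    off <- starts[[g$gene_id]]
    chn <- chrom_names[chroms[[g$gene_id]]]
    m <- transcript_model(g$gene_id, g$transcript_id, chn, g$strand,
                          off + g$ex_s, off + g$ex_e, cds_span = g$cds,
                          mature_seq = g$mature)
    models[[g$transcript_id]] <- m
    man_genes[[length(man_genes) + 1L]] <- list(
      gene_id = g$gene_id, chrom = chn, start = off, end = off + g$len,
      strand = g$strand, n_exons = length(g$ex_s),
      mature_len = nchar(g$mature))
  }
  clusters <- data.frame(
    cluster_id = vapply(clus, `[[`, "", "cluster_id"),
    chrom = chrom_names[vapply(clus, function(c) chroms[[c$cluster_id]], 0L)],
    start = vapply(clus, function(c) starts[[c$cluster_id]], 0L),
    end = vapply(clus, function(c) starts[[c$cluster_id]] + nchar(c$seq), 0L),
    strand = vapply(clus, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  man_pgfs <- lapply(pgfs, function(p) {
    off <- starts[[p$cluster_id]]
    p$ins_genomic <- off + p$ins_local
    p$chrom <- chrom_names[chroms[[p$cluster_id]]]
    p$tsd_left <- c(p$ins_genomic[1L] - p$tsd_len, p$ins_genomic[1L])
    p$tsd_right <- c(p$ins_genomic[2L], p$ins_genomic[2L] + p$tsd_len)
    p
  })
  structure(list(genome = genome, models = models, clusters = clusters,
                 cluster_seqs = stats::setNames(
                   vapply(clus, `[[`, "", "seq"),
                   vapply(clus, `[[`, "", "cluster_id")),
                 manifest = list(genes = man_genes, pgfs = man_pgfs,
                                 clusters = clusters,
                                 genome_size = nchar(genome)),
                 config = config),
            class = "pirna_sim")
}

# Sample read start positions with the configured 1U bias: with
# probability u1_bias the start is drawn from T positions, otherwise
# from non-T positions (falling back to any valid start when a pool is
# empty).
.biased_starts <- function(tx, lens, u1) {
  chars <- strsplit(tx, NULL)[[1L]]
  is_t <- chars == "T"
  L <- length(chars)
  out <- integer(length(lens))
  for (len in unique(lens)) {
    idx <- which(lens == len)
    hi <- L - len + 1L
    tp <- which(is_t[seq_len(hi)])
    np <- which(!is_t[seq_len(hi)])
    for (want_t in c(TRUE, FALSE)) {
      sel <- idx[u1[idx] == want_t]
      if (!length(sel)) next
      pool <- if (want_t) tp else np
      if (!length(pool)) pool <- seq_len(hi)
      out[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
    }
  }
  out
}

#' Simulate a collapsed piRNA library from a simulated genome
#'
#' Species are substrings of cluster transcripts (strand per cluster)
#' with the configured length distribution and 1U bias, plus a background
#' of species from random non-cluster loci. Species abundances follow a
#' capped Pareto law scaled to the library depth; per-read sequencing
#' errors are applied before collapsing. The truth manifest records each
#' species' origin, whether it truly targets a planted parental gene
#' (direct comparison of its guide core against the planted mRNA window),
#' and its perfect-origin multiplicity.
#'
#' @param sim A `pirna_sim` from [simulate_genome()].
#' @param seed Seed for the emission stage (default `config$seed + 1`).
#' @return List with `lib` (a `pirna_library`) and `manifest` (emission
#'   truth: `species` table, `planted_regulons`, `emission` summary).
#' @export
simulate_pirna_library <- function(sim, seed = NULL) {
  cw <- sim$config
  set.seed(seed %||% (cw$seed + 1L))
  n_bg <- round(cw$n_species * cw$background_fraction)
  n_cl <- cw$n_species - n_bg
  # cluster transcripts and insert coordinates in transcript space
  ct <- character(cw$n_clusters)
  for (c in seq_len(cw$n_clusters)) {
    s <- sim$cluster_seqs[[c]]
    ct[c] <- if (sim$clusters$strand[c] == "+") s else revcomp(s)
  }
  pgf_by_cluster <- list()
  for (p in sim$manifest$pgfs) {
    Lt <- nchar(ct[p$cluster])
    i0 <- p$ins_local[1L]; i1 <- p$ins_local[2L]
    if (sim$clusters$strand[p$cluster] == "-") {
      tmp <- Lt - i1; i1 <- Lt - i0; i0 <- tmp
    }
    p$ins_tx <- c(i0, i1)
    pgf_by_cluster[[p$cluster]] <- p
  }
  # --- cluster species -------------------------------------------------
  cl_idx <- sample.int(cw$n_clusters, n_cl, replace = TRUE,
                       prob = cw$cluster_weights)
  lens <- sample(cw$pirna_len, n_cl, replace = TRUE, prob = cw$pirna_len_prob)
  u1 <- stats::runif(n_cl) < cw$u1_bias
  starts1 <- integer(n_cl)           # 1-based transcript positions
  for (c in seq_len(cw$n_clusters)) {
    idx <- which(cl_idx == c)
    if (length(idx))
      starts1[idx] <- .biased_starts(ct[c], lens[idx], u1[idx])
  }
  seqs <- substring(ct[cl_idx], starts1, starts1 + lens - 1L)
  # genomic coordinates of each species' emission locus
  cl_start <- sim$clusters$start[cl_idx]
  cl_strandv <- sim$clusters$strand[cl_idx]
  Ltx <- nchar(ct)[cl_idx]
  s0 <- starts1 - 1L
  g_start <- ifelse(cl_strandv == "+", cl_start + s0,
                    cl_start + Ltx - (s0 + lens))
  sp <- data.table::data.table(
    seq = seqs, source = sim$clusters$cluster_id[cl_idx],
    chrom = sim$clusters$chrom[cl_idx],
    start = as.integer(g_start), end = as.integer(g_start + lens),
    strand = cl_strandv, s0 = s0, len = lens, cl = cl_idx)
  # --- background species ---------------------------------------------
  if (n_bg > 0L) {
    allowed <- list()
    for (ch in names(sim$genome)) {
      Lg <- nchar(sim$genome[[ch]])
      cl_ch <- sim$clusters[sim$clusters$chrom == ch, , drop = FALSE]
      cl_ch <- cl_ch[order(cl_ch$start), , drop = FALSE]
      s <- c(0L, cl_ch$end); e <- c(cl_ch$start, Lg)
      keep <- e - s > 40L
      allowed[[ch]] <- data.frame(chrom = ch, start = s[keep], end = e[keep])
    }
    allowed <- do.call(rbind, allowed)
    seg_len <- allowed$end - allowed$start
    bl <- sample(cw$pirna_len, n_bg, replace = TRUE, prob = cw$pirna_len_prob)
    bu <- stats::runif(n_bg) < cw$u1_bias
    bseq <- character(n_bg); bch <- character(n_bg)
    bst <- integer(n_bg); bstr <- character(n_bg)
    for (i in seq_len(n_bg)) {
      for (try in 1:20) {
        seg <- sample.int(nrow(allowed), 1L, prob = seg_len)
        pos <- allowed$start[seg] +
          sample.int(seg_len[seg] - bl[i] + 1L, 1L) - 1L
        strand <- sample(c("+", "-"), 1L)
        s <- substr(sim$genome[[allowed$chrom[seg]]], pos + 1L, pos + bl[i])
        if (strand == "-") s <- revcomp(s)
        if ((substr(s, 1L, 1L) == "T") == bu[i] || try == 20L) break
      }
      bseq[i] <- s; bch[i] <- allowed$chrom[seg]; bst[i] <- pos; bstr[i] <- strand
    }
    sp <- data.table::rbindlist(list(sp, data.table::data.table(
      seq = bseq, source = "background", chrom = bch,
      start = bst, end = bst + bl, strand = bstr,
      s0 = NA_integer_, len = bl, cl = NA_integer_)))
  }
  # --- abundance -------------------------------------------------------
  n_sp <- nrow(sp)
  w <- pmin(stats::runif(n_sp)^(-1 / cw$powerlaw_exponent), cw$powerlaw_cap)
  sp[, "count" := as.vector(stats::rmultinom(1L, cw$depth, w))]
  sp <- sp[sp$count > 0L]
  # --- sequencing errors ----------------------------------------------
  if (cw$error_rate > 0 && nrow(sp) > 0L) {
    p_read <- 1 - (1 - cw$error_rate)^sp$len
    ne <- stats::rbinom(nrow(sp), sp$count, p_read)
    sp[, "count" := sp$count - ne]
    parents <- rep(seq_len(nrow(sp)), ne)
    if (length(parents)) {
      plen <- sp$len[parents]
      pos <- vapply(plen, function(L) sample.int(L, 1L), 0L)
      old <- substr(sp$seq[parents], pos, pos)
      bases <- c("A", "C", "G", "T")
      new <- vapply(old, function(b) sample(setdiff(bases, b), 1L), "")
      eseq <- paste0(substr(sp$seq[parents], 1L, pos - 1L), new,
                     substring(sp$seq[parents], pos + 1L))
      err <- sp[parents]
      err[, "seq" := eseq]
      err[, "count" := 1L]
      err[, c("start", "end", "strand") :=
            list(NA_integer_, NA_integer_, NA_character_)]
      sp <- data.table::rbindlist(list(sp[sp$count > 0L], err))
    } else {
      sp <- sp[sp$count > 0L]
    }
  }
  # --- truth: targeting and perfect-origin multiplicity ----------------
  sp[, "targets_gene" := NA_character_]
  sp[, "parental_perfect" := FALSE]
  gene_mats <- stats::setNames(
    vapply(sim$models, `[[`, "", "mature_seq"),
    vapply(sim$models, `[[`, "", "gene_id"))
  for (p in pgf_by_cluster) {
    if (is.null(p)) next
    i0 <- p$ins_tx[1L]; i1 <- p$ins_tx[2L]
    gid <- p$gene_id
    mature <- gene_mats[[gid]]
    segs <- p$segments
    rows <- which(sp$cl == p$cluster & !is.na(sp$s0) &
                    sp$s0 + 1L >= i0 & sp$s0 + 21L <= i1)
    if (length(rows)) {
      s0 <- sp$s0[rows]
      f_lo <- i1 - s0 - 21L          # fragment coords of the core, 0-based
      seg_i <- rep(NA_integer_, length(rows))
      for (si in seq_len(nrow(segs))) {
        inside <- f_lo >= segs$f_start[si] & f_lo + 20L <= segs$f_end[si] &
          !is.na(segs$mrna_start[si])
        seg_i[inside & is.na(seg_i)] <- si
      }
      okr <- which(!is.na(seg_i))
      if (length(okr)) {
        m_lo <- segs$mrna_start[seg_i[okr]] + (f_lo[okr] - segs$f_start[seg_i[okr]])
        win <- substring(mature, m_lo + 1L, m_lo + 20L)
        qc <- revcomp(substr(sp$seq[rows[okr]], 2L, 21L))
        mm <- hamming_pairs(qc, win)
        tg <- rows[okr][mm <= 1L]
        sp[tg, "targets_gene" := gid]
      }
    }
    # perfect match back to the parental locus (single exon, no
    # substitution, read fully inside the insert)
    rows2 <- which(sp$cl == p$cluster & !is.na(sp$s0) &
                     sp$s0 >= i0 & sp$s0 + sp$len <= i1)
    if (length(rows2)) {
      s0 <- sp$s0[rows2]; lenv <- sp$len[rows2]
      fr_lo <- i1 - s0 - lenv
      seg_i <- rep(NA_integer_, length(rows2))
      for (si in seq_len(nrow(segs))) {
        inside <- fr_lo >= segs$f_start[si] &
          fr_lo + lenv <= segs$f_end[si] & !is.na(segs$mrna_start[si])
        seg_i[inside & is.na(seg_i)] <- si
      }
      okr <- which(!is.na(seg_i))
      if (length(okr)) {
        m_lo <- segs$mrna_start[seg_i[okr]] + (fr_lo[okr] - segs$f_start[seg_i[okr]])
        win <- substring(mature, m_lo + 1L, m_lo + lenv[okr])
        perfect <- revcomp(sp$seq[rows2[okr]]) == win
        # within a single exon of the parental locus
        gmod <- NULL
        for (m in sim$models) if (m$gene_id == gid) gmod <- m
        widths <- gmod$exon_ends - gmod$exon_starts
        if (gmod$strand == "-") widths <- rev(widths)
        cumx <- cumsum(c(0L, widths))
        e_i <- findInterval(m_lo, cumx)
        one_exon <- m_lo + lenv[okr] <= cumx[e_i + 1L]
        sp[rows2[okr][perfect & one_exon], "parental_perfect" := TRUE]
      }
    }
  }
  # background species drawn antisense to a gene exon genuinely target
  # that gene; record them so the truth matches the analysis definition
  sp[, "extra_origins" := 0L]
  plan_by_gene <- stats::setNames(pgf_by_cluster[!vapply(pgf_by_cluster,
                                                         is.null, TRUE)],
                                  vapply(pgf_by_cluster[!vapply(pgf_by_cluster,
                                                                is.null, TRUE)],
                                         `[[`, "", "gene_id"))
  bg_rows <- which(sp$source == "background" & !is.na(sp$start))
  if (length(bg_rows)) {
    for (m in sim$models) {
      cand <- bg_rows[sp$chrom[bg_rows] == m$chrom &
                        sp$start[bg_rows] >= m$start &
                        sp$end[bg_rows] <= m$end]
      if (!length(cand)) next
      for (i in cand) {
        if (sp$strand[i] == "+") {
          fs <- sp$start[i] + 1L; fe <- sp$start[i] + 21L
        } else {
          fs <- sp$end[i] - 21L; fe <- sp$end[i] - 1L
        }
        t1 <- genomic_to_tx(m, fs); t2 <- genomic_to_tx(m, fe - 1L)
        if (is.na(t1) || is.na(t2)) next
        lo <- min(t1, t2)
        if (max(t1, t2) - lo != 19L) next
        win <- substr(m$mature_seq, lo + 1L, lo + 20L)
        qc <- revcomp(substr(sp$seq[i], 2L, 21L))
        if (hamming_pairs(qc, win) <= 1L) {
          sp[i, "targets_gene" := m$gene_id]
          # an exact cis read may also occur verbatim in the planted PGF
          # copy, giving it a second perfect origin inside the cluster
          pl <- plan_by_gene[[m$gene_id]]
          if (!is.null(pl)) {
            ins_seq <- substr(ct[pl$cluster], pl$ins_tx[1L] + 1L,
                              pl$ins_tx[2L])
            if (grepl(sp$seq[i], ins_seq, fixed = TRUE) ||
                grepl(revcomp(sp$seq[i]), ins_seq, fixed = TRUE))
              sp[i, "extra_origins" := 1L]
          }
        }
      }
    }
  }
  sp[, "true_origins" := ifelse(is.na(sp$start), 0L,
                                1L + as.integer(sp$parental_perfect) +
                                  sp$extra_origins)]
  # weight attributed to the host cluster of the gene each species
  # targets: cluster-emitted species carry one origin there, background
  # species only their possible PGF-copy origin
  sp[, "true_cluster_weight" := ifelse(
    sp$true_origins == 0L, 0,
    ifelse(sp$source == "background",
           sp$extra_origins / sp$true_origins, 1 / sp$true_origins))]
  # --- aggregate identical sequences ----------------------------------
  agg <- sp[, list(count = sum(count), source = source[1L],
                   chrom = chrom[1L], start = start[1L], end = end[1L],
                   strand = strand[1L], targets_gene = targets_gene[1L],
                   parental_perfect = parental_perfect[1L],
                   extra_origins = extra_origins[1L],
                   true_origins = true_origins[1L],
                   true_cluster_weight = true_cluster_weight[1L]),
            by = "seq"]
  data.table::setorderv(agg, c("count", "seq"), order = c(-1L, 1L))
  lib <- pirna_library(agg[, c("seq", "count"), with = FALSE],
                       range(cw$pirna_len))
  regs <- list()
  for (p in sim$manifest$pgfs) {
    tg <- agg[!is.na(agg$targets_gene) & agg$targets_gene == p$gene_id]
    denom <- sum(tg$count)
    num <- sum(tg$count * tg$true_cluster_weight)
    regs[[length(regs) + 1L]] <- data.frame(
      gene_id = p$gene_id, cluster_id = p$cluster_id,
      planted_reads = denom,
      planted_share = if (denom > 0) num / denom else NA_real_,
      stringsAsFactors = FALSE)
  }
  emission <- list(
    total_reads = sum(agg$count),
    n_species = nrow(agg),
    cluster_read_fraction = sum(agg$count[agg$source != "background"]) /
      sum(agg$count),
    reads_by_source = as.list(tapply(agg$count, agg$source, sum)))
  list(lib = lib,
       manifest = list(species = as.data.frame(agg),
                       planted_regulons = do.call(rbind, regs),
                       emission = emission))
}

#' Simulate a KO/WT count matrix
#'
#' Per-gene negative-binomial counts with log-normal means; true targets
#' (genes with a planted PGF) have their KO-condition mean multiplied by
#' the derepression fold change.
#'
#' @param sim A `pirna_sim`.
#' @param seed Seed for the expression stage (default `config$seed + 2`).
#' @return List with `counts` (matrix), `conditions` (data.frame) and
#'   `manifest` (per-gene means and true-target flags).
#' @export
simulate_counts <- function(sim, seed = NULL) {
  cw <- sim$config
  set.seed(seed %||% (cw$seed + 2L))
  gene_ids <- vapply(sim$models, `[[`, "", "gene_id")
  n <- length(gene_ids)
  mu <- stats::rlnorm(n, log(cw$nb_mean), cw$nb_meanlog_sd)
  targets <- gene_ids %in% vapply(sim$manifest$pgfs, `[[`, "", "gene_id")
  k <- cw$n_replicates
  size <- 1 / cw$nb_dispersion
  wt <- matrix(stats::rnbinom(n * k, mu = rep(mu, k), size = size), n, k)
  ko_mu <- ifelse(targets, mu * cw$derepression_fc, mu)
  ko <- matrix(stats::rnbinom(n * k, mu = rep(ko_mu, k), size = size), n, k)
  counts <- cbind(wt, ko)
  rownames(counts) <- gene_ids
  colnames(counts) <- c(sprintf("wt_%d", seq_len(k)), sprintf("ko_%d", seq_len(k)))
  conditions <- data.frame(sample = colnames(counts),
                           condition = rep(c("WT", "KO"), each = k),
                           stringsAsFactors = FALSE)
  list(counts = counts, conditions = conditions,
       manifest = list(expression = data.frame(
         gene_id = gene_ids, mu = mu, is_target = targets,
         fold_change = ifelse(targets, cw$derepression_fc, 1),
         stringsAsFactors = FALSE)))
}

#' Simulate a complete dataset
#'
#' Runs [simulate_genome()], [simulate_pirna_library()] and
#' [simulate_counts()], optionally writing the dataset (genome FASTA, gene
#' GTF, cluster BED, collapsed piRNA FASTA, count and condition TSVs, and
#' the truth manifest JSON) to a directory.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory (created if needed).
#' @return List with `sim`, `lib`, `counts`, `conditions`, `manifest`
#'   (structural + emission + expression truth), and `dir`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  sim <- simulate_genome(config)
  pir <- simulate_pirna_library(sim)
  expr <- simulate_counts(sim)
  manifest <- c(sim$manifest, pir$manifest, expr$manifest)
  out <- list(sim = sim, lib = pir$lib, counts = expr$counts,
              conditions = expr$conditions, manifest = manifest, dir = dir)
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

#' Write a simulated dataset to disk
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- dataset$sim
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_transcript_gtf(sim$models, file.path(dir, "genes.gtf"))
  write_cluster_bed(sim$clusters, file.path(dir, "clusters.bed"))
  write_pirna_fasta(dataset$lib, file.path(dir, "pirnas.fa"))
  cdt <- data.table::data.table(gene_id = rownames(dataset$counts),
                                dataset$counts)
  data.table::fwrite(cdt, file.path(dir, "counts.tsv"), sep = "\t")
  data.table::fwrite(dataset$conditions, file.path(dir, "conditions.tsv"),
                     sep = "\t")
  man <- dataset$manifest
  man$pgfs <- lapply(man$pgfs, function(p) {
    p$segments <- as.list(p$segments)
    p
  })
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(dir)
}

#' Validate a written dataset against its truth manifest
#'
#' Re-reads the emitted files and checks key manifest assertions: TSD
#' copies present in the genome at the recorded positions, cluster BED
#' intervals matching the manifest, mature transcript lengths, and
#' library read totals.
#'
#' @param dir Dataset directory written by [simulate_dataset()].
#' @return data.frame of checks with a logical `ok` column; overall
#'   success in the `ok` attribute.
#' @export
validate_manifest <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  genome <- read_genome(file.path(dir, "genome.fa"))
  models <- read_transcript_models(file.path(dir, "genes.gtf"), genome)
  clusters <- read_cluster_bed(file.path(dir, "clusters.bed"))
  lib <- read_pirna_fasta(file.path(dir, "pirnas.fa"))
  checks <- list()
  add <- function(name, ok) checks[[length(checks) + 1L]] <<-
    data.frame(check = name, ok = ok, stringsAsFactors = FALSE)
  tsd_ok <- TRUE
  for (p in man$pgfs) {
    chseq <- genome[[p$chrom]]
    tl <- unlist(p$tsd_left); tr <- unlist(p$tsd_right)
    left <- substr(chseq, tl[1] + 1, tl[2])
    right <- substr(chseq, tr[1] + 1, tr[2])
    tsd_ok <- tsd_ok && identical(left, p$tsd_seq) && identical(right, p$tsd_seq)
  }
  add("tsd_copies_in_genome", tsd_ok)
  mat_ok <- all(vapply(man$genes, function(g) {
    m <- Filter(function(x) x$gene_id == g$gene_id, models)[[1]]
    tx_length(m) == g$mature_len
  }, TRUE))
  add("mature_lengths", mat_ok)
  mc <- man$clusters
  add("cluster_bed_matches",
      nrow(clusters) == length(mc$cluster_id) &&
        all(clusters$cluster_id == unlist(mc$cluster_id)) &&
        all(clusters$start == unlist(mc$start)) &&
        all(clusters$end == unlist(mc$end)))
  add("library_total_reads",
      lib$total_reads == man$emission$total_reads)
  add("library_species_count",
      nrow(lib$records) == man$emission$n_species)
  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$ok)
  out
}
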