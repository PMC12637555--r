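# The targeting engine: antisense matching of piRNA guide cores
# (nucleotides 2-21) against mature mRNAs with at most one mismatch,
# read-weighted target ranking, and coverage/cleavage profiles.
#
# Matching is strict Watson-Crick Hamming matching: G:U wobbles count as
# mismatches and no indels are allowed. piRNA nucleotide 1 is excluded
# from the core, reflecting its non-pairing 1U identity.

#' Extract the guide core (nt 2-21) of a piRNA
#'
#' @param pirna_seq Character vector of piRNA sequences (>= 21 nt each).
#' @return Character vector of 20-nt cores.
#' @export
extract_guide_core <- function(pirna_seq) {
  if (any(nchar(pirna_seq) < 21L))
    stop("piRNA too short for a nt 2-21 guide core (length < 21)")
  substr(pirna_seq, 2L, 21L)
}

# Guide cores for a whole library; species shorter than 21 nt are
# excluded and tallied rather than raising an error.
guide_cores <- function(lib) {
  r <- lib$records
  ok <- nchar(r$seq) >= 21L
  dt <- data.table::data.table(
    pirna = r$seq[ok], count = r$count[ok],
    core = substr(r$seq[ok], 2L, 21L))
  dt[, "query" := revcomp(dt$core)]
  data.table::setattr(dt, "too_short_species", sum(!ok))
  data.table::setattr(dt, "too_short_reads", sum(r$count[!ok]))
  dt
}

#' Build a half-site index over a transcriptome
#'
#' Every 10-mer of every mature mRNA is indexed by exact sequence, so a
#' 20-nt window with at most one mismatch is always reachable through an
#' exact lookup of one of its two 10-mer halves (pigeonhole principle).
#'
#' @param models Named list of `transcript_model` objects with mature
#'   sequences (one representative per gene).
#' @param k Half-site length (default 10; half of the 20-nt core).
#' @return An object of class `target_index`.
#' @export
build_target_index <- function(models, k = 10L) {
  seqs <- vapply(models, `[[`, "", "mature_seq")
  if (anyNA(seqs) || any(!nzchar(seqs)))
    stop("all models must carry mature sequences; run build_mature_transcript()")
  genes <- vapply(models, `[[`, "", "gene_id")
  if (anyDuplicated(genes))
    stop("one representative transcript per gene expected; run select_representative_transcripts()")
  names(seqs) <- genes
  pieces <- lapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[i])
    if (L < k) return(NULL)
    pos <- 0L:(L - k)
    data.table::data.table(kmer = substring(seqs[i], pos + 1L, pos + k),
                           gene_id = genes[i], pos = pos)
  })
  kmers <- data.table::rbindlist(pieces)
  data.table::setkeyv(kmers, "kmer")
  structure(list(kmers = kmers, seqs = seqs,
                 lens = stats::setNames(nchar(seqs), genes), k = k),
            class = "target_index")
}

#' Scan one mRNA with one piRNA guide
#'
#' Reports every 20-nt window of the mRNA whose sense sequence is within
#' `max_mm` mismatches of the reverse complement of the piRNA core
#' (antisense pairing). The predicted cleavage site is recorded as the
#' 0-based transcript index of the nucleotide paired to piRNA nt 11
#' (window start + 10); the scissile phosphate lies at the downstream
#' boundary of that position, between the nucleotides paired to piRNA
#' nt 11 and nt 10.
#'
#' @param pirna_seq One piRNA sequence (>= 21 nt).
#' @param mrna_seq Mature mRNA sequence (>= 20 nt for any hit).
#' @param max_mm Mismatch budget over nt 2-21 (default 1).
#' @return data.frame of hits: `start`, `end` (transcript window),
#'   `mismatches`, `mismatch_core_pos` (1-based within nt 2-21, i.e. 1 =
#'   piRNA nt 2; NA for perfect hits), `cleavage_site`.
#' @export
scan_transcript <- function(pirna_seq, mrna_seq, max_mm = 1L) {
  query <- revcomp(extract_guide_core(pirna_seq))
  L <- nchar(mrna_seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0), mismatch_core_pos = integer(0),
                      cleavage_site = integer(0))
  if (L < 20L) return(empty)
  ti <- utf8ToInt(mrna_seq)
  qi <- utf8ToInt(query)
  nw <- L - 19L
  mm <- integer(nw)
  for (j in 1:20) mm <- mm + (ti[j:(j + nw - 1L)] != qi[j])
  p <- which(mm <= max_mm) - 1L
  if (length(p) == 0L) return(empty)
  mmc <- mm[p + 1L]
  mpos <- rep(NA_integer_, length(p))
  one <- which(mmc == 1L)
  for (i in one) {
    w <- ti[(p[i] + 1L):(p[i] + 20L)]
    mpos[i] <- 21L - which(w != qi)[1L]
  }
  data.frame(start = p, end = p + 20L, mismatches = mmc,
             mismatch_core_pos = mpos, cleavage_site = p + 10L)
}

#' Scan a piRNA library against a transcriptome
#'
#' Indexed antisense scan of every guide core (nt 2-21) against every
#' mature mRNA, allowing up to `max_mm` mismatches. Results are identical
#' to the exhaustive windowed Hamming scan.
#'
#' @param lib A `pirna_library`.
#' @param models Named list of representative `transcript_model`s with
#'   mature sequences.
#' @param max_mm Mismatch budget (0 or 1; the half-site index guarantees
#'   completeness only for `max_mm <= 1`).
#' @param index Optional prebuilt [build_target_index()] result.
#' @return data.frame of hits with columns `pirna` (the piRNA sequence,
#'   which identifies the species), `gene_id`, `start`, `end`,
#'   `mismatches`, `mismatch_core_pos`, `cleavage_site`, `count`.
#' @export
scan_targets <- function(lib, models, max_mm = 1L, index = NULL) {
  stopifnot(max_mm %in% c(0L, 1L))
  if (is.null(index)) index <- build_target_index(models)
  g <- guide_cores(lib)
  empty <- data.frame(pirna = character(0), gene_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), mismatch_core_pos = integer(0),
                      cleavage_site = integer(0), count = integer(0))
  if (nrow(g) == 0L) return(empty)
  valid <- !grepl("[^ACGT]", g$query)
  n_skipped <- sum(!valid)
  g <- g[valid]
  if (nrow(g) == 0L) return(empty)
  k <- index$k
  q1 <- data.table::data.table(kmer = substr(g$query, 1L, k), qid = seq_len(nrow(g)))
  q2 <- data.table::data.table(kmer = substr(g$query, k + 1L, 2L * k), qid = seq_len(nrow(g)))
  c1 <- index$kmers[q1, on = "kmer", nomatch = 0L, allow.cartesian = TRUE]
  c2 <- index$kmers[q2, on = "kmer", nomatch = 0L, allow.cartesian = TRUE]
  c2[, "pos" := c2$pos - k]
  cand <- unique(data.table::rbindlist(list(c1, c2))[, c("gene_id", "pos", "qid"),
                                                     with = FALSE])
  cand <- cand[cand$pos >= 0L & cand$pos + 20L <= index$lens[cand$gene_id]]
  if (nrow(cand) == 0L) {
    out <- empty
  } else {
    win <- substring(index$seqs[cand$gene_id], cand$pos + 1L, cand$pos + 20L)
    qry <- g$query[cand$qid]
    W <- char_matrix(win, 20L)
    Q <- char_matrix(qry, 20L)
    diffs <- W != Q
    mmv <- rowSums(diffs)
    keep <- mmv <= max_mm
    mpos <- rep(NA_integer_, nrow(cand))
    one <- which(keep & mmv == 1L)
    if (length(one)) mpos[one] <- 21L - max.col(diffs[one, , drop = FALSE], "first")
    out <- data.frame(pirna = g$pirna[cand$qid][keep],
                      gene_id = cand$gene_id[keep],
                      start = cand$pos[keep], end = cand$pos[keep] + 20L,
                      mismatches = as.integer(mmv[keep]),
                      mismatch_core_pos = mpos[keep],
                      cleavage_site = cand$pos[keep] + 10L,
                      count = g$count[cand$qid][keep])
    out <- out[order(out$gene_id, out$start, out$pirna), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "too_short_species") <- attr(g, "too_short_species")
  attr(out, "skipped_alphabet") <- n_skipped
  out
}

#' Rank target genes by converging antisense piRNA mass
#'
#' A piRNA species is mRNA-targeting iff it has at least one hit. By
#' default each species contributes its full read count to every gene it
#' hits (`assign = "all"`); `assign = "best"` assigns each species to a
#' single gene (fewest mismatches, then longest covered span, then
#' lexicographic gene id), under which per-gene fractions sum to exactly 1.
#'
#' @param hits Hit table from [scan_targets()].
#' @param lib The `pirna_library` the hits came from.
#' @param mass_threshold Cumulative-fraction threshold defining the
#'   top-target set (default 0.70).
#' @param count_mode `"reads"` (read-weighted, default) or `"species"`
#'   (each species counts once).
#' @param assign `"all"` or `"best"` (see above).
#' @param models Optional representative models; when given, per-gene
#'   target-space length and CDS/UTR read splits are added.
#' @return Object of class `target_ranking`: a list with `table` (one row
#'   per target gene, ranked), `total_targeting`, `targeting_fraction`
#'   (share of library mass that is mRNA-targeting), and the parameters.
#' @export
rank_targets <- function(hits, lib, mass_threshold = 0.70,
                         count_mode = c("reads", "species"),
                         assign = c("all", "best"), models = NULL) {
  count_mode <- match.arg(count_mode)
  assign <- match.arg(assign)
  h <- data.table::as.data.table(hits)
  if (nrow(h) == 0L) {
    warning("no mRNA-targeting piRNAs found; empty ranking")
    return(structure(list(table = data.frame(), total_targeting = 0,
                          targeting_fraction = 0,
                          mass_threshold = mass_threshold,
                          count_mode = count_mode, assign = assign),
                     class = "target_ranking"))
  }
  counts <- stats::setNames(lib$records$count, lib$records$seq)
  if (assign == "best") {
    per <- h[, list(best_mm = min(mismatches),
                    cov = union_length(start, end)),
             by = c("pirna", "gene_id")]
    data.table::setorderv(per, c("pirna", "best_mm", "cov", "gene_id"),
                          order = c(1L, 1L, -1L, 1L))
    sg <- per[, .SD[1L], by = "pirna"][, c("pirna", "gene_id"), with = FALSE]
  } else {
    sg <- unique(h[, c("pirna", "gene_id"), with = FALSE])
  }
  w <- if (count_mode == "reads") counts[sg$pirna] else rep(1, nrow(sg))
  sg[, "w" := w]
  species <- unique(sg$pirna)
  total <- if (count_mode == "reads") sum(counts[species]) else length(species)
  tab <- sg[, list(targeting_reads = sum(w)), by = "gene_id"]
  tab[, "fraction" := tab$targeting_reads / total]
  data.table::setorderv(tab, c("fraction", "gene_id"), order = c(-1L, 1L))
  tab[, "rank" := seq_len(nrow(tab))]
  tab[, "cum_fraction" := cumsum(tab$fraction)]
  top_n <- which(tab$cum_fraction >= mass_threshold)[1L]
  if (is.na(top_n)) top_n <- nrow(tab)
  tab[, "in_top" := tab$rank <= top_n]
  if (!is.null(models)) {
    gmods <- stats::setNames(models, vapply(models, `[[`, "", "gene_id"))
    space <- integer(nrow(tab)); cdsr <- numeric(nrow(tab))
    utr3r <- numeric(nrow(tab)); utr5r <- numeric(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      gid <- tab$gene_id[i]
      prof <- coverage_profile(h[h$gene_id == gid], lib, gmods[[gid]])
      space[i] <- prof$target_space
      cdsr[i] <- prof$region_reads[["CDS"]]
      utr3r[i] <- prof$region_reads[["UTR3"]]
      utr5r[i] <- prof$region_reads[["UTR5"]]
    }
    tab[, c("target_space", "cds_reads", "utr3_reads", "utr5_reads") :=
          list(space, cdsr, utr3r, utr5r)]
  }
  lib_total <- if (count_mode == "reads") lib$total_reads else nrow(lib$records)
  structure(list(table = as.data.frame(tab), total_targeting = total,
                 targeting_fraction = total / lib_total,
                 mass_threshold = mass_threshold,
                 count_mode = count_mode, assign = assign),
            class = "target_ranking")
}

#' @export
print.target_ranking <- function(x, ...) {
  cat(sprintf("<target_ranking> %d target genes; %.3g%% of library mass is mRNA-targeting (%s-weighted, assign=%s)\n",
              nrow(x$table), 100 * x$targeting_fraction, x$count_mode, x$assign))
  if (nrow(x$table)) print(utils::head(x$table, 5L))
  invisible(x)
}

#' Per-nucleotide antisense coverage of one gene
#'
#' @param hits Hit rows for a single gene.
#' @param lib The `pirna_library`.
#' @param model The gene's representative `transcript_model`.
#' @return List with `coverage` (read-weighted per-nt vector over the
#'   mature mRNA), `target_space` (number of positions with coverage > 0),
#'   and `region_reads` (read-weighted hit counts by the region - 5'UTR,
#'   CDS, 3'UTR - containing each predicted cleavage site; NA split when
#'   the model has no CDS).
#' @export
coverage_profile <- function(hits, lib, model) {
  L <- tx_length(model)
  counts <- stats::setNames(lib$records$count, lib$records$seq)
  cov <- numeric(L)
  region_reads <- c(UTR5 = 0, CDS = 0, UTR3 = 0)
  if (nrow(hits) > 0L) {
    d <- numeric(L + 1L)
    w <- counts[hits$pirna]
    for (i in seq_len(nrow(hits))) {
      d[hits$start[i] + 1L] <- d[hits$start[i] + 1L] + w[i]
      d[hits$end[i] + 1L] <- d[hits$end[i] + 1L] - w[i]
    }
    cov <- cumsum(d[seq_len(L)])
    if (!is.null(model$cds_span)) {
      cs <- hits$cleavage_site
      reg <- ifelse(cs < model$cds_span[1L], "UTR5",
                    ifelse(cs < model$cds_span[2L], "CDS", "UTR3"))
      agg <- tapply(w, reg, sum)
      region_reads[names(agg)] <- agg
    } else {
      region_reads[] <- NA_real_
    }
  }
  list(coverage = cov, target_space = sum(cov > 0), region_reads = region_reads)
}

#' Convert a piRNA pool fraction to molecules per cell
#'
#' @param fraction Fraction of the piRNA pool (in `[0, 1]`).
#' @param pool_size_per_cell Total piRNA molecules per cell (user-supplied
#'   literature constant).
#' @return Estimated molecule count (unrounded).
#' @export
molecules_per_cell <- function(fraction, pool_size_per_cell) {
  stopifnot(all(fraction >= 0 & fraction <= 1), pool_size_per_cell > 0)
  fraction * pool_size_per_cell
}
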