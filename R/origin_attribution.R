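# Perfect-match genomic origin mapping, cis/trans classification,
# cluster attribution and one-to-one regulon calls.
#
# Origin mapping is strict: full-length, zero-mismatch occurrences on
# either strand, mirroring the contrast between imperfect mRNA
# complementarity and perfect genomic matches. Multimapped species are
# apportioned equally across their origins.

#' Map perfect genomic origins of every piRNA species
#'
#' @param lib A `pirna_library`.
#' @param genome Named character vector from [read_genome()].
#' @return data.frame of origins: `pirna`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`. Species with zero perfect origins are
#'   listed in the `unplaced` attribute.
#' @export
map_genomic_origins <- function(lib, genome) {
  seqs <- lib$records$seq
  chromsets <- lapply(genome, Biostrings::DNAString)
  pieces <- list()
  for (w in sort(unique(nchar(seqs)))) {
    sub <- seqs[nchar(seqs) == w]
    ns <- length(sub)
    # one dictionary holding forward and reverse-complement queries
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(c(sub, revcomp(sub))))
    for (chrom in names(chromsets)) {
      si <- Biostrings::startIndex(Biostrings::matchPDict(pd, chromsets[[chrom]]))
      n <- lengths(si)
      if (sum(n) == 0L) next
      starts <- unlist(si, use.names = FALSE) - 1L
      qi <- rep(seq_along(si), n)
      pieces[[length(pieces) + 1L]] <- data.table::data.table(
        pirna = sub[ifelse(qi > ns, qi - ns, qi)], chrom = chrom,
        start = starts, end = starts + w,
        strand = ifelse(qi > ns, "-", "+"))
    }
  }
  out <- if (length(pieces)) data.table::rbindlist(pieces) else
    data.table::data.table(pirna = character(0), chrom = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0))
  data.table::setorderv(out, c("pirna", "chrom", "start", "strand"))
  out <- as.data.frame(out)
  attr(out, "unplaced") <- setdiff(seqs, out$pirna)
  out
}

#' Classify targeting events as cis, trans or unplaced
#'
#' A piRNA targets a gene in cis iff any of its perfect genomic origins
#' overlaps the gene's full genomic span (any strand); in trans iff all
#' origins lie elsewhere; unplaced iff it has no perfect origin.
#'
#' @param hits Hit table from [scan_targets()].
#' @param origins Origin table from [map_genomic_origins()].
#' @param models Representative `transcript_model`s supplying gene loci.
#' @return data.frame with one row per (pirna, gene_id) pair: `status`
#'   in `{cis, trans, unplaced}`, `n_origins`, and `mixed` (TRUE for cis
#'   calls that also have origins outside the gene).
#' @export
classify_cis_trans <- function(hits, origins, models) {
  loci <- data.table::data.table(
    gene_id = vapply(models, `[[`, "", "gene_id"),
    g_chrom = vapply(models, `[[`, "", "chrom"),
    g_start = vapply(models, `[[`, 0L, "start"),
    g_end = vapply(models, `[[`, 0L, "end"))
  pairs <- unique(data.table::as.data.table(hits)[, c("pirna", "gene_id"), with = FALSE])
  pairs <- loci[pairs, on = "gene_id"]
  o <- data.table::as.data.table(origins)
  n_org <- o[, list(n_origins = .N), by = "pirna"]
  j <- o[pairs, on = "pirna", allow.cartesian = TRUE]
  j[, "ov" := !is.na(j$chrom) & j$chrom == j$g_chrom &
      j$start < j$g_end & j$end > j$g_start]
  res <- j[, list(any_ov = any(ov), n = sum(!is.na(chrom))),
           by = c("pirna", "gene_id")]
  res[, "status" := ifelse(res$n == 0L, "unplaced",
                           ifelse(res$any_ov, "cis", "trans"))]
  res[, "mixed" := res$status == "cis" & res$n > 1L]
  out <- as.data.frame(res[, c("pirna", "gene_id", "status", "n", "mixed"), with = FALSE])
  names(out)[4L] <- "n_origins"
  out
}

# Merge cluster intervals per id; error if intervals of *different* ids
# still overlap after the merge.
merge_clusters <- function(clusters) {
  dt <- data.table::as.data.table(clusters)
  merged <- dt[, {
    o <- order(start)
    s <- start[o]; e <- end[o]; ch <- chrom[o]
    keep_s <- integer(0); keep_e <- integer(0); keep_c <- character(0)
    for (i in seq_along(s)) {
      k <- length(keep_s)
      if (k > 0L && ch[i] == keep_c[k] && s[i] <= keep_e[k]) {
        keep_e[k] <- max(keep_e[k], e[i])
      } else {
        keep_s <- c(keep_s, s[i]); keep_e <- c(keep_e, e[i])
        keep_c <- c(keep_c, ch[i])
      }
    }
    list(chrom = keep_c, start = keep_s, end = keep_e)
  }, by = "cluster_id"]
  data.table::setorderv(merged, c("chrom", "start"))
  if (nrow(merged) > 1L) {
    same_chrom <- merged$chrom[-1L] == merged$chrom[-nrow(merged)]
    overlap <- merged$start[-1L] < merged$end[-nrow(merged)]
    clash <- same_chrom & overlap &
      merged$cluster_id[-1L] != merged$cluster_id[-nrow(merged)]
    if (any(clash))
      stop("configuration error: cluster annotations of different ids overlap; clusters must be disjoint after per-id merge")
  }
  merged
}

#' Attribute piRNA read mass to clusters
#'
#' Each species' read count is apportioned equally across its perfect
#' origins; the share of each origin falling inside a cluster accrues to
#' that cluster, shares elsewhere to `"unassigned"`. Species with no
#' perfect origin are carried as fully unassigned so that total mass is
#' conserved.
#'
#' @param origins Origin table from [map_genomic_origins()].
#' @param clusters Cluster data.frame from [read_cluster_bed()].
#' @param lib The `pirna_library`.
#' @return data.frame with columns `pirna`, `cluster_id` (or
#'   `"unassigned"`), `weight`; weights sum to 1 for every species.
#' @export
attribute_to_clusters <- function(origins, clusters, lib) {
  merged <- merge_clusters(clusters)
  o <- data.table::as.data.table(origins)
  if (nrow(o) > 0L) {
    data.table::setkeyv(merged, c("chrom", "start", "end"))
    ov <- data.table::foverlaps(
      o[, c("pirna", "chrom", "start", "end"), with = FALSE],
      merged, type = "any", mult = "first", which = FALSE, nomatch = NA)
    o[, "cluster_id" := ifelse(is.na(ov$cluster_id), "unassigned", ov$cluster_id)]
    o[, "share" := 1 / .N, by = "pirna"]
    w <- o[, list(weight = sum(share)), by = c("pirna", "cluster_id")]
  } else {
    w <- data.table::data.table(pirna = character(0),
                                cluster_id = character(0), weight = numeric(0))
  }
  unplaced <- setdiff(lib$records$seq, w$pirna)
  if (length(unplaced)) {
    w <- data.table::rbindlist(list(w, data.table::data.table(
      pirna = unplaced, cluster_id = "unassigned", weight = 1)))
  }
  data.table::setorderv(w, c("pirna", "cluster_id"))
  out <- as.data.frame(w)
  attr(out, "unplaced") <- unplaced
  out
}

#' Call per-gene cluster regulons
#'
#' For each target gene, read mass over its targeting species is split
#' across source clusters; the dominant cluster is the argmax (ties broken
#' by lexicographically smaller cluster id) and a one-to-one regulon flag
#' is set when its share reaches `dominant_threshold`.
#'
#' @param hits Hit table from [scan_targets()].
#' @param weights Attribution table from [attribute_to_clusters()].
#' @param lib The `pirna_library`.
#' @param dominant_threshold Share required for the one-to-one flag
#'   (default 0.5).
#' @return data.frame with one row per target gene: `gene_id`,
#'   `targeting_reads`, `dominant_cluster`, `dominant_fraction`,
#'   `unassigned_fraction`, `one_to_one`.
#' @export
call_regulons <- function(hits, weights, lib, dominant_threshold = 0.5) {
  counts <- stats::setNames(lib$records$count, lib$records$seq)
  sg <- unique(data.table::as.data.table(hits)[, c("pirna", "gene_id"), with = FALSE])
  sg[, "count" := counts[sg$pirna]]
  w <- data.table::as.data.table(weights)
  j <- w[sg, on = "pirna", allow.cartesian = TRUE]
  shares <- j[, list(mass = sum(count * weight)), by = c("gene_id", "cluster_id")]
  totals <- sg[, list(total = sum(count)), by = "gene_id"]
  shares <- totals[shares, on = "gene_id"]
  shares[, "share" := shares$mass / shares$total]
  out <- shares[, {
    cl <- cluster_id != "unassigned"
    un <- if (any(!cl)) sum(share[!cl]) else 0
    if (any(cl)) {
      sub_sh <- share[cl]; sub_id <- cluster_id[cl]
      o <- order(-sub_sh, sub_id)
      list(targeting_reads = total[1L], dominant_cluster = sub_id[o[1L]],
           dominant_fraction = sub_sh[o[1L]], unassigned_fraction = un)
    } else {
      list(targeting_reads = total[1L], dominant_cluster = NA_character_,
           dominant_fraction = 0, unassigned_fraction = un)
    }
  }, by = "gene_id"]
  out[, "one_to_one" := !is.na(out$dominant_cluster) &
        out$dominant_fraction >= dominant_threshold]
  data.table::setorderv(out, c("targeting_reads", "gene_id"), order = c(-1L, 1L))
  as.data.frame(out)
}

#' Tiled genomic small-RNA coverage (rpm)
#'
#' Apportioned read counts of origins whose start falls in each fixed-size
#' tile, per strand, scaled to reads per million retained reads.
#'
#' @param origins Origin table from [map_genomic_origins()].
#' @param lib The `pirna_library` (supplies the rpm denominator).
#' @param tile Tile width in nt (default 100).
#' @return data.frame: `chrom`, `strand`, `tile_start`, `tile_end`, `rpm`.
#' @export
tiled_coverage <- function(origins, lib, tile = 100L) {
  if (tile <= 0L) stop("parameter error: tile must be positive")
  o <- data.table::as.data.table(origins)
  counts <- stats::setNames(lib$records$count, lib$records$seq)
  if (nrow(o) == 0L)
    return(data.frame(chrom = character(0), strand = character(0),
                      tile_start = integer(0), tile_end = integer(0),
                      rpm = numeric(0)))
  o[, "share" := 1 / .N, by = "pirna"]
  o[, "count" := counts[o$pirna]]
  o[, "tile_start" := (o$start %/% tile) * tile]
  res <- o[, list(rpm = sum(count * share) * 1e6 / lib$total_reads),
           by = c("chrom", "strand", "tile_start")]
  res[, "tile_end" := res$tile_start + tile]
  data.table::setorderv(res, c("chrom", "tile_start", "strand"))
  as.data.frame(res[, c("chrom", "strand", "tile_start", "tile_end", "rpm"), with = FALSE])
}

#' Per-cluster expression (rpm) and top-cluster subset
#'
#' @param weights Attribution table from [attribute_to_clusters()].
#' @param lib The `pirna_library`.
#' @param clusters Optional cluster data.frame; when given, clusters with
#'   zero attributed mass are included with rpm 0.
#' @param percentile Expression percentile defining the top subset
#'   (default 0.90).
#' @return List with `table` (cluster_id, rpm, in_top) and `top`
#'   (character vector of top-cluster ids, ties at the threshold included).
#' @export
cluster_expression <- function(weights, lib, clusters = NULL, percentile = 0.90) {
  counts <- stats::setNames(lib$records$count, lib$records$seq)
  w <- data.table::as.data.table(weights)
  w <- w[w$cluster_id != "unassigned"]
  tab <- w[, list(rpm = sum(counts[pirna] * weight) * 1e6 / lib$total_reads),
           by = "cluster_id"]
  if (!is.null(clusters)) {
    missing <- setdiff(unique(clusters$cluster_id), tab$cluster_id)
    if (length(missing))
      tab <- data.table::rbindlist(list(tab, data.table::data.table(
        cluster_id = missing, rpm = 0)))
  }
  if (nrow(tab) == 0L || all(tab$rpm == 0)) {
    warning("no cluster-attributed piRNA mass; empty top-cluster subset")
    tab[, "in_top" := logical(nrow(tab))]
    return(list(table = as.data.frame(tab), top = character(0),
                percentile = percentile))
  }
  thr <- stats::quantile(tab$rpm, percentile, names = FALSE)
  tab[, "in_top" := tab$rpm >= thr]
  data.table::setorderv(tab, c("rpm", "cluster_id"), order = c(-1L, 1L))
  list(table = as.data.frame(tab), top = tab$cluster_id[tab$in_top],
       percentile = percentile)
}
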