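# Reading and writing standard formats, mature transcript construction,
# and small-RNA read collapsing.
#
# Coordinate conventions: all internal coordinates are 0-based half-open
# on the forward genomic strand. GTF input (1-based inclusive) and BED
# input (0-based half-open) are converted at the boundary. Transcript
# coordinate 0 is the 5' end of the mature mRNA.

#' Construct a transcript model
#'
#' A transcript model holds the exon structure of one transcript, an
#' optional CDS span in transcript coordinates, and (once built) the
#' mature spliced sequence.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of 0-based half-open exon
#'   coordinates, sorted by genomic start and non-overlapping.
#' @param cds_span Optional numeric length-2 vector: the CDS as a 0-based
#'   half-open interval in transcript coordinates.
#' @param mature_seq Optional mature (spliced) sequence; usually filled in
#'   by [build_mature_transcript()].
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand,
                             exon_starts, exon_ends,
                             cds_span = NULL, mature_seq = NULL) {
  id <- paste0("transcript ", transcript_id)
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) == 0L)
    stop_positioned(id, "exon_starts and exon_ends must be non-empty and equal length")
  if (any(exon_starts < 0L) || any(exon_ends <= exon_starts))
    stop_positioned(id, "exons must satisfy 0 <= start < end")
  o <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[o]); exon_ends <- as.integer(exon_ends[o])
  n <- length(exon_starts)
  if (n > 1L && any(exon_starts[-1L] < exon_ends[-n]))
    stop_positioned(id, "annotation error: overlapping exons")
  if (!strand %in% c("+", "-"))
    stop_positioned(id, "strand must be '+' or '-'")
  len <- sum(exon_ends - exon_starts)
  if (!is.null(cds_span)) {
    cds_span <- as.integer(cds_span)
    if (length(cds_span) != 2L || cds_span[1L] < 0L ||
        cds_span[2L] <= cds_span[1L] || cds_span[2L] > len)
      stop_positioned(id, "cds_span must lie within [0, transcript length)")
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand,
                 exon_starts = exon_starts, exon_ends = exon_ends,
                 start = exon_starts[1L], end = exon_ends[n],
                 cds_span = cds_span, mature_seq = mature_seq),
            class = "transcript_model")
}

#' Transcript length of a model
#' @param model A `transcript_model`.
#' @return Integer mature transcript length.
#' @export
tx_length <- function(model) sum(model$exon_ends - model$exon_starts)

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d(%s), %d exon(s), %d nt%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$start, x$end, x$strand,
              length(x$exon_starts), tx_length(x),
              if (is.null(x$cds_span)) "" else
                sprintf(", CDS [%d,%d)", x$cds_span[1L], x$cds_span[2L])))
  invisible(x)
}

#' Map genomic positions to transcript coordinates
#'
#' @param model A `transcript_model`.
#' @param gpos Integer vector of 0-based genomic positions.
#' @return Integer vector of transcript coordinates (`NA` for positions
#'   outside exons).
#' @export
genomic_to_tx <- function(model, gpos) {
  widths <- model$exon_ends - model$exon_starts
  cum <- cumsum(c(0L, widths))
  idx <- findInterval(gpos, model$exon_starts)
  ok <- idx >= 1L & gpos < model$exon_ends[pmax(idx, 1L)]
  t_plus <- ifelse(ok, cum[idx] + gpos - model$exon_starts[idx], NA_integer_)
  if (model$strand == "+") t_plus else sum(widths) - 1L - t_plus
}

#' Map a transcript-coordinate interval to genomic intervals
#'
#' @param model A `transcript_model`.
#' @param start,end 0-based half-open interval in transcript coordinates.
#' @return A data.frame with columns `start`, `end` of genomic intervals in
#'   genomic order.
#' @export
tx_to_genomic <- function(model, start, end) {
  len <- tx_length(model)
  if (start < 0L || end > len || end <= start)
    stop_positioned(model$transcript_id, "transcript interval out of bounds")
  widths <- model$exon_ends - model$exon_starts
  cum <- cumsum(c(0L, widths))
  if (model$strand == "-") {
    tmp <- len - end
    end <- len - start
    start <- tmp
  }
  out <- list()
  for (i in seq_along(widths)) {
    a <- max(start, cum[i]); b <- min(end, cum[i + 1L])
    if (a < b) {
      out[[length(out) + 1L]] <- c(model$exon_starts[i] + (a - cum[i]),
                                   model$exon_starts[i] + (b - cum[i]))
    }
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1L], end = m[, 2L])
}

#' Read a genome FASTA
#'
#' @param path FASTA file (multi-record allowed).
#' @return Named character vector of chromosome sequences (names truncated
#'   at the first whitespace).
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), nm)
}

#' Write a genome FASTA
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Build the mature spliced sequence of a transcript
#'
#' Concatenates exon sequences in genomic order and reverse-complements the
#' result as one unit for minus-strand transcripts, so that transcript
#' coordinate 0 is the 5' end of the mature mRNA.
#'
#' @param genome Named character vector from [read_genome()].
#' @param model A `transcript_model`.
#' @return The model with `mature_seq` filled in.
#' @export
build_mature_transcript <- function(genome, model) {
  if (!model$chrom %in% names(genome))
    stop_positioned(model$transcript_id,
                    sprintf("coordinate error: chromosome '%s' not in genome", model$chrom))
  chromseq <- genome[[model$chrom]]
  if (model$end > nchar(chromseq))
    stop_positioned(model$transcript_id,
                    "coordinate error: exon beyond chromosome bounds")
  pieces <- substring(chromseq, model$exon_starts + 1L, model$exon_ends)
  seq <- paste(pieces, collapse = "")
  if (model$strand == "-") seq <- revcomp(seq)
  model$mature_seq <- seq
  model
}

#' Read transcript models from a GTF/GFF file
#'
#' Requires `exon` features (and optionally `CDS` features) carrying
#' `gene_id` and `transcript_id` attributes. Coordinates are converted to
#' the internal 0-based half-open convention.
#'
#' @param path GTF or GFF3 file.
#' @param genome Optional genome from [read_genome()]; when supplied,
#'   mature sequences are built.
#' @return Named list of `transcript_model` objects (by transcript_id).
#' @export
read_transcript_models <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!"type" %in% names(df))
    stop_positioned(path, "annotation lacks a feature type column")
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(df) == 0L)
    stop_positioned(path, "no exon or CDS features found")
  for (col in c("gene_id", "transcript_id")) {
    if (!col %in% names(df) || anyNA(df[[col]]))
      stop_positioned(path, sprintf(
        "exon/CDS feature missing required attribute '%s' (line for %s:%s)",
        col, df$seqnames[1L], df$start[1L]))
  }
  models <- list()
  for (tid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tid, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L)
      stop_positioned(path, sprintf("transcript %s has CDS but no exon features", tid))
    strand <- as.character(ex$strand[1L])
    model <- transcript_model(
      gene_id = ex$gene_id[1L], transcript_id = tid,
      chrom = as.character(ex$seqnames[1L]), strand = strand,
      exon_starts = ex$start - 1L, exon_ends = ex$end)
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    if (nrow(cds) > 0L) {
      tpos <- c(genomic_to_tx(model, cds$start - 1L),
                genomic_to_tx(model, cds$end - 1L))
      if (anyNA(tpos))
        stop_positioned(path, sprintf("CDS of %s extends outside its exons", tid))
      model$cds_span <- c(min(tpos), max(tpos) + 1L)
    }
    if (!is.null(genome)) model <- build_mature_transcript(genome, model)
    models[[tid]] <- model
  }
  models
}

#' Write transcript models as GTF
#' @param models List of `transcript_model` objects.
#' @param path Output path.
#' @export
write_transcript_gtf <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', m$gene_id, m$transcript_id)
    ex <- sprintf("%s\tpiregulon\texon\t%d\t%d\t.\t%s\t.\t%s",
                  m$chrom, m$exon_starts + 1L, m$exon_ends, m$strand, attrs)
    lines <- c(lines, ex)
    if (!is.null(m$cds_span)) {
      g <- tx_to_genomic(m, m$cds_span[1L], m$cds_span[2L])
      cds <- sprintf("%s\tpiregulon\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                     m$chrom, g$start + 1L, g$end, m$strand, attrs)
      lines <- c(lines, cds)
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Pick one representative transcript per gene
#'
#' The transcript with the longest CDS wins; ties are broken by longest
#' mature sequence, then lexicographically smallest transcript_id.
#'
#' @param models Named list of `transcript_model` objects.
#' @return Named list with one model per gene.
#' @export
select_representative_transcripts <- function(models) {
  info <- data.table::data.table(
    tid = vapply(models, `[[`, "", "transcript_id"),
    gene = vapply(models, `[[`, "", "gene_id"),
    cds_len = vapply(models, function(m)
      if (is.null(m$cds_span)) 0L else m$cds_span[2L] - m$cds_span[1L], 0L),
    tx_len = vapply(models, tx_length, 0L))
  data.table::setorder(info, gene, -cds_len, -tx_len, tid)
  keep <- info[, .SD[1L], by = "gene"]$tid
  models[keep]
}

#' Construct a collapsed small-RNA library
#'
#' @param records data.frame with columns `seq`, `count`.
#' @param length_range Integer length-2 vector of the retained length window.
#' @param dropped Named list of dropped read tallies.
#' @return Object of class `pirna_library` with elements `records`,
#'   `total_reads`, `length_range`, `dropped`.
#' @export
pirna_library <- function(records, length_range, dropped = list()) {
  stopifnot(all(c("seq", "count") %in% names(records)))
  if (any(records$count <= 0)) stop("library counts must be positive")
  structure(list(records = as.data.frame(records),
                 total_reads = sum(records$count),
                 length_range = as.integer(length_range),
                 dropped = dropped),
            class = "pirna_library")
}

#' @export
print.pirna_library <- function(x, ...) {
  cat(sprintf("<pirna_library> %d species, %s reads, lengths %d-%d\n",
              nrow(x$records), format(x$total_reads, big.mark = ","),
              x$length_range[1L], x$length_range[2L]))
  invisible(x)
}

#' Collapse raw small-RNA reads into a counted library
#'
#' U is normalized to T, reads containing other ambiguous characters are
#' dropped, identical sequences are merged with summed counts, and reads
#' outside the length window are dropped. Dropped totals are kept in the
#' returned object.
#'
#' @param seqs Character vector of read sequences (ACGTUN alphabet).
#' @param counts Optional read multiplicities (default 1 per sequence).
#' @param min_len,max_len Retained length window. The default 24-34 nt
#'   brackets the 26-31 nt pachytene piRNA range with margin for
#'   incompletely trimmed ends.
#' @return A `pirna_library`.
#' @export
collapse_reads <- function(seqs, counts = NULL, min_len = 24L, max_len = 34L) {
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  stopifnot(length(counts) == length(seqs))
  seqs <- chartr("u", "U", toupper(seqs))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGT]", seqs)
  n_ambig <- sum(counts[bad])
  seqs <- seqs[!bad]; counts <- counts[!bad]
  len <- nchar(seqs)
  keep <- len >= min_len & len <= max_len
  n_len <- sum(counts[!keep])
  seqs <- seqs[keep]; counts <- counts[keep]
  if (length(seqs) == 0L) {
    return(pirna_library(data.frame(seq = character(0), count = integer(0)),
                         c(min_len, max_len),
                         dropped = list(ambiguous = n_ambig, length = n_len)))
  }
  dt <- data.table::data.table(seq = seqs, count = counts)
  dt <- dt[, list(count = sum(count)), by = "seq"]
  data.table::setorder(dt, -count, seq)
  pirna_library(dt, c(min_len, max_len),
                dropped = list(ambiguous = n_ambig, length = n_len))
}

#' Read a collapsed small-RNA FASTA
#'
#' Headers must follow the `>idNNN_xCOUNT` dialect, the trailing
#' `_x<count>` giving the read count of each unique sequence.
#'
#' @param path FASTA path.
#' @param min_len,max_len Length window passed to [collapse_reads()].
#' @return A `pirna_library`.
#' @export
read_pirna_fasta <- function(path, min_len = 24L, max_len = 34L) {
  x <- Biostrings::readBStringSet(path)
  heads <- names(x)
  m <- regmatches(heads, regexpr("_x([0-9]+)\\s*$", heads))
  if (length(m) != length(heads) || any(!nzchar(m)))
    stop_positioned(path, sprintf(
      "malformed count header '%s' (expected '..._xCOUNT')",
      heads[which(!grepl("_x[0-9]+\\s*$", heads))[1L]]))
  counts <- as.integer(sub("_x", "", sub("\\s*$", "", m)))
  collapse_reads(as.character(x), counts, min_len, max_len)
}

#' Read and collapse a raw small-RNA FASTQ
#' @inheritParams read_pirna_fasta
#' @return A `pirna_library`.
#' @export
read_pirna_fastq <- function(path, min_len = 24L, max_len = 34L) {
  x <- Biostrings::readBStringSet(path, format = "fastq")
  collapse_reads(as.character(x), NULL, min_len, max_len)
}

#' Write a collapsed small-RNA FASTA
#' @param lib A `pirna_library`.
#' @param path Output path.
#' @export
write_pirna_fasta <- function(lib, path) {
  r <- lib$records
  heads <- sprintf("seq%06d_x%d", seq_len(nrow(r)), r$count)
  writeLines(paste0(">", heads, "\n", r$seq), path, sep = "\n")
  invisible(path)
}

#' Read a piRNA cluster BED file
#'
#' BED6 with the name column carrying the cluster id. A `.` strand is
#' taken to mean a bidirectional locus (strand `*`). The same cluster id
#' may appear on several lines (e.g. the two arms of a bidirectional
#' cluster).
#'
#' @param path BED path.
#' @return data.frame with columns `cluster_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @export
read_cluster_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  if (!"name" %in% names(df) || anyNA(df$name))
    stop_positioned(path, "BED name column (cluster id) is required")
  out <- data.frame(cluster_id = as.character(df$name),
                    chrom = as.character(df$seqnames),
                    start = df$start - 1L, end = df$end,
                    strand = as.character(df$strand),
                    stringsAsFactors = FALSE)
  if (any(out$end <= out$start))
    stop_positioned(path, "cluster interval with end <= start")
  out
}

#' Write clusters as BED6
#' @param clusters data.frame as returned by [read_cluster_bed()].
#' @param path Output path.
#' @export
write_cluster_bed <- function(clusters, path) {
  strand <- ifelse(clusters$strand == "*", ".", clusters$strand)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     clusters$chrom, clusters$start, clusters$end,
                     clusters$cluster_id, strand), path)
  invisible(path)
}

#' Read a feature-by-sample count matrix TSV
#' @param path TSV with a header row of sample ids and feature ids in the
#'   first column.
#' @return Integer matrix with feature rownames.
#' @export
read_count_matrix <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1L]]
  if (any(m < 0)) stop_positioned(path, "negative counts")
  storage.mode(m) <- "numeric"
  m
}

#' Read a sample-to-condition map TSV
#' @param path TSV with columns `sample`, `condition`.
#' @return data.frame with those columns.
#' @export
read_conditions <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!all(c("sample", "condition") %in% names(df)))
    stop_positioned(path, "expected columns 'sample' and 'condition'")
  df
}
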