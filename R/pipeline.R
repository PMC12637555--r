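# End-to-end orchestration: scan -> origins -> regulons -> PGF ->
# signatures (-> expression when counts are supplied), with plain-TSV
# interchange, provenance headers and a JSON run report. Outputs carry
# no timestamps, so reruns with the same inputs are byte-identical.

#' Pipeline parameters
#'
#' All stage parameters in one validated list. Unknown names are
#' rejected.
#'
#' @param ... Name-value overrides of the defaults.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(...) {
  defaults <- list(
    min_len = 24L, max_len = 34L,          # library length window
    max_mm = 1L,                           # core mismatch budget
    mass_threshold = 0.70,                 # top-target cumulative mass
    count_mode = "reads", assign = "all",
    dominant_threshold = 0.5,              # one-to-one regulon flag
    tile = 100L, cluster_percentile = 0.90,
    min_identity = 0.80, min_span = 200L,  # PGF promotion
    truncation_margin = 50L,
    alpha = 0.05, pseudocount = 1,
    cond_ref = NULL, cond_alt = NULL,
    max_pos = 32L)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop(sprintf("unknown pipeline parameter(s): %s", paste(bad, collapse = ", ")))
  utils::modifyList(defaults, over)
}

.write_stage_tsv <- function(df, path, meta) {
  writeLines(sprintf("#%s=%s", names(meta), unlist(meta)), path)
  suppressWarnings(data.table::fwrite(df, path, sep = "\t", append = TRUE,
                                      col.names = TRUE))
  invisible(path)
}

#' Run the full target-centered piRNA analysis
#'
#' Accepts either file paths (genome FASTA, gene GTF, cluster BED,
#' collapsed piRNA FASTA, optional count/condition TSVs) or the
#' corresponding in-memory objects. Inputs are validated before any
#' stage runs; a failing stage writes `error.log` naming the stage and
#' preserves outputs of completed stages.
#'
#' @param genome Path to a genome FASTA or a named character vector.
#' @param annotation Path to a GTF/GFF or a list of `transcript_model`s.
#' @param clusters Path to a cluster BED or a cluster data.frame.
#' @param pirnas Path to a collapsed piRNA FASTA or a `pirna_library`.
#' @param counts Optional count matrix path or matrix.
#' @param conditions Optional condition map path or data.frame.
#' @param out_dir Output directory for TSVs and the run report.
#' @param params [pipeline_params()].
#' @return Invisibly, the run report list (also written as
#'   `report.json`).
#' @export
run_pipeline <- function(genome, annotation, clusters, pirnas,
                         counts = NULL, conditions = NULL,
                         out_dir, params = pipeline_params()) {
  paths <- Filter(is.character, list(genome = genome, annotation = annotation,
                                     clusters = clusters, pirnas = pirnas,
                                     counts = counts, conditions = conditions))
  missing <- names(paths)[!vapply(paths, function(p) file.exists(p[1L]), TRUE)]
  if (length(missing))
    stop(sprintf("missing input file(s): %s",
                 paste(sprintf("%s (%s)", missing,
                               unlist(paths[missing])), collapse = ", ")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(tool = paste0("piregulon ",
                             as.character(utils::packageVersion("piregulon"))),
               config = config_hash(params))
  stage <- "load"
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "error.log"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  inputs <- run_stage("load", {
    g <- if (is.character(genome)) read_genome(genome) else genome
    mods <- if (is.character(annotation))
      read_transcript_models(annotation, g) else annotation
    cl <- if (is.character(clusters)) read_cluster_bed(clusters) else clusters
    lib <- if (is.character(pirnas))
      read_pirna_fasta(pirnas, params$min_len, params$max_len) else pirnas
    cm <- if (is.character(counts)) read_count_matrix(counts) else counts
    cd <- if (is.character(conditions)) read_conditions(conditions) else conditions
    list(genome = g, models = select_representative_transcripts(mods),
         clusters = cl, lib = lib, counts = cm, conditions = cd)
  })
  scan_res <- run_stage("scan", {
    hits <- scan_targets(inputs$lib, inputs$models, max_mm = params$max_mm)
    ranking <- rank_targets(hits, inputs$lib,
                            mass_threshold = params$mass_threshold,
                            count_mode = params$count_mode,
                            assign = params$assign, models = inputs$models)
    .write_stage_tsv(hits, file.path(out_dir, "hits.tsv"), meta)
    if (nrow(ranking$table))
      .write_stage_tsv(ranking$table, file.path(out_dir, "ranking.tsv"),
                       c(meta, list(count_mode = params$count_mode,
                                    assign = params$assign)))
    list(hits = hits, ranking = ranking)
  })
  origin_res <- run_stage("origins", {
    origins <- map_genomic_origins(inputs$lib, inputs$genome)
    ct <- classify_cis_trans(scan_res$hits, origins, inputs$models)
    .write_stage_tsv(origins, file.path(out_dir, "origins.tsv"), meta)
    .write_stage_tsv(ct, file.path(out_dir, "cis_trans.tsv"), meta)
    tiles <- tiled_coverage(origins, inputs$lib, tile = params$tile)
    for (s in c("+", "-")) {
      sub <- tiles[tiles$strand == s, c("chrom", "tile_start", "tile_end", "rpm")]
      f <- file.path(out_dir, sprintf("coverage_%s.bedgraph",
                                      if (s == "+") "plus" else "minus"))
      writeLines(sprintf("%s\t%d\t%d\t%.6g", sub$chrom, sub$tile_start,
                         sub$tile_end, sub$rpm), f)
    }
    list(origins = origins, cis_trans = ct, tiles = tiles)
  })
  regulon_res <- run_stage("regulons", {
    weights <- attribute_to_clusters(origin_res$origins, inputs$clusters,
                                     inputs$lib)
    regulons <- call_regulons(scan_res$hits, weights, inputs$lib,
                              dominant_threshold = params$dominant_threshold)
    clexp <- cluster_expression(weights, inputs$lib, inputs$clusters,
                                percentile = params$cluster_percentile)
    .write_stage_tsv(weights, file.path(out_dir, "cluster_attribution.tsv"), meta)
    .write_stage_tsv(regulons, file.path(out_dir, "regulons.tsv"), meta)
    .write_stage_tsv(clexp$table, file.path(out_dir, "cluster_expression.tsv"), meta)
    list(weights = weights, regulons = regulons, cluster_expression = clexp)
  })
  pgf_res <- run_stage("pgf", {
    calls <- call_pgfs(inputs$genome, inputs$clusters, inputs$models,
                       min_identity = params$min_identity,
                       min_span = params$min_span,
                       truncation_margin = params$truncation_margin)
    .write_stage_tsv(calls, file.path(out_dir, "pgf_calls.tsv"), meta)
    if (nrow(calls) && "chrom" %in% names(calls)) {
      gff <- sprintf(
        paste0("%s\tpiregulon\tpseudogene_fragment\t%d\t%d\t.\t%s\t.\t",
               "ID=PGF_%s_%s;parent_gene=%s;identity=%.4f;processed=%s;",
               "five_prime_truncated=%s;tsd=%s"),
        calls$chrom, calls$ins_start + 1L, calls$ins_end,
        ifelse(calls$orientation == "same", "+", "-"),
        calls$cluster_id, calls$gene_id, calls$gene_id, calls$identity,
        calls$processed, calls$five_prime_truncated,
        ifelse(is.na(calls$tsd_seq), ".", calls$tsd_seq))
      writeLines(c("##gff-version 3", gff), file.path(out_dir, "pgf_calls.gff3"))
    }
    calls
  })
  sig_res <- run_stage("signatures", {
    pf <- positional_base_frequency(inputs$lib, max_pos = params$max_pos)
    ld <- length_distribution(inputs$lib)
    fdf <- data.frame(position = seq_len(nrow(pf$freq)), pf$freq)
    .write_stage_tsv(fdf, file.path(out_dir, "positional_frequency.tsv"), meta)
    .write_stage_tsv(data.frame(length = names(ld), fraction = as.numeric(ld)),
                     file.path(out_dir, "length_distribution.tsv"), meta)
    pf
  })
  expr_res <- NULL
  if (!is.null(inputs$counts)) {
    expr_res <- run_stage("expression", {
      cond <- inputs$conditions
      ca <- params$cond_ref %||% unique(cond$condition)[1L]
      cb <- params$cond_alt %||% unique(cond$condition)[2L]
      volcano <- feature_volcano_table(inputs$counts, cond, ca, cb,
                                       alpha = params$alpha,
                                       pseudocount = params$pseudocount)
      .write_stage_tsv(volcano, file.path(out_dir, "volcano.tsv"), meta)
      lfc <- stats::setNames(volcano$log2fc, volcano$feature)
      rt <- scan_res$ranking$table
      tiers <- NULL
      if (nrow(rt)) {
        top <- rt$gene_id[rt$in_top]
        lower <- rt$gene_id[!rt$in_top]
        nont <- setdiff(rownames(inputs$counts), rt$gene_id)
        tiers <- compare_target_tiers(lfc, top, lower, nont)
        if (nrow(tiers$comparisons))
          .write_stage_tsv(tiers$comparisons,
                           file.path(out_dir, "tier_comparison.tsv"), meta)
        ecdf_pts <- do.call(rbind, lapply(names(tiers$values), function(nm) {
          v <- sort(tiers$values[[nm]])
          if (!length(v)) return(NULL)
          data.frame(tier = nm, log2fc = v,
                     ecdf = seq_along(v) / length(v))
        }))
        if (!is.null(ecdf_pts))
          .write_stage_tsv(ecdf_pts, file.path(out_dir, "ecdf_points.tsv"), meta)
      }
      list(volcano = volcano, tiers = tiers, cond_ref = ca, cond_alt = cb)
    })
  }
  stage <- "report"
  rt <- scan_res$ranking$table
  report <- list(
    tool = meta$tool, config = meta$config,
    n_species = nrow(inputs$lib$records),
    total_reads = inputs$lib$total_reads,
    targeting_fraction = scan_res$ranking$targeting_fraction,
    n_targets = nrow(rt),
    top_targets = if (nrow(rt)) utils::head(
      rt[, c("gene_id", "targeting_reads", "fraction", "rank")], 10L) else NULL,
    n_one_to_one_regulons = sum(regulon_res$regulons$one_to_one),
    regulons = regulon_res$regulons[regulon_res$regulons$one_to_one, , drop = FALSE],
    n_pgf_calls = if (is.data.frame(pgf_res)) nrow(pgf_res) else 0L,
    u1 = sig_res$u1, a10 = sig_res$a10,
    n_significant_features = if (!is.null(expr_res))
      sum(expr_res$volcano$significant, na.rm = TRUE) else NULL)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  invisible(c(report, list(
    hits = scan_res$hits, ranking = scan_res$ranking,
    origins = origin_res$origins, cis_trans = origin_res$cis_trans,
    weights = regulon_res$weights, regulon_calls = regulon_res$regulons,
    cluster_expression = regulon_res$cluster_expression,
    pgf_calls = pgf_res, signatures = sig_res, expression = expr_res)))
}
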