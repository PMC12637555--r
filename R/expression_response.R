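# Expression response: median-of-ratios normalization, fold changes,
# two-sample Kolmogorov-Smirnov comparison of target tiers, and a
# Welch-test volcano table with Benjamini-Hochberg correction.

#' Median-of-ratios count normalization
#'
#' Per-sample size factors are the median, over features with a finite
#' log-geometric mean, of the count-to-geometric-mean ratio; counts are
#' divided by the size factors.
#'
#' @param mat Non-negative count matrix (features x samples).
#' @return Normalized matrix with a `size_factors` attribute.
#' @export
normalize_counts <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("counts must be non-negative")
  if (all(mat == 0)) stop("all-zero count matrix")
  lg <- rowMeans(log(mat))
  use <- is.finite(lg)
  if (!any(use))
    stop("no feature has all-positive counts; size factors undefined")
  sf <- apply(mat, 2L, function(col) {
    exp(stats::median(log(col[use]) - lg[use]))
  })
  out <- sweep(mat, 2L, sf, "/")
  attr(out, "size_factors") <- sf
  out
}

#' Per-feature log2 fold change between conditions
#'
#' @param mat Normalized matrix (features x samples).
#' @param conditions data.frame with `sample`, `condition` (samples must
#'   match the matrix columns) or a named character vector.
#' @param cond_a,cond_b Condition labels; the fold change is b versus a.
#' @param pseudocount Added to both means (default 1).
#' @return Named numeric vector of log2((mean_b + pc) / (mean_a + pc)).
#' @export
log2_fold_change <- function(mat, conditions, cond_a, cond_b, pseudocount = 1) {
  cond <- if (is.data.frame(conditions))
    stats::setNames(conditions$condition, conditions$sample) else conditions
  if (!all(c(cond_a, cond_b) %in% cond))
    stop(sprintf("unknown condition label: %s",
                 paste(setdiff(c(cond_a, cond_b), cond), collapse = ", ")))
  sa <- names(cond)[cond == cond_a]
  sb <- names(cond)[cond == cond_b]
  if (!all(c(sa, sb) %in% colnames(mat)))
    stop("condition map names samples absent from the matrix")
  ma <- rowMeans(mat[, sa, drop = FALSE])
  mb <- rowMeans(mat[, sb, drop = FALSE])
  log2((mb + pseudocount) / (ma + pseudocount))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the absolute ECDF difference; the p-value comes
#' from the asymptotic Kolmogorov distribution evaluated at
#' `sqrt(n_eff) * D` with effective size `n_x n_y / (n_x + n_y)`.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @return List with `D`, `p`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed")
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  D <- max(abs(Fx - Fy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  lambda <- sqrt(ne) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(D = D, p = min(1, max(0, p)), n_x = length(x), n_y = length(y))
}

#' Compare expression response across target tiers
#'
#' ECDFs and all pairwise KS tests between the fold-change distributions
#' of the top-target, lower-ranked-target and non-target tiers. The
#' signed D of a comparison is positive when the first tier is shifted
#' toward up-regulation relative to the second.
#'
#' @param lfc Named numeric vector of per-gene log2 fold changes.
#' @param top,lower,nontarget Character vectors of gene ids (disjoint).
#' @return List with `values` (fold changes per tier) and `comparisons`
#'   (data.frame: tier_a, tier_b, D, signed_D, p, n_a, n_b).
#' @export
compare_target_tiers <- function(lfc, top, lower, nontarget) {
  tiers <- list(top = top, lower = lower, nontarget = nontarget)
  if (anyDuplicated(unlist(tiers)))
    stop("tiers must be disjoint")
  values <- lapply(tiers, function(g) unname(lfc[intersect(g, names(lfc))]))
  comps <- list()
  nm <- names(tiers)
  for (i in 1:2) for (j in (i + 1):3) {
    a <- values[[i]]; b <- values[[j]]
    if (length(a) == 0L || length(b) == 0L) {
      warning(sprintf("empty tier in comparison %s vs %s; skipped", nm[i], nm[j]))
      next
    }
    ks <- ks_two_sample(a, b)
    pts <- sort(unique(c(a, b)))
    Fa <- stats::ecdf(a)(pts); Fb <- stats::ecdf(b)(pts)
    signed <- if (max(Fb - Fa) >= max(Fa - Fb)) ks$D else -ks$D
    comps[[length(comps) + 1L]] <- data.frame(
      tier_a = nm[i], tier_b = nm[j], D = ks$D, signed_D = signed,
      p = ks$p, n_a = ks$n_x, n_b = ks$n_y, stringsAsFactors = FALSE)
  }
  list(values = values,
       comparisons = if (length(comps)) do.call(rbind, comps) else
         data.frame())
}

#' Benjamini-Hochberg adjustment and rejection set
#'
#' Classic step-up FDR control; adjusted values are computed with
#' [stats::p.adjust()] and features with adjusted p <= alpha are rejected.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return List with `adjusted` and logical `rejected`.
#' @export
benjamini_hochberg <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = !is.na(adj) & adj <= alpha)
}

# Vectorized per-feature Welch t-test on two matrices with identical
# rows. Degenerate rows (zero variance in both groups) get p = 1 when
# the means agree and p = 0 otherwise.
welch_t_rows <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1L)
  vb <- rowSums((B - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  p
}

#' Per-feature fold change, test and BH adjustment (volcano table)
#'
#' Normalizes the matrix, computes log2 fold changes, and tests each
#' feature with a two-sided Welch t-test on log2(normalized count +
#' pseudocount) across replicates, followed by Benjamini-Hochberg
#' adjustment.
#'
#' @param mat Raw count matrix (features x samples).
#' @param conditions Condition map (data.frame or named vector).
#' @param cond_a,cond_b Reference and alternative condition labels.
#' @param alpha Significance level on adjusted p (default 0.05).
#' @param pseudocount Pseudocount for fold change and log transform.
#' @return data.frame: `feature`, `log2fc`, `p`, `adj_p`, `significant`,
#'   `direction`. With fewer than 2 replicates in either condition the
#'   test columns are NA (fold change only) with a warning.
#' @export
feature_volcano_table <- function(mat, conditions, cond_a, cond_b,
                                  alpha = 0.05, pseudocount = 1) {
  cond <- if (is.data.frame(conditions))
    stats::setNames(conditions$condition, conditions$sample) else conditions
  norm <- normalize_counts(mat)
  lfc <- log2_fold_change(norm, cond, cond_a, cond_b, pseudocount)
  sa <- names(cond)[cond == cond_a]
  sb <- names(cond)[cond == cond_b]
  out <- data.frame(feature = rownames(mat), log2fc = unname(lfc),
                    stringsAsFactors = FALSE)
  if (length(sa) < 2L || length(sb) < 2L) {
    warning("fewer than 2 replicates per condition; fold change only, no test")
    out$p <- NA_real_; out$adj_p <- NA_real_; out$significant <- NA
  } else {
    L <- log2(norm + pseudocount)
    out$p <- welch_t_rows(L[, sa, drop = FALSE], L[, sb, drop = FALSE])
    bh <- benjamini_hochberg(out$p, alpha)
    out$adj_p <- bh$adjusted
    out$significant <- bh$rejected
  }
  out$direction <- ifelse(out$log2fc > 0, "up", ifelse(out$log2fc < 0, "down", "none"))
  out
}
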