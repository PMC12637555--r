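# Positional nucleotide composition (1U/10A signatures) and length
# distributions of small-RNA libraries.

#' Positional base frequencies and 1U/10A fractions
#'
#' Base frequencies at each position among sequences long enough to cover
#' it, read-weighted by default (so the signature reflects abundance, as
#' a sequence logo would). The 1U fraction is the frequency of T (U in
#' RNA) at position 1; the 10A fraction is the frequency of A at
#' position 10 - enrichment there is the ping-pong amplification
#' signature, its absence the mark of primary biogenesis.
#'
#' @param lib A `pirna_library`, or a subset of its records.
#' @param max_pos Last position tabulated (default 32).
#' @param weighting `"reads"` (default) or `"species"`.
#' @param min_count Drop species below this read count before tabulating
#'   (default 1, i.e. keep all). Setting 2 suppresses the singleton
#'   species that sequencing errors scatter around abundant piRNAs, the
#'   usual precaution when reading composition signatures.
#' @return Object of class `positional_freq`: list with `freq` (position
#'   x base matrix, rows summing to 1), `u1`, `a10`, `weighting`.
#' @export
positional_base_frequency <- function(lib, max_pos = 32L,
                                      weighting = c("reads", "species"),
                                      min_count = 1L) {
  weighting <- match.arg(weighting)
  r <- if (inherits(lib, "pirna_library")) lib$records else as.data.frame(lib)
  r <- r[r$count >= min_count, , drop = FALSE]
  if (nrow(r) == 0L) stop("empty library")
  w <- if (weighting == "reads") r$count else rep(1, nrow(r))
  len <- nchar(r$seq)
  maxp <- min(max_pos, max(len))
  bases <- c("A", "C", "G", "T")
  freq <- matrix(NA_real_, maxp, 4L, dimnames = list(seq_len(maxp), bases))
  for (p in seq_len(maxp)) {
    idx <- len >= p
    if (!any(idx)) next
    b <- substr(r$seq[idx], p, p)
    tot <- sum(w[idx])
    for (base in bases) freq[p, base] <- sum(w[idx][b == base]) / tot
  }
  structure(list(freq = freq,
                 u1 = freq[1L, "T"],
                 a10 = if (maxp >= 10L) freq[10L, "A"] else NA_real_,
                 weighting = weighting),
            class = "positional_freq")
}

#' @export
print.positional_freq <- function(x, ...) {
  cat(sprintf("<positional_freq> %s-weighted; 1U = %.3f, 10A = %.3f\n",
              x$weighting, x$u1, x$a10))
  invisible(x)
}

#' Length distribution of a library
#'
#' @param lib A `pirna_library`.
#' @param weighting `"reads"` (default) or `"species"`.
#' @return Named numeric vector mapping length to fraction (sums to 1).
#' @export
length_distribution <- function(lib, weighting = c("reads", "species")) {
  weighting <- match.arg(weighting)
  r <- lib$records
  if (nrow(r) == 0L) stop("empty library")
  w <- if (weighting == "reads") r$count else rep(1, nrow(r))
  tab <- tapply(w, nchar(r$seq), sum)
  out <- as.numeric(tab) / sum(w)
  names(out) <- names(tab)
  out
}
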