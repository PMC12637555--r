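# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over the DNA alphabet (ACGTN).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Uniform random DNA string of length n (uses the current RNG stream).
random_dna <- function(n) {
  if (n == 0L) return("")
  intToUtf8(sample(c(65L, 67L, 71L, 84L), n, replace = TRUE))
}

# Split equal-width strings into an n x width character matrix.
char_matrix <- function(x, width) {
  matrix(unlist(strsplit(x, NULL), use.names = FALSE),
         ncol = width, byrow = TRUE)
}

# Elementwise Hamming distance between two equal-length vectors of
# equal-width strings.
hamming_pairs <- function(a, b) {
  if (length(a) == 0L) return(integer(0))
  w <- nchar(a[1L])
  rowSums(char_matrix(a, w) != char_matrix(b, w))
}

# All-pairs Hamming distance between two vectors of equal-width strings,
# via one-hot crossproducts (fast for the small flank searches used in
# TSD detection).
hamming_cross <- function(a, b) {
  w <- nchar(a[1L])
  A <- char_matrix(a, w)
  B <- char_matrix(b, w)
  m <- matrix(0L, nrow(A), nrow(B))
  for (base in c("A", "C", "G", "T")) {
    m <- m + (A == base) %*% t(B == base)
  }
  w - m
}

# Substitute bases at given 1-based positions with a uniformly chosen
# different base; returns the mutated string.
substitute_bases <- function(seq, pos) {
  if (length(pos) == 0L) return(seq)
  chars <- strsplit(seq, NULL)[[1L]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# Total length of the union of half-open intervals [start, end).
union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0L
  cur_s <- start[1L]; cur_e <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    } else {
      cur_e <- max(cur_e, end[i])
    }
  }
  total + (cur_e - cur_s)
}

# Cheap deterministic hash of an R object, for output provenance headers.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97L + 1L)) %% 2147483647L)
}

stop_positioned <- function(where, msg) {
  stop(sprintf("%s: %s", where, msg), call. = FALSE)
}
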