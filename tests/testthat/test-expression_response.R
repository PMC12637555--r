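test_that("median-of-ratios normalization has the expected invariances", {
  set.seed(61)
  m <- matrix(rnbinom(400, mu = 150, size = 20), 100, 4,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:4)))
  ident <- cbind(s1 = m[, 1], s2 = m[, 1])
  n1 <- normalize_counts(ident)
  expect_equal(unname(attr(n1, "size_factors")), c(1, 1))
  expect_equal(n1, ident, ignore_attr = TRUE)

  doubled <- cbind(a = m[, 1], b = 2L * m[, 1])
  n2 <- normalize_counts(doubled)
  sf <- attr(n2, "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(n2[, "a"], n2[, "b"])

  # independent recomputations: step-by-step and DESeq2
  n3 <- normalize_counts(m)
  lg <- rowMeans(log(m)); use <- is.finite(lg)
  sf_manual <- apply(m, 2, function(col) exp(median(log(col[use]) - lg[use])))
  expect_equal(attr(n3, "size_factors"), sf_manual)
  expect_equal(unname(attr(n3, "size_factors")),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)))

  expect_error(normalize_counts(matrix(0, 3, 2)), "all-zero")
})

test_that("log2 fold changes are plain pseudocounted ratios and antisymmetric", {
  m <- rbind(f1 = c(10, 10, 10, 10), f2 = c(1, 1, 7, 7))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  cond <- data.frame(sample = colnames(m),
                     condition = c("A", "A", "B", "B"))
  lfc <- log2_fold_change(m, cond, "A", "B")
  expect_equal(unname(lfc["f1"]), 0)
  expect_equal(unname(lfc["f2"]), 2)          # log2(8/2)
  expect_equal(log2_fold_change(m, cond, "B", "A"), -lfc)
  expect_error(log2_fold_change(m, cond, "A", "C"), "unknown condition")
})

test_that("the KS statistic matches a brute-force supremum and ks.test", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(0, 0, 0), c(1, 1, 1))$D, 1)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
  brute_D <- function(x, y) {
    pts <- c(x, y)
    max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), 0))
  }
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(30); y <- rnorm(40, mean = 0.4)
    got <- ks_two_sample(x, y)
    expect_equal(got$D, brute_D(x, y))
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(got$D, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  # invariance under a strictly monotone transform of both samples
  set.seed(6)
  x <- rgamma(25, 2); y <- rgamma(35, 3)
  expect_equal(ks_two_sample(x, y)$D, ks_two_sample(log(x), log(y))$D)
})

test_that("tier comparison reports signed shifts and tolerates degenerate tiers", {
  lfc <- stats::setNames(rep(0.5, 9), sprintf("g%d", 1:9))
  same <- compare_target_tiers(lfc, sprintf("g%d", 1:3),
                               sprintf("g%d", 4:6), sprintf("g%d", 7:9))
  expect_true(all(same$comparisons$D == 0))
  expect_error(compare_target_tiers(lfc, "g1", "g1", "g3"), "disjoint")

  single <- compare_target_tiers(
    stats::setNames(c(2, 0, 0.1), c("a", "b", "c")), "a", "b", "c")
  expect_true(all(is.finite(single$comparisons$D)))

  set.seed(62)
  shifted <- stats::setNames(c(rnorm(20, 1.5), rnorm(40), rnorm(40)),
                             sprintf("g%d", 1:100))
  cmp <- compare_target_tiers(shifted, sprintf("g%d", 1:20),
                              sprintf("g%d", 21:60), sprintf("g%d", 61:100))
  row <- cmp$comparisons
  expect_gt(row$signed_D[row$tier_a == "top" & row$tier_b == "nontarget"], 0)
})

test_that("derepression only on the top tier separates it from the others", {
  wins <- 0L
  for (seed in 1:20) {
    set.seed(600 + seed)
    lfc <- stats::setNames(
      c(rnorm(30, log2(3), 0.4), rnorm(100, 0, 0.4), rnorm(100, 0, 0.4)),
      sprintf("g%d", 1:230))
    cmp <- compare_target_tiers(lfc, sprintf("g%d", 1:30),
                                sprintf("g%d", 31:130),
                                sprintf("g%d", 131:230))$comparisons
    d_top <- cmp$D[cmp$tier_a == "top" & cmp$tier_b == "nontarget"]
    d_low <- cmp$D[cmp$tier_a == "lower" & cmp$tier_b == "nontarget"]
    if (d_top > d_low) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("Benjamini-Hochberg equals the hand-stepped procedure", {
  got <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.9))
  expect_equal(got$adjusted, c(0.04, 0.04, 0.04, 0.9))
  expect_identical(got$rejected, c(TRUE, TRUE, TRUE, FALSE))
  one <- benjamini_hochberg(0.03)
  expect_equal(one$adjusted, 0.03)
  expect_true(one$rejected)
  expect_false(any(benjamini_hochberg(rep(1, 5))$rejected))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  # adjusted values are monotone in raw-p rank order
  set.seed(63)
  p <- runif(50)
  adj <- benjamini_hochberg(p)$adjusted
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
})

test_that("the vectorized Welch test agrees with t.test row by row", {
  set.seed(64)
  A <- matrix(rnorm(60, 5), 10, 6)
  B <- matrix(rnorm(40, 5.5), 10, 4)
  mine <- piregulon:::welch_t_rows(A, B)
  ref <- vapply(1:10, function(i)
    stats::t.test(A[i, ], B[i, ])$p.value, 0)
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("volcano tables flag a strongly derepressed feature and only it", {
  # a feature identical across samples carries no signal
  m <- matrix(50, 3, 6, dimnames = list(sprintf("f%d", 1:3), sprintf("s%d", 1:6)))
  cond <- data.frame(sample = colnames(m),
                     condition = rep(c("WT", "KO"), each = 3))
  v <- feature_volcano_table(m, cond, "WT", "KO")
  expect_equal(v$log2fc, rep(0, 3))
  expect_equal(v$p, rep(1, 3))

  hits <- 0L
  for (seed in 1:25) {
    set.seed(640 + seed)
    n <- 200L; reps <- 6L
    wt <- matrix(rnbinom(n * reps, mu = 500, size = 20), n, reps)
    ko <- matrix(rnbinom(n * reps, mu = 500, size = 20), n, reps)
    ko[1, ] <- rnbinom(reps, mu = 2000, size = 20)
    mat <- cbind(wt, ko)
    rownames(mat) <- sprintf("f%03d", 1:n)
    colnames(mat) <- c(sprintf("wt%d", 1:reps), sprintf("ko%d", 1:reps))
    cond <- data.frame(sample = colnames(mat),
                       condition = rep(c("WT", "KO"), each = reps))
    v <- feature_volcano_table(mat, cond, "WT", "KO")
    if (identical(v$feature[which(v$significant)], "f001")) hits <- hits + 1L
  }
  expect_gte(hits, 22L)

  # with a single replicate the table degrades to fold changes
  m1 <- matrix(c(10, 30), 1, 2, dimnames = list("f1", c("a", "b")))
  cond1 <- data.frame(sample = c("a", "b"), condition = c("WT", "KO"))
  expect_warning(v1 <- feature_volcano_table(m1, cond1, "WT", "KO"),
                 "fewer than 2 replicates")
  expect_true(is.na(v1$p))
})

test_that("null simulations keep the BH false-rejection rate at the nominal level", {
  total_tests <- 0L; total_rejected <- 0L
  for (seed in 1:200) {
    set.seed(6400 + seed)
    n <- 300L
    mat <- matrix(rnbinom(n * 6L, mu = 200, size = 20), n, 6)
    rownames(mat) <- sprintf("f%03d", 1:n)
    colnames(mat) <- sprintf("s%d", 1:6)
    cond <- data.frame(sample = colnames(mat),
                       condition = rep(c("A", "B"), each = 3))
    v <- feature_volcano_table(mat, cond, "A", "B")
    total_tests <- total_tests + n
    total_rejected <- total_rejected + sum(v$significant)
  }
  alpha <- 0.05
  bound <- alpha + 2 * sqrt(alpha * (1 - alpha) / total_tests)
  expect_lte(total_rejected / total_tests, bound)
})
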