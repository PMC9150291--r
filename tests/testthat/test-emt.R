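test_that("signature refinement applies the 2-of-3 rule and conflict drop", {
  sig <- refine_signature(list(E = c("a", "b", "c"), M = c("x", "y")),
                          list(E = c("b", "c", "d"), M = c("y", "z")),
                          hallmark = c("c", "d", "e", "y"))
  expect_setequal(sig$epithelial, c("b", "c", "d"))
  expect_setequal(sig$mesenchymal, "y")

  # identical inputs act as the identity on each class
  sig2 <- refine_signature(list(E = c("a", "b"), M = c("m")),
                           list(E = c("a", "b"), M = c("m")),
                           hallmark = character(0))
  expect_setequal(sig2$epithelial, c("a", "b"))
  expect_setequal(sig2$mesenchymal, "m")

  # a gene qualifying for both classes is dropped with a warning
  expect_warning(
    s3 <- refine_signature(list(E = c("g", "a"), M = c("g", "m")),
                           list(E = c("g", "a"), M = c("g", "m")),
                           hallmark = character(0)),
    "both classes")
  expect_false("g" %in% c(s3$epithelial, s3$mesenchymal))
  expect_error(refine_signature(list(E = "a", M = "m"), list(E = "b", M = "n"),
                                hallmark = character(0)),
               "empty")
})

test_that("EMT score: extremes, zeros, antisymmetry, missing genes", {
  z <- rbind(m1 = c(s1 = 1, s2 = 0), m2 = c(1, 0),
             e1 = c(-1, 0), e2 = c(-1, 0))
  sig <- list(epithelial = c("e1", "e2"), mesenchymal = c("m1", "m2"))
  s <- emt_score(z, sig)
  expect_equal(as.vector(s), c(1, 0))
  # swapping E and M flips the sign
  swap <- list(epithelial = sig$mesenchymal, mesenchymal = sig$epithelial)
  expect_equal(as.vector(emt_score(z, swap)), -as.vector(s))
  # absent genes are ignored and counted
  sig2 <- list(epithelial = c("e1", "e2", "ghost"), mesenchymal = c("m1", "m2"))
  s2 <- emt_score(z, sig2)
  expect_equal(attr(s2, "n_missing"), 1)
  expect_error(emt_score(z, list(epithelial = "nope", mesenchymal = "nada")),
               "no signature genes")
})

test_that("panel EMT scores recover the planted ordering exactly", {
  p <- default_panel()
  z <- expression_zscores(p$omics$fpkm)
  s <- emt_score(z, p$gen$signature)
  expect_equal(cor(s, p$spec$emt_scores, method = "spearman"), 1)
})

test_that("expression z-scores standardize per gene", {
  fpkm <- matrix(c(1, 3, 7, 2, 2, 2), 2, 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
  z <- expression_zscores(fpkm)
  expect_equal(unname(rowMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 1, sd)), c(1, 0))
})

test_that("interval signal means are base-pair weighted with zero fill", {
  track <- data.frame(chrom = "chr1", start = c(0, 100), end = c(100, 200),
                      value = c(2, 4))
  iv <- data.frame(chrom = "chr1", start = 0, end = 200)
  expect_equal(mean_signal_in_intervals(track, iv), 3)
  # half covered at 2, half uncovered -> 1
  iv2 <- data.frame(chrom = "chr1", start = 50, end = 250)
  track2 <- data.frame(chrom = "chr1", start = 50, end = 150, value = 2)
  expect_equal(mean_signal_in_intervals(track2, iv2), 1)
  # empty overlap -> 0
  iv3 <- data.frame(chrom = "chr1", start = 1000, end = 1100)
  expect_equal(mean_signal_in_intervals(track, iv3), 0)
})

test_that("interval signal means are additive over partitions", {
  set.seed(9)
  track <- data.frame(chrom = "chr1", start = seq(0, 900, 100),
                      end = seq(100, 1000, 100), value = runif(10, 0, 5))
  whole <- data.frame(chrom = "chr1", start = 0, end = 1000)
  parts <- data.frame(chrom = "chr1", start = c(0, 350), end = c(350, 1000))
  mw <- mean_signal_in_intervals(track, whole)
  mp <- mean_signal_in_intervals(track, parts)
  w <- (parts$end - parts$start) / (whole$end - whole$start)
  expect_equal(sum(mp * w), mw, tolerance = 1e-12)
})

test_that("score-signal correlation matches brute force and permutation ranks", {
  s <- c(a = -1, b = -0.5, c = 0, d = 0.5, e = 1)
  lin <- setNames(2 * s + 3, names(s))
  out <- correlate_score_signal(s, lin)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_lt(out$p, 0.05)
  out_neg <- correlate_score_signal(s, -lin)
  expect_equal(out_neg$r, -1, tolerance = 1e-12)

  set.seed(2)
  tp <- c(); pp <- c()
  for (rep in 1:5) {
    sig <- setNames(rnorm(5), names(s))
    out <- correlate_score_signal(s, sig)
    expect_equal(out$r, pearson_oracle(unname(s), unname(sig)), tolerance = 1e-10)
    tp <- c(tp, out$p)
    pp <- c(pp, perm_p_oracle(unname(s), unname(sig)))
  }
  # the t-based p and the exact permutation p rank the fixtures identically
  expect_equal(order(tp), order(pp))
  expect_error(correlate_score_signal(s[1:2], lin[1:2]), "at least 3")
})

test_that("group tests: Wilcoxon statistic equals exhaustive U, t behaves", {
  set.seed(4)
  for (rep in 1:5) {
    a <- rnorm(5); b <- rnorm(5)
    out <- group_difference_test(a, b, "wilcoxon")
    expect_equal(out$statistic, u_statistic_oracle(a, b))
  }
  same <- c(1, 2, 3, 4, 5)
  expect_gt(group_difference_test(same, same, "wilcoxon")$p, 0.95)
  far <- group_difference_test(rnorm(20), rnorm(20) + 10, "wilcoxon")
  expect_lt(far$p, 1e-4)
  tt <- group_difference_test(rnorm(20), rnorm(20) + 10, "t")
  expect_lt(tt$p, 1e-4)
  expect_error(group_difference_test(1, c(1, 2), "t"), "at least 2")
})

test_that("log2 fold changes use the pseudocount and are monotone", {
  fpkm <- matrix(c(2, 0, 1, 2, 3, 7), 3, 2,
                 dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  fc <- expression_foldchange(fpkm, "a", "b")
  expect_equal(unname(fc["g1"]), 0)
  expect_equal(unname(fc["g2"]), 2)         # (0 + 1) -> (3 + 1)
  expect_equal(unname(fc["g3"]), 2)         # (1 + 1) -> (7 + 1)
  # monotone in the numerator sample
  grid <- sapply(c(1, 2, 5, 9), function(v)
    expression_foldchange(matrix(c(2, v), 1, 2,
                                 dimnames = list("g", c("a", "b"))), "a", "b"))
  expect_true(all(diff(grid) > 0))
  expect_error(expression_foldchange(fpkm, "a", "zz"), "not present")
})

test_that("histone-score correlations on the panel show the planted pattern", {
  p <- default_panel()
  z <- expression_zscores(p$omics$fpkm)
  sc <- emt_score(z, p$gen$signature)
  flags <- assign_emt_tads(p$gen$ref_tads, p$gen$genes)$flags
  eiv <- flags[flags$is_eTAD, c("chrom", "start", "end")]
  miv <- flags[flags$is_mTAD, c("chrom", "start", "end")]
  sig_of <- function(mark, iv) {
    setNames(vapply(seq_len(p$spec$n_samples), function(s)
      mean(mean_signal_in_intervals(p$omics$tracks[[s]][[mark]], iv)),
      numeric(1)), names(sc))
  }
  r_me3_e <- correlate_score_signal(sc, sig_of("H3K27me3", eiv))
  r_ac_e <- correlate_score_signal(sc, sig_of("H3K27ac", eiv))
  r_me3_m <- correlate_score_signal(sc, sig_of("H3K27me3", miv))
  expect_gte(r_me3_e$r, 0.9)
  expect_lte(r_ac_e$r, -0.5)
  expect_lte(abs(r_me3_m$r), 0.5)
})
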