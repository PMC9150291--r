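test_that("insulation score is ~0 on a constant matrix and matches the oracle", {
  m <- matrix(3, 30, 30)
  cm <- cm_from_dense(m, state = "balanced")
  prof <- insulation_profile(cm, "chr1", windows = c(2, 4))
  interior <- prof$score[5:26]
  expect_true(all(abs(interior) < 1e-12))

  set.seed(17)
  m <- matrix(rexp(60 * 60, 1 / 10), 60, 60)
  m <- (m + t(m)) / 2
  cm <- cm_from_dense(m, state = "balanced")
  for (wset in list(c(1, 3, 5), c(2, 6))) {
    prof <- insulation_profile(cm, "chr1", windows = wset)
    expect_equal(prof$score, insulation_oracle(m, wset), tolerance = 1e-10)
  }
  expect_error(insulation_profile(cm, "chr1", windows = 31), "half the chromosome")
})

test_that("two dense blocks give the insulation minimum at the boundary", {
  n <- 30
  m <- matrix(0.2, n, n)
  m[1:15, 1:15] <- 5
  m[16:30, 16:30] <- 5
  cm <- cm_from_dense(m, state = "balanced")
  prof <- insulation_profile(cm, "chr1", windows = c(3, 5))
  s <- prof$score
  # oracle: global minimum over the brute-force computation
  expect_equal(which.min(s), which.min(insulation_oracle(m, c(3, 5))))
  expect_true(which.min(s) %in% c(15, 16))
})

test_that("a monotone profile yields no TADs", {
  prof <- structure(list(chrom = "chr1", score = seq(-2, 2, length.out = 40),
                         windows = 3L), class = "insulation_profile")
  ts <- call_tads(prof, toy_genome(40))
  expect_equal(ts$boundaries, integer(0))
  expect_equal(nrow(ts$intervals), 1)  # whole chromosome, no internal boundary
})

test_that("planted boundaries are recovered within one bin on the panel", {
  p <- default_panel()
  spec <- p$spec
  bal <- panel_balanced(2)
  arch <- p$archs[[2]]
  hits <- 0; tot <- 0
  for (ch in p$gen$genome$chrom_names) {
    ts <- call_tads(insulation_profile(bal, ch), p$gen$genome)
    iv <- arch$tads$intervals[arch$tads$intervals$chrom == ch, ]
    tb <- unique(c(iv$start, iv$end)) / spec$resolution
    tb <- tb[tb > 0 & tb < spec$bins_per_chrom]
    tot <- tot + length(tb)
    hits <- hits + sum(vapply(tb, function(b) any(abs(ts$boundaries - b) <= 1),
                              logical(1)))
  }
  expect_gte(hits / tot, 0.9)
})

test_that("TAD change classifier equals the rule-table oracle on all offsets", {
  res <- 1000
  for (ds in -5:5) for (de in -5:5) {
    ref <- tad_set(data.frame(chrom = "chr1", start = 100 * res, end = 200 * res))
    qs <- (100 + ds) * res; qe <- (200 + de) * res
    query <- tad_set(data.frame(chrom = "chr1", start = qs, end = qe))
    out <- classify_tad_change(ref, query, res, tol_bins = 1)
    expect_equal(out$records$category, tad_class_oracle(ds, de, 1),
                 info = paste("ds", ds, "de", de))
  }
})

test_that("classifier identity, swap duality and worked examples", {
  res <- 1000
  tad <- function(s, e) tad_set(data.frame(chrom = "chr1", start = s * res, end = e * res))
  expect_equal(classify_tad_change(tad(100, 200), tad(100, 200), res)$records$category,
               "Stable")
  expect_equal(classify_tad_change(tad(100, 200), tad(95, 210), res)$records$category,
               "Expand")
  expect_equal(classify_tad_change(tad(95, 210), tad(100, 200), res)$records$category,
               "Shrink")
  expect_equal(classify_tad_change(tad(100, 200), tad(150, 250), res)$records$category,
               "Shift")
  # Expand/Shrink swap under exchanging ref and query, for every offset pair
  for (ds in c(-4, -2, 0, 2, 4)) for (de in c(-4, 0, 3)) {
    a <- classify_tad_change(tad(100, 200), tad(100 + ds, 200 + de), res)$records$category
    b <- classify_tad_change(tad(100 + ds, 200 + de), tad(100, 200), res)$records$category
    map <- c(Stable = "Stable", Expand = "Shrink", Shrink = "Expand", Shift = "Shift")
    expect_equal(b, unname(map[a]))
  }
})

test_that("matching uses maximal overlap, Absent and proportions behave", {
  res <- 1000
  ref <- tad_set(data.frame(chrom = "chr1", start = c(0, 500 * res),
                            end = c(100 * res, 600 * res)))
  query <- tad_set(data.frame(chrom = "chr1",
                              start = c(0, 60 * res),
                              end = c(50 * res, 100 * res)))
  out <- classify_tad_change(ref, query, res)
  expect_equal(out$records$category, c("Shrink", "Absent"))
  expect_equal(out$records$q_start[1], 0)  # 50-bin overlap beats 40-bin
  expect_equal(sum(out$proportions), 1)
  bad <- data.frame(chrom = "chr1", start = c(0, 40 * res), end = c(50 * res, 80 * res))
  expect_error(tad_set(bad), "overlapping")
})

test_that("planted TAD edits classify perfectly from true sets on the panel", {
  p <- default_panel()
  res <- p$spec$resolution
  for (q in c(2, 5)) {
    out <- classify_tad_change(p$archs[[1]]$tads, p$archs[[q]]$tads, res, 1)
    expect_equal(out$records$category, p$archs[[q]]$tad_classes$class)
  }
  # the scripted roster plants at least 5 of each class panel-wide
  all_cls <- unlist(lapply(p$archs[2:5], function(a) a$tad_classes$class))
  expect_true(all(table(factor(all_cls, c("Stable", "Expand", "Shrink", "Shift"))) >= 5))
})

test_that("eTAD/mTAD assignment follows the half-open TSS rule", {
  res <- 1000
  tads <- tad_set(data.frame(chrom = "chr1", start = c(0, 10 * res),
                             end = c(10 * res, 20 * res)))
  genes <- data.frame(
    chrom = "chr1",
    start = c(0, 10 * res, 19 * res + 999, 5 * res),
    end = c(res, 11 * res, 20 * res, 6 * res),
    name = c("e_at_start", "e_at_second_start", "m_last_base", "m_mid"),
    strand = c("+", "+", "-", "+"),
    class = c("E", "E", "M", "M"))
  out <- assign_emt_tads(tads, genes)
  expect_equal(out$flags$is_eTAD, c(TRUE, TRUE))
  expect_equal(out$flags$is_mTAD, c(TRUE, TRUE))
  # TSS exactly at a TAD end coordinate is outside that TAD
  genes2 <- data.frame(chrom = "chr1", start = 10 * res, end = 11 * res,
                       name = "e", strand = "+", class = "E")
  out2 <- assign_emt_tads(tad_set(data.frame(chrom = "chr1", start = 0,
                                             end = 10 * res)), genes2)
  expect_false(out2$flags$is_eTAD)
  expect_equal(out2$outside, "e")
})

test_that("panel eTAD/mTAD flags equal planted gene placement", {
  p <- default_panel()
  out <- assign_emt_tads(p$gen$ref_tads, p$gen$genes)
  tt <- p$gen$tad_table
  res <- p$spec$resolution
  planted_e <- planted_m <- logical(nrow(tt))
  for (k in seq_len(nrow(tt))) {
    tss <- p$gen$genes$start / res
    inside <- p$gen$genes$chrom == tt$chrom[k] &
      tss >= tt$start_bin[k] & tss < tt$end_bin[k]
    planted_e[k] <- any(inside & p$gen$genes$class == "E")
    planted_m[k] <- any(inside & p$gen$genes$class == "M")
  }
  ord <- order(out$flags$chrom, out$flags$start)
  ord_t <- order(tt$chrom, tt$start)
  expect_equal(out$flags$is_eTAD[ord], planted_e[ord_t])
  expect_equal(out$flags$is_mTAD[ord], planted_m[ord_t])
})
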