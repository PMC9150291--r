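test_that("the generator is deterministic and matches the requested panel dimensions", {
  spec <- panel_spec(seed = 9, bins_per_chrom = 200, n_E_genes = 10,
                     n_M_genes = 8, n_other = 20, depth = 5e4)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$ref_tads$intervals, g2$ref_tads$intervals)
  expect_equal(table(g1$genes$class)[["E"]], 10)
  expect_equal(table(g1$genes$class)[["M"]], 8)
  expect_equal(table(g1$genes$class)[["other"]], 20)

  # minimum TSS spacing: scan every pair on the same chromosome
  bins <- g1$genes$start / spec$resolution
  for (ch in unique(g1$genes$chrom)) {
    b <- sort(bins[g1$genes$chrom == ch])
    if (length(b) > 1) expect_gte(min(diff(b)), 5)
  }

  # changing the seed changes the matrices but planting follows its own seed
  m1 <- simulate_contact_matrix(g1, plant_architecture(g1, spec, 1), spec, 1)
  m2 <- simulate_contact_matrix(g1, plant_architecture(g1, spec, 1), spec, 1)
  expect_identical(m1$cm$entries, m2$cm$entries)
})

test_that("planted architecture: reference identity, flips, roster audit", {
  p <- default_panel()
  spec <- p$spec
  # reference sample: every TAD Stable against itself
  expect_true(all(p$archs[[1]]$tad_classes$class == "Stable"))
  # flip-set M-gene bins: B in the most epithelial, A in the most mesenchymal
  gen <- p$gen
  flip_bins <- bin_index(gen$genome, gen$genes$chrom[gen$genes$flip],
                         gen$genes$start[gen$genes$flip])
  expect_true(all(p$archs[[1]]$v[flip_bins + 1] == -1))
  expect_true(all(p$archs[[spec$n_samples]]$v[flip_bins + 1] == 1))
  # roster audit: each edited sample plants all four classes
  for (s in 2:spec$n_samples) {
    cls <- table(factor(p$archs[[s]]$tad_classes$class,
                        c("Stable", "Expand", "Shrink", "Shift")))
    expect_true(all(cls > 0))
  }
})

test_that("pure decay counts match the Poisson expectation by diagonal", {
  spec <- panel_spec(seed = 3, n_chrom = 1, bins_per_chrom = 150,
                     n_E_genes = 6, n_M_genes = 5, n_other = 10,
                     kappa = 0, lambda = 0, rho = 0, bias_sd = 0, depth = 2e5)
  gen <- generate_genome(spec)
  arch <- plant_architecture(gen, spec, 1)
  sim <- simulate_contact_matrix(gen, arch, spec, 1)
  m <- chrom_dense(sim$cm, "chr1", na_masked = FALSE)
  n <- nrow(m)
  # expected count on diagonal d is proportional to 1/(1+d)
  Z <- sum(vapply(0:(n - 1), function(d) (n - d) / (1 + d), numeric(1)))
  for (d in c(0, 1, 5, 20)) {
    idx <- cbind(seq_len(n - d), seq_len(n - d) + d)
    mu <- spec$depth / Z / (1 + d)
    obs <- mean(m[idx])
    se <- sqrt(mu / (n - d))
    expect_lt(abs(obs - mu), 3.5 * se)
  }
})

test_that("planted loop pixels are enriched over same-distance background", {
  p <- default_panel()
  spec <- p$spec
  s <- spec$n_samples  # most mesenchymal: loops active
  m <- chrom_dense(p$sims[[s]]$cm, "chr1", na_masked = FALSE)
  lp <- p$archs[[s]]$loops
  lp <- lp[lp$chrom == "chr1" & lp$active, ]
  d <- lp$bin_b[1] - lp$bin_a[1]
  expect_true(all(lp$bin_b - lp$bin_a == d))
  loop_mean <- mean(m[cbind(lp$bin_a + 1, lp$bin_b + 1)])
  idx <- cbind(seq_len(nrow(m) - d), seq_len(nrow(m) - d) + d)
  bg <- m[idx]
  bg <- bg[!(idx[, 1] %in% (lp$bin_a + 1))]
  # loops are planted at (1 + rho) times their local expectation
  expect_gt(loop_mean, mean(bg) * (1 + spec$rho) / 2)
  expect_gt(loop_mean, mean(bg) * 1.5)
})

test_that("noiseless-limit and planted slopes of the track generator", {
  p <- default_panel()
  spec <- p$spec
  region <- p$omics$truth$region
  # planted eTAD H3K27me3 differs by slope * score gap before noise; verify
  # the realized per-sample means are ordered with the scores
  g <- p$gen$genome
  e_idx <- region == "eTAD"
  mu <- vapply(seq_len(spec$n_samples), function(s)
    mean(p$omics$tracks[[s]]$H3K27me3$value[e_idx]), numeric(1))
  expect_equal(order(mu), order(spec$emt_scores))
  fit <- coef(lm(mu ~ spec$emt_scores))[2]
  expect_equal(unname(fit), p$omics$truth$slope_k27, tolerance = 0.1)
})

test_that("single-cell generator: twins, radius rule, state separation", {
  sc0 <- simulate_single_cells(n_bins = 60, n_cells_per_state = 2,
                               contact_radius = 3, contacts_per_cell = 200,
                               noise_sd = 0, seed = 5)
  # sigma = 0 twins: identical contact sets within a state
  c1 <- sc0$contacts[sc0$contacts$cell_id == "cell01_E" &
                       sc0$contacts$chrom == "chr10like", c("bin_a", "bin_b")]
  c2 <- sc0$contacts[sc0$contacts$cell_id == "cell02_E" &
                       sc0$contacts$chrom == "chr10like", c("bin_a", "bin_b")]
  expect_equal(sort(paste(c1$bin_a, c1$bin_b)), sort(paste(c2$bin_a, c2$bin_b)))

  sc <- simulate_single_cells(n_bins = 60, n_cells_per_state = 3,
                              contact_radius = 3, contacts_per_cell = 200,
                              noise_sd = 0.3, seed = 6)
  # contacts always satisfy the radius rule in the true coordinates
  for (cell in unique(sc$contacts$cell_id)[1:2]) {
    for (ch in c("chr2like", "chr10like")) {
      cc <- sc$contacts[sc$contacts$cell_id == cell & sc$contacts$chrom == ch, ]
      X <- sc$true_coords[[cell]][[ch]]
      dd <- sqrt(rowSums((X[cc$bin_a + 1, ] - X[cc$bin_b + 1, ])^2))
      expect_true(all(dd < 3))
      expect_true(all(cc$bin_b - cc$bin_a >= 2))
    }
  }
  # state-specific chromosome: inter-state true r.m.s.d exceeds intra-state
  cells <- unique(sc$contacts$cell_id)
  states <- sub(".*_", "", cells)
  structs <- lapply(cells, function(cl) {
    X <- sc$true_coords[[cl]][["chr10like"]]
    structure(list(coords = scale(X, scale = FALSE) /
                     sqrt(mean(rowSums(scale(X, scale = FALSE)^2))),
                   energy = 0, cell_id = cl, chrom = "chr10like",
                   masked_bins = integer(0)), class = "cell_structure")
  })
  m <- rmsd_matrix(structs)
  same <- outer(states, states, "==") & upper.tri(m)
  diff <- outer(states, states, "!=") & upper.tri(m)
  expect_gt(mean(m[diff]), mean(m[same]))
})

test_that("panel files round-trip through the plain-text writers", {
  spec <- panel_spec(seed = 2, bins_per_chrom = 100, n_E_genes = 5,
                     n_M_genes = 5, n_other = 10, depth = 2e4)
  panel <- simulate_panel(spec)
  dir <- withr::local_tempdir()
  write_panel(panel, dir)
  expect_true(file.exists(file.path(dir, "chrom.sizes")))
  cm <- read_contact_matrix(file.path(dir, "line1.triplets.txt"),
                            file.path(dir, "chrom.sizes"), spec$resolution)
  expect_equal(cm$entries, panel$sims[[1]]$cm$entries)
  genes <- read_genes_bed(file.path(dir, "genes.bed"))
  expect_equal(nrow(genes), nrow(panel$gen$genes))
  expect_equal(genes$start, panel$gen$genes$start)
  sig <- read_signature_tsv(file.path(dir, "signature.tsv"))
  expect_setequal(sig$epithelial, panel$gen$signature$epithelial)
  tr <- read_track_bedgraph(file.path(dir, "line1.H3K27me3.bedGraph"))
  expect_equal(nrow(tr), panel$gen$genome$n_bins)
  expect_equal(tr$value, panel$omics$tracks[[1]]$H3K27me3$value, tolerance = 1e-6)
})
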