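# Synthetic panel generator: plants every structure the pipeline is designed
# to recover (compartment plaid, TAD blocks and boundary edits, loops, bin
# biases, EMT-coupled tracks/expression, single-cell conformations), and
# exposes the planted truth for recovery tests.

.subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + k) %% 2147483647)
}

#' Specification of a synthetic EMT cell-line panel
#'
#' Defines the study conditions emulated by the generator: a small panel of
#' cell lines spread along the EMT spectrum, each with a binned Hi-C matrix,
#' histone tracks and expression, over a toy genome.
#'
#' @param n_chrom number of chromosomes (default 2).
#' @param bins_per_chrom bins per chromosome (default 400).
#' @param resolution bin width in bp (default 50000).
#' @param emt_scores per-sample latent EMT scores, ascending, in \[-1, 1\]
#'   (default five lines from strongly epithelial to strongly mesenchymal,
#'   with the two endpoints at the characteristic scores of an E-state and
#'   an M-state ovarian line).
#' @param n_E_genes,n_M_genes,n_other gene counts (defaults 30/20/100).
#' @param flip_fraction fraction of M genes planted with a B-to-A
#'   compartment flip in mesenchymal-like samples (default 0.4).
#' @param depth expected total intra-chromosomal counts per chromosome
#'   (default 2e5).
#' @param bias_sd log-normal sd of planted per-bin biases (default 0.3).
#' @param kappa,lambda,rho compartment plaid, TAD enrichment and loop
#'   enrichment strengths (defaults 0.6, 1.0, 3.0).
#' @param seed master seed (default 1).
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(n_chrom = 2, bins_per_chrom = 400, resolution = 50000,
                       emt_scores = c(-0.6, -0.328, 0.05, 0.4, 0.643),
                       n_E_genes = 30, n_M_genes = 20, n_other = 60,
                       flip_fraction = 0.4, depth = 2e5, bias_sd = 0.3,
                       kappa = 0.6, lambda = 1.0, rho = 3.0, seed = 1) {
  stopifnot(n_chrom >= 1, bins_per_chrom >= 50,
            all(diff(emt_scores) >= 0), all(abs(emt_scores) <= 1),
            n_E_genes > 0, n_M_genes > 0, depth > 0)
  structure(list(
    n_chrom = n_chrom, bins_per_chrom = bins_per_chrom, resolution = resolution,
    n_samples = length(emt_scores), emt_scores = emt_scores,
    sample_ids = paste0("line", seq_along(emt_scores)),
    n_E_genes = n_E_genes, n_M_genes = n_M_genes, n_other = n_other,
    flip_fraction = flip_fraction, depth = depth, bias_sd = bias_sd,
    kappa = kappa, lambda = lambda, rho = rho, seed = seed
  ), class = "panel_spec")
}

#' Generate the toy genome, reference TADs, compartment blocks and genes
#'
#' Lays out, deterministically per seed: reference TADs of 10-15 bins tiling
#' each chromosome; compartment blocks (runs of 1-2 TADs) with alternating
#' A/B sign; E genes seeded one per TAD into A-block TADs (eTADs-to-be),
#' M genes one per TAD into B-block TADs (mTADs-to-be); non-signature genes
#' scattered elsewhere. All TSSs sit at distinct bins at least 5 bins apart.
#' A seeded subset of M-gene-bearing B blocks is designated to flip B-to-A
#' in mesenchymal-like samples.
#'
#' @param spec a [panel_spec()].
#' @return list with `genome` ([binned_genome()]), `genes` (data.frame with
#'   `chrom`, `start`, `end`, `name`, `strand`, `class`, `flip`),
#'   `ref_tads` ([tad_set()]), `blocks` (per-chrom block table with planted
#'   sign and flip flag), `signature` (E/M gene id sets).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  # random TAD/block layouts occasionally lack room for every gene; retry
  # with a fresh (still seed-determined) layout
  err <- NULL
  for (attempt in 0:9) {
    out <- tryCatch(.generate_genome_once(spec, attempt),
                    error = function(e) e)
    if (!inherits(out, "error")) return(out)
    if (!grepl("genome too small", conditionMessage(out))) stop(out)
    err <- out
  }
  stop(err)
}

.generate_genome_once <- function(spec, attempt) {
  set.seed(.subseed(spec$seed, 1 + 97 * attempt))
  res <- spec$resolution
  sizes <- stats::setNames(rep(spec$bins_per_chrom * res, spec$n_chrom),
                           paste0("chr", seq_len(spec$n_chrom)))
  genome <- binned_genome(sizes, res)

  tads <- list(); blocks <- list()
  for (ch in genome$chrom_names) {
    nb <- spec$bins_per_chrom
    bnd <- 0L
    while (utils::tail(bnd, 1) < nb) {
      bnd <- c(bnd, utils::tail(bnd, 1) + sample(10:15, 1))
    }
    bnd[length(bnd)] <- nb
    if (diff(utils::tail(bnd, 2)) < 10) bnd <- bnd[-(length(bnd) - 1)]
    nt <- length(bnd) - 1L
    tads[[ch]] <- data.frame(chrom = ch, start = bnd[-length(bnd)] * res,
                             end = bnd[-1] * res,
                             start_bin = bnd[-length(bnd)], end_bin = bnd[-1])
    # compartment blocks: runs of 1-2 consecutive TADs, alternating sign
    run <- sample(1:2, nt, replace = TRUE)
    grp <- rep(seq_along(run), run)[seq_len(nt)]
    sgn <- rep(c(1, -1), length.out = max(grp))
    blocks[[ch]] <- data.frame(
      chrom = ch,
      start_bin = tapply(tads[[ch]]$start_bin, grp, min),
      end_bin = tapply(tads[[ch]]$end_bin, grp, max),
      sign = sgn[seq_len(max(grp))]
    )
    tads[[ch]]$block <- grp
    tads[[ch]]$block_sign <- sgn[grp]
  }
  tad_df <- do.call(rbind, tads)
  block_df <- do.call(rbind, blocks)
  rownames(tad_df) <- rownames(block_df) <- NULL

  mid_bin <- function(t) (t$start_bin + t$end_bin) %/% 2
  a_tads <- tad_df[tad_df$block_sign > 0, ]
  b_tads <- tad_df[tad_df$block_sign < 0, ]
  if (nrow(a_tads) < spec$n_E_genes || nrow(b_tads) < spec$n_M_genes)
    stop("genome too small for requested gene counts")
  e_rows <- a_tads[sample(nrow(a_tads), spec$n_E_genes), ]
  m_rows <- b_tads[sample(nrow(b_tads), spec$n_M_genes), ]

  mk_gene <- function(rows, prefix, class) {
    bins <- mid_bin(rows)
    data.frame(chrom = rows$chrom,
               start = bins * spec$resolution,
               end = (bins + 1) * spec$resolution,
               name = paste0(prefix, seq_len(nrow(rows))),
               strand = sample(c("+", "-"), nrow(rows), replace = TRUE),
               class = class)
  }
  e_genes <- mk_gene(e_rows, "Egene", "E")
  m_genes <- mk_gene(m_rows, "Mgene", "M")

  # non-signature genes: greedy placement >= 5 bins from every placed TSS,
  # enriched in A blocks (gene-dense regions are the active compartment, the
  # property that lets gene density orient PC1)
  used <- data.frame(chrom = c(e_genes$chrom, m_genes$chrom),
                     bin = c(e_genes$start, m_genes$start) %/% res)
  bin_sign <- function(ch, bin) {
    bl <- block_df[block_df$chrom == ch, ]
    bl$sign[bl$start_bin <= bin & bl$end_bin > bin][1]
  }
  others <- list()
  cand <- do.call(rbind, lapply(genome$chrom_names, function(ch)
    data.frame(chrom = ch, bin = 5:(spec$bins_per_chrom - 6))))
  cand <- cand[sample(nrow(cand)), ]
  cand$keep_p <- ifelse(vapply(seq_len(nrow(cand)), function(k)
    bin_sign(cand$chrom[k], cand$bin[k]), numeric(1)) > 0, 0.95, 0.1)
  cand$draw <- stats::runif(nrow(cand))
  for (pass in 1:2) {
    for (k in seq_len(nrow(cand))) {
      if (length(others) >= spec$n_other) break
      if (pass == 1 && cand$draw[k] > cand$keep_p[k]) next
      near <- used$chrom == cand$chrom[k] & abs(used$bin - cand$bin[k]) < 5
      if (any(near)) next
      others[[length(others) + 1L]] <- cand[k, c("chrom", "bin")]
      used <- rbind(used, cand[k, c("chrom", "bin")])
    }
  }
  if (length(others) < spec$n_other)
    stop("genome too small to place ", spec$n_other, " non-signature genes")
  o_df <- do.call(rbind, others)
  o_genes <- data.frame(chrom = o_df$chrom,
                        start = o_df$bin * res, end = (o_df$bin + 1) * res,
                        name = paste0("gene", seq_len(nrow(o_df))),
                        strand = sample(c("+", "-"), nrow(o_df), replace = TRUE),
                        class = "other")
  genes <- rbind(e_genes, m_genes, o_genes)
  rownames(genes) <- NULL

  # flip designation: sample M-bearing B blocks until ~flip_fraction of the
  # M genes sit in flipping blocks
  m_bin <- m_genes$start %/% res
  block_key <- paste(block_df$chrom, seq_len(nrow(block_df)))
  m_block <- vapply(seq_len(nrow(m_genes)), function(g) {
    hit <- which(block_df$chrom == m_genes$chrom[g] &
                   block_df$start_bin <= m_bin[g] & block_df$end_bin > m_bin[g])
    hit[1]
  }, numeric(1))
  target <- round(spec$flip_fraction * spec$n_M_genes)
  flip_blocks <- integer(0)
  for (bk in sample(unique(m_block))) {
    if (sum(m_block %in% flip_blocks) >= target) break
    flip_blocks <- c(flip_blocks, bk)
  }
  block_df$flip <- seq_len(nrow(block_df)) %in% flip_blocks
  genes$flip <- FALSE
  genes$flip[genes$class == "M"] <- m_block %in% flip_blocks

  list(genome = genome,
       genes = genes,
       ref_tads = tad_set(tad_df[, c("chrom", "start", "end")], sample_id = "reference"),
       tad_table = tad_df,
       blocks = block_df,
       signature = structure(list(epithelial = e_genes$name,
                                  mesenchymal = m_genes$name),
                             class = "emt_signature"))
}

#' Plant the per-sample architecture
#'
#' For one sample of the panel: the compartment eigenvector (blocky +/-1,
#' with designated flip blocks switched to A when the sample's EMT score is
#' positive), the sample's TAD set (reference boundaries moved by a scripted
#' roster of offsets producing Stable/Expand/Shrink/Shift edits; the
#' reference sample gets offsets of zero), the implied true change class of
#' every reference TAD, and the loop list (M-gene TSS to enhancer pairs,
#' active only when the EMT score is positive).
#'
#' @param gen output of [generate_genome()].
#' @param spec the [panel_spec()].
#' @param sample_index sample number (1 = reference, most epithelial).
#' @return list with `v` (per-bin +/-1), `labels` (per-bin "A"/"B"),
#'   `tads` ([tad_set()]), `tad_classes` (true class per reference TAD),
#'   `loops` (data.frame `chrom`, `bin_a`, `bin_b`, `active`).
#' @export
plant_architecture <- function(gen, spec, sample_index) {
  stopifnot(sample_index >= 1, sample_index <= spec$n_samples)
  score <- spec$emt_scores[sample_index]
  g <- gen$genome
  res <- spec$resolution

  # scripted boundary-offset roster (deterministic per seed and sample)
  set.seed(.subseed(spec$seed, 100 + sample_index))
  iv_list <- list(); cls_list <- list()
  v <- numeric(g$n_bins)
  patterns <- list(Expand = c(-3L, 3L), Shrink = c(3L, -3L),
                   ShiftR = c(3L, 3L), ShiftL = c(-3L, -3L))
  for (ch in g$chrom_names) {
    tt <- gen$tad_table[gen$tad_table$chrom == ch, ]
    bl <- gen$blocks[gen$blocks$chrom == ch, ]
    nt <- nrow(tt)
    bnd <- c(tt$start_bin, tt$end_bin[nt])   # nt + 1 boundaries
    off <- integer(nt + 1)
    if (sample_index > 1) {
      targets <- seq(3, nt - 2, by = 4)
      pat <- rep(names(patterns), length.out = length(targets))
      pat <- sample(pat)                     # shuffle the roster order
      for (q in seq_along(targets)) {
        t <- targets[q]
        off[t] <- patterns[[pat[q]]][1]
        off[t + 1] <- patterns[[pat[q]]][2]
      }
    }
    qbnd <- bnd + off
    iv_list[[ch]] <- data.frame(chrom = ch,
                                start = qbnd[-length(qbnd)] * res,
                                end = qbnd[-1] * res)
    # compartment sign follows the (possibly shifted) TAD intervals, so block
    # transitions stay aligned with domain boundaries in every sample
    gb <- chrom_bins(g, ch)
    for (k in seq_len(nt)) {
      sgn <- tt$block_sign[k]
      if (bl$flip[tt$block[k]] && score > 0) sgn <- +1
      v[gb[(qbnd[k] + 1):qbnd[k + 1]] + 1L] <- sgn
    }
    # implied true class of each reference TAD from its boundary offsets
    cls <- vapply(seq_len(nt), function(k) {
      .classify_pair(0, 0, off[k] * res, off[k + 1] * res, res)
    }, character(1))
    cls_list[[ch]] <- data.frame(chrom = ch, start = tt$start, end = tt$end,
                                 class = cls)
  }
  labels <- ifelse(v > 0, "A", "B")
  tads <- tad_set(do.call(rbind, iv_list), sample_id = spec$sample_ids[sample_index])
  tad_classes <- do.call(rbind, cls_list)
  rownames(tad_classes) <- NULL

  # loops: M-gene TSS <-> intra-TAD enhancer, active in mesenchymal samples
  mg <- gen$genes[gen$genes$class == "M", ]
  loops <- do.call(rbind, lapply(seq_len(nrow(mg)), function(k) {
    tssb <- mg$start[k] %/% res
    tt <- gen$tad_table
    row <- tt[tt$chrom == mg$chrom[k] & tt$start_bin <= tssb & tt$end_bin > tssb, ][1, ]
    enh <- if (tssb + 4 < row$end_bin) tssb + 4 else tssb - 4
    data.frame(chrom = mg$chrom[k], bin_a = min(tssb, enh),
               bin_b = max(tssb, enh), gene = mg$name[k])
  }))
  loops$active <- score > 0
  list(v = v, labels = labels, tads = tads, tad_classes = tad_classes,
       loops = loops, emt_score = score,
       sample_id = spec$sample_ids[sample_index])
}

#' Simulate a raw contact matrix for one planted architecture
#'
#' Expected counts follow a power-law distance decay modulated by the
#' compartment plaid, TAD enrichment, loop enrichment and per-bin biases:
#' `mu_ij = depth * Z^-1 * (1+|i-j|)^-1 * exp(kappa v_i v_j) *
#' (1 + lambda [same TAD]) * (1 + rho [loop pixel]) * b_i b_j`, normalized so
#' the expected intra-chromosomal total equals `depth` per chromosome;
#' counts are Poisson. A small uniform inter-chromosomal background
#' (10% of depth) is added. Biases `b` are log-normal(0, `bias_sd`).
#'
#' @param gen output of [generate_genome()].
#' @param arch output of [plant_architecture()].
#' @param spec the [panel_spec()].
#' @param sample_index sample number (seeds the draw).
#' @return list with `cm` (raw [contact_matrix()]) and `bias` (planted
#'   per-bin bias vector).
#' @export
simulate_contact_matrix <- function(gen, arch, spec, sample_index) {
  set.seed(.subseed(spec$seed, 200 + sample_index))
  g <- gen$genome
  n <- g$n_bins
  b <- exp(stats::rnorm(n, 0, spec$bias_sd))
  entries <- list()
  for (ch in g$chrom_names) {
    gb <- chrom_bins(g, ch)
    nb <- length(gb)
    loc <- seq_len(nb)
    dmat <- abs(outer(loc, loc, "-"))
    vv <- arch$v[gb + 1L]
    base <- (1 + dmat)^(-1) * exp(spec$kappa * outer(vv, vv))
    # TAD and loop enrichment
    tadiv <- arch$tads$intervals[arch$tads$intervals$chrom == ch, ]
    tid <- rep(0L, nb)
    for (k in seq_len(nrow(tadiv))) {
      sb <- tadiv$start[k] %/% g$resolution
      eb <- ceiling(tadiv$end[k] / g$resolution)
      tid[(sb + 1):eb] <- k
    }
    same <- outer(tid, tid, "==") & tid > 0
    base <- base * (1 + spec$lambda * same)
    if (any(arch$loops$active)) {
      lp <- arch$loops[arch$loops$chrom == ch & arch$loops$active, , drop = FALSE]
      for (k in seq_len(nrow(lp))) {
        ia <- lp$bin_a[k] + 1L; ib <- lp$bin_b[k] + 1L
        base[ia, ib] <- base[ia, ib] * (1 + spec$rho)
        base[ib, ia] <- base[ib, ia] * (1 + spec$rho)
      }
    }
    bb <- b[gb + 1L]
    base <- base * outer(bb, bb)
    ut <- upper.tri(base, diag = TRUE)
    mu <- base
    mu[ut] <- spec$depth * base[ut] / sum(base[ut])
    cnt <- stats::rpois(sum(ut), mu[ut])
    idx <- which(ut, arr.ind = TRUE)
    keep <- cnt > 0
    entries[[ch]] <- data.frame(i = gb[idx[keep, 1]], j = gb[idx[keep, 2]],
                                x = cnt[keep])
  }
  # uniform inter-chromosomal background
  if (length(g$chrom_names) > 1) {
    for (a in 1:(length(g$chrom_names) - 1)) for (bq in (a + 1):length(g$chrom_names)) {
      ga <- chrom_bins(g, g$chrom_names[a]); gbq <- chrom_bins(g, g$chrom_names[bq])
      mu_i <- 0.1 * spec$depth / (length(ga) * length(gbq)) *
        outer(b[ga + 1L], b[gbq + 1L])
      cnt <- stats::rpois(length(mu_i), mu_i)
      keep <- cnt > 0
      idx <- which(array(TRUE, dim(mu_i)), arr.ind = TRUE)[keep, , drop = FALSE]
      if (nrow(idx))
        entries[[paste(a, bq)]] <- data.frame(i = ga[idx[, 1]], j = gbq[idx[, 2]],
                                              x = cnt[keep])
    }
  }
  cm <- contact_matrix(g, do.call(rbind, entries))
  list(cm = cm, bias = b)
}

#' Simulate histone tracks and expression for one sample
#'
#' Planted pattern: the mean H3K27me3 in eTADs rises linearly with the EMT
#' score and H3K27ac falls with it; mTAD marks carry no score dependence --
#' their across-line variation comes from a line-specific nuisance component
#' constructed orthogonal to the score vector, so the planted null is exact.
#' E-gene expression decreases and M-gene expression increases monotonically
#' in the score; flip-set M genes are instead coupled to their planted
#' compartment sign (low in B, high in A).
#'
#' @param gen output of [generate_genome()].
#' @param archs list of [plant_architecture()] outputs, one per sample.
#' @param spec the [panel_spec()].
#' @param track_noise_sd per-bin track noise (default 0.1).
#' @param expr_noise_sd per-gene log2 expression noise (default 0.15).
#' @param slope_k27 score slope of eTAD histone means (default 0.5).
#' @return list with `tracks` (per sample: per mark data.frame chrom, start,
#'   end, value), `fpkm` (gene x sample matrix), `truth` (planted slopes and
#'   nuisance vectors).
#' @export
simulate_tracks_and_expression <- function(gen, archs, spec,
                                           track_noise_sd = 0.1,
                                           expr_noise_sd = 0.15,
                                           slope_k27 = 0.5) {
  set.seed(.subseed(spec$seed, 300))
  g <- gen$genome
  scores <- spec$emt_scores
  ns <- spec$n_samples
  # nuisance: line-specific variation orthogonalized against the score
  orth_nuisance <- function() {
    z <- stats::rnorm(ns)
    r <- stats::residuals(stats::lm(z ~ scores))
    r / stats::sd(r)
  }
  nuis <- list(H3K27me3 = orth_nuisance(), H3K27ac = orth_nuisance())

  tt <- gen$tad_table
  m_bins_tad <- function(row) {
    gb <- chrom_bins(g, row$chrom)
    gb[(row$start_bin + 1):row$end_bin] + 1L
  }
  e_tss <- gen$genes$start[gen$genes$class == "E"] %/% g$resolution
  m_tss <- gen$genes$start[gen$genes$class == "M"] %/% g$resolution
  in_tad <- function(row, tssb, chs, chrom) {
    any(chs == chrom & tssb >= row$start_bin & tssb < row$end_bin)
  }
  e_ch <- gen$genes$chrom[gen$genes$class == "E"]
  m_ch <- gen$genes$chrom[gen$genes$class == "M"]
  etad_rows <- which(vapply(seq_len(nrow(tt)), function(k)
    in_tad(tt[k, ], e_tss, e_ch, tt$chrom[k]), logical(1)))
  mtad_rows <- which(vapply(seq_len(nrow(tt)), function(k)
    in_tad(tt[k, ], m_tss, m_ch, tt$chrom[k]), logical(1)))

  region <- rep("other", g$n_bins)
  for (k in etad_rows) region[m_bins_tad(tt[k, ])] <- "eTAD"
  for (k in mtad_rows) region[m_bins_tad(tt[k, ])] <- "mTAD"

  tracks <- vector("list", ns)
  names(tracks) <- spec$sample_ids
  for (s in seq_len(ns)) {
    set.seed(.subseed(spec$seed, 300 + s))
    val27me3 <- 1 + stats::rnorm(g$n_bins, 0, track_noise_sd)
    val27ac <- 1 + 0.15 * (archs[[s]]$labels == "A") +
      stats::rnorm(g$n_bins, 0, track_noise_sd)
    # the enhancer mark tracks the active compartment and carries no EMT
    # dependence; it is the activity track of choice for orienting PC1
    val4me1 <- 1 + 0.3 * (archs[[s]]$labels == "A") +
      stats::rnorm(g$n_bins, 0, track_noise_sd)
    e_idx <- region == "eTAD"; m_idx <- region == "mTAD"
    val27me3[e_idx] <- val27me3[e_idx] + slope_k27 * scores[s]
    val27ac[e_idx] <- val27ac[e_idx] - slope_k27 * scores[s]
    val27me3[m_idx] <- val27me3[m_idx] + 0.4 * nuis$H3K27me3[s]
    val27ac[m_idx] <- val27ac[m_idx] + 0.4 * nuis$H3K27ac[s]
    mk <- function(v) data.frame(chrom = g$bins$chrom, start = g$bins$start,
                                 end = g$bins$end, value = v)
    tracks[[s]] <- list(H3K27me3 = mk(val27me3), H3K27ac = mk(val27ac),
                        H3K4me1 = mk(val4me1))
  }

  set.seed(.subseed(spec$seed, 400))
  genes <- gen$genes
  ng <- nrow(genes)
  base_other <- stats::runif(ng, 2, 6)
  fpkm <- matrix(0, ng, ns, dimnames = list(genes$name, spec$sample_ids))
  for (s in seq_len(ns)) {
    lg <- numeric(ng)
    for (k in seq_len(ng)) {
      noise <- stats::rnorm(1, 0, expr_noise_sd)
      lg[k] <- if (genes$class[k] == "E") {
        5 - 2 * scores[s] + noise
      } else if (genes$class[k] == "M" && genes$flip[k]) {
        bsign <- archs[[s]]$labels[bin_index(g, genes$chrom[k], genes$start[k]) + 1L]
        2 + 3 * (bsign == "A") + noise
      } else if (genes$class[k] == "M") {
        3 + 2 * scores[s] + noise
      } else {
        base_other[k] + noise
      }
    }
    fpkm[, s] <- 2^lg
  }
  list(tracks = tracks, fpkm = fpkm,
       truth = list(region = region, nuisance = nuis, slope_k27 = slope_k27,
                    etad_rows = etad_rows, mtad_rows = mtad_rows))
}

#' Generate the full synthetic panel
#'
#' Convenience wrapper running [generate_genome()], [plant_architecture()],
#' [simulate_contact_matrix()] and [simulate_tracks_and_expression()] for
#' every sample.
#'
#' @param spec a [panel_spec()].
#' @param matrices also simulate contact matrices (default TRUE; tracks and
#'   expression are always generated).
#' @return object of class `emt_panel`: `spec`, `gen`, `archs`, `sims`
#'   (per-sample `cm` + `bias`), `omics` (tracks/fpkm/truth).
#' @export
simulate_panel <- function(spec, matrices = TRUE) {
  gen <- generate_genome(spec)
  archs <- lapply(seq_len(spec$n_samples), function(s)
    plant_architecture(gen, spec, s))
  sims <- if (matrices)
    lapply(seq_len(spec$n_samples), function(s)
      simulate_contact_matrix(gen, archs[[s]], spec, s))
  else NULL
  omics <- simulate_tracks_and_expression(gen, archs, spec)
  structure(list(spec = spec, gen = gen, archs = archs, sims = sims,
                 omics = omics),
            class = "emt_panel")
}

#' @export
print.emt_panel <- function(x, ...) {
  cat("emt_panel:", x$spec$n_samples, "samples,", x$spec$n_chrom,
      "chromosomes x", x$spec$bins_per_chrom, "bins,",
      nrow(x$gen$genes), "genes\n")
  invisible(x)
}

#' Simulate single-cell Hi-C contacts from planted conformations
#'
#' One base conformation (a smoothed random walk with unit mean bond length)
#' per state per chromosome; the shared chromosome ("chr2like") uses one
#' conformation for all states while the state-specific chromosome
#' ("chr10like") gets a distinct conformation per state. Each cell perturbs
#' its state's conformation with isotropic Gaussian noise; its contacts are
#' all bin pairs (separation >= 2) closer than `contact_radius`, subsampled
#' to `contacts_per_cell`.
#'
#' @param n_bins particles per chromosome (default 200).
#' @param n_cells_per_state cells per state (default 10).
#' @param states state labels (default c("E", "M")).
#' @param contact_radius capture radius in conformation units (default 4).
#' @param contacts_per_cell contacts retained per cell and chromosome
#'   (default 1000).
#' @param noise_sd per-cell coordinate perturbation (default 0.3).
#' @param seed random seed.
#' @return list with `contacts` (data.frame cell_id, state, chrom, bin_a,
#'   bin_b), `true_coords` (per cell, per chrom matrices), `base_coords`.
#' @export
simulate_single_cells <- function(n_bins = 200, n_cells_per_state = 10,
                                  states = c("E", "M"), contact_radius = 4,
                                  contacts_per_cell = 1000, noise_sd = 0.3,
                                  seed = 1) {
  set.seed(.subseed(seed, 500))
  # smoothed self-avoiding walk: correlated Gaussian steps, then an
  # excluded-volume relaxation that pushes non-neighbour particles apart
  # (deeply crumpled conformations are unrealistic and poorly constrained
  # by proximity contacts)
  walk <- function(rep_dist = 1.0, relax_iters = 60) {
    steps <- matrix(stats::rnorm(3 * (n_bins + 6)), ncol = 3)
    sm <- apply(steps, 2, function(z) stats::filter(z, rep(1 / 7, 7), sides = 2))
    sm <- sm[stats::complete.cases(sm), , drop = FALSE][seq_len(n_bins - 1), ]
    X <- rbind(0, apply(sm, 2, cumsum))
    X <- X / mean(sqrt(rowSums(diff(X)^2)))
    for (it in seq_len(relax_iters)) {
      D <- as.matrix(stats::dist(X))
      close <- which(D < rep_dist & abs(row(D) - col(D)) > 1 & upper.tri(D),
                     arr.ind = TRUE)
      if (!nrow(close)) break
      for (k in seq_len(nrow(close))) {
        i <- close[k, 1]; j <- close[k, 2]
        v <- X[i, ] - X[j, ]
        dn <- sqrt(sum(v^2))
        v <- if (dn < 1e-6) stats::rnorm(3) * 0.1 else v / dn
        push <- 0.3 * (rep_dist - dn)
        X[i, ] <- X[i, ] + v * push / 2
        X[j, ] <- X[j, ] - v * push / 2
      }
      # soften bond lengths back toward 1 after the pushes
      for (b in seq_len(nrow(X) - 1)) {
        v <- X[b + 1, ] - X[b, ]
        dn <- sqrt(sum(v^2))
        X[b + 1, ] <- X[b, ] + v / dn * (0.5 + 0.5 * dn)
      }
    }
    X / mean(sqrt(rowSums(diff(X)^2)))
  }
  chroms <- c("chr2like", "chr10like")
  base <- list()
  shared <- walk()
  for (st in states) {
    base[[st]] <- list(chr2like = shared,
                       chr10like = walk())
  }
  contacts <- list(); true_coords <- list()
  cid <- 0L
  for (st in states) for (cc in seq_len(n_cells_per_state)) {
    cid <- cid + 1L
    cell <- sprintf("cell%02d_%s", cid, st)
    true_coords[[cell]] <- list()
    for (ch in chroms) {
      X <- base[[st]][[ch]] + matrix(stats::rnorm(3 * n_bins, 0, noise_sd), ncol = 3)
      true_coords[[cell]][[ch]] <- X
      D <- as.matrix(stats::dist(X))
      sep <- abs(row(D) - col(D))
      cand <- which(D < contact_radius & sep >= 2 & upper.tri(D), arr.ind = TRUE)
      if (nrow(cand) > contacts_per_cell)
        cand <- cand[sample(nrow(cand), contacts_per_cell), , drop = FALSE]
      contacts[[paste(cell, ch)]] <- data.frame(
        cell_id = cell, state = st, chrom = ch,
        bin_a = cand[, 1] - 1L, bin_b = cand[, 2] - 1L)
    }
  }
  list(contacts = do.call(rbind, contacts), true_coords = true_coords,
       base_coords = base)
}
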