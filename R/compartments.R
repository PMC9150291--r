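#' A/B compartment eigenvector (PC1)
#'
#' Leading eigenvector of the O/E Pearson correlation matrix of one
#' chromosome, computed on the unmasked submatrix and scaled to unit norm.
#' The eigenvector sign is arbitrary, so it is oriented against an activity
#' track (gene density or an active chromatin mark): the sign is flipped if
#' needed so that the Pearson correlation between PC1 and the track is
#' non-negative, making positive PC1 the active (A) compartment.
#'
#' @param corr a [correlation_matrix()].
#' @param orientation_track per-bin activity values for the chromosome
#'   (length = number of chromosome bins).
#' @return per-bin numeric PC1 vector, NA at masked bins.
#' @export
compute_pc1 <- function(corr, orientation_track) {
  stopifnot(inherits(corr, "correlation_matrix"))
  n <- nrow(corr$values)
  if (length(orientation_track) != n)
    stop("orientation_track must cover all ", n, " bins of the chromosome")
  unm <- which(!corr$mask)
  sub <- corr$values[unm, unm, drop = FALSE]
  sub[is.na(sub)] <- 0
  ev <- eigen(sub, symmetric = TRUE)
  v <- ev$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  r <- suppressWarnings(stats::cor(v, orientation_track[unm]))
  if (is.na(r) || r == 0)
    stop("orientation undetermined: supply a different orientation track")
  if (r < 0) v <- -v
  pc1 <- rep(NA_real_, n)
  pc1[unm] <- v
  pc1
}

#' Smoothed gene-density orientation track
#'
#' Per-bin TSS count smoothed with a boxcar window, the default activity
#' track used to orient PC1 (gene-dense regions are the active A
#' compartment).
#'
#' @param genome a [binned_genome()].
#' @param genes gene data.frame (`chrom`, `start`, `end`, `strand`).
#' @param smooth_bins half-width of the boxcar smoother (default 5; wider
#'   windows blur density across compartment-block boundaries).
#' @return per-bin numeric vector over the whole genome.
#' @export
gene_density_track <- function(genome, genes, smooth_bins = 5) {
  tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  bins <- bin_index(genome, genes$chrom, tss)
  dens <- tabulate(bins + 1L, nbins = genome$n_bins)
  out <- numeric(genome$n_bins)
  for (ch in genome$chrom_names) {
    gb <- chrom_bins(genome, ch) + 1L
    d <- dens[gb]
    n <- length(d)
    sm <- vapply(seq_len(n), function(i)
      mean(d[max(1, i - smooth_bins):min(n, i + smooth_bins)]), numeric(1))
    out[gb] <- sm
  }
  out
}

#' Label bins as A or B from PC1
#'
#' Positive PC1 is A (active); zero or negative is B. The tie at exactly zero
#' is broken toward the inactive compartment.
#'
#' @param pc1 per-bin PC1 values (NA = masked).
#' @return character vector of `"A"`, `"B"`, or NA.
#' @export
label_compartments <- function(pc1) {
  ifelse(is.na(pc1), NA_character_, ifelse(pc1 > 0, "A", "B"))
}

#' Compartment label of each gene
#'
#' A gene takes the A/B label of the bin containing its transcription start
#' site. For minus-strand genes the TSS is the annotated end of the interval.
#'
#' @param labels per-bin labels for the whole genome (A/B/NA), in global bin
#'   order.
#' @param genome a [binned_genome()].
#' @param genes data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand` (0-based half-open, as BED).
#' @return character vector of labels named by gene, NA where the TSS bin is
#'   masked.
#' @export
gene_compartment <- function(labels, genome, genes) {
  tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  bins <- bin_index(genome, genes$chrom, tss)
  stats::setNames(labels[bins + 1L], genes$name)
}

#' Classify compartment switches between two samples
#'
#' The ordered pair of labels (sample 1, sample 2) determines the class:
#' AA and BB are stable, AB switches active to inactive, BA inactive to
#' active. Genes masked in either sample are excluded (NA).
#'
#' @param labels_s1,labels_s2 per-gene labels (named, same genes).
#' @return factor with levels AA, BB, AB, BA, named by gene; NA where
#'   excluded.
#' @export
classify_switch <- function(labels_s1, labels_s2) {
  if (length(labels_s1) != length(labels_s2) ||
      (!is.null(names(labels_s1)) && !is.null(names(labels_s2)) &&
       !identical(names(labels_s1), names(labels_s2))))
    stop("label vectors must cover the same genes in the same order")
  cls <- ifelse(is.na(labels_s1) | is.na(labels_s2), NA_character_,
                paste0(labels_s1, labels_s2))
  factor(cls, levels = c("AA", "BB", "AB", "BA")) |>
    stats::setNames(names(labels_s1))
}

#' Stable vs dynamic compartment membership across a sample panel
#'
#' A gene is `stable` if its label is identical in every sample, `dynamic`
#' otherwise. Genes masked in any sample are excluded.
#'
#' @param label_list list (length >= 2) of per-gene label vectors.
#' @return character vector `"stable"`/`"dynamic"`/NA per gene.
#' @export
compartment_dynamics <- function(label_list) {
  if (length(label_list) < 2) stop("need at least 2 samples")
  lab <- do.call(cbind, label_list)
  apply(lab, 1, function(z) {
    if (anyNA(z)) NA_character_
    else if (length(unique(z)) == 1) "stable" else "dynamic"
  })
}

#' Expression concordance of compartment switches
#'
#' A gene switching A-to-B is concordant if its expression drops
#' (log2 fold change sample1 -> sample2 below `-threshold`); a B-to-A gene
#' is concordant if expression rises (log2FC above `+threshold`).
#' Concordance is defined only for the dynamic classes AB and BA.
#'
#' @param switch per-gene switch factor from [classify_switch()].
#' @param log2fc per-gene log2 fold change, sample1 -> sample2.
#' @param threshold minimum |log2FC| to count as a directional change
#'   (default 0: any directional change counts).
#' @return list with `concordant` (per-gene logical, NA outside AB/BA),
#'   `fraction` and `n` per switch class (AB, BA).
#' @export
expression_concordance <- function(switch, log2fc, threshold = 0) {
  stopifnot(length(switch) == length(log2fc))
  conc <- rep(NA, length(switch))
  ab <- !is.na(switch) & switch == "AB"
  ba <- !is.na(switch) & switch == "BA"
  conc[ab] <- log2fc[ab] < -threshold
  conc[ba] <- log2fc[ba] > threshold
  frac <- c(AB = mean(conc[ab]), BA = mean(conc[ba]))
  list(concordant = stats::setNames(conc, names(switch)),
       fraction = frac,
       n = c(AB = sum(ab), BA = sum(ba)))
}

#' Per-gene correlation of PC1 with expression across samples
#'
#' @param pc1_mat gene x sample matrix of PC1 values at the gene TSS bin.
#' @param z_mat gene x sample matrix of expression z-scores, same samples in
#'   the same order.
#' @return per-gene Pearson r, NA where either vector has zero variance.
#' @export
pc1_expression_correlation <- function(pc1_mat, z_mat) {
  if (!identical(dim(pc1_mat), dim(z_mat)) ||
      !identical(colnames(pc1_mat), colnames(z_mat)))
    stop("sample sets of the two matrices do not match")
  if (ncol(pc1_mat) < 3) stop("need at least 3 samples")
  r <- vapply(seq_len(nrow(pc1_mat)), function(g) {
    x <- pc1_mat[g, ]; y <- z_mat[g, ]
    if (anyNA(x) || anyNA(y) || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  stats::setNames(r, rownames(pc1_mat))
}

#' Eight-class nested sub-compartments
#'
#' A simplified nested sub-compartment caller. Each bin receives a
#' compartment score: its mean correlation with the 10% most A-like bins
#' (highest PC1). Within A and within B separately, bins are split at the
#' median score (A.1/A.2, B.1/B.2) and each half is split again at its own
#' median, giving eight ranked classes A.1.1 > A.1.2 > A.2.1 > A.2.2 >
#' B.1.1 > B.1.2 > B.2.1 > B.2.2. The class prefix always agrees with the
#' A/B label (exact nesting).
#'
#' @param corr a [correlation_matrix()].
#' @param pc1 per-bin PC1 for the same chromosome.
#' @return character vector of sub-compartment labels, NA at masked bins.
#' @export
call_subcompartments <- function(corr, pc1) {
  stopifnot(inherits(corr, "correlation_matrix"))
  n <- nrow(corr$values)
  stopifnot(length(pc1) == n)
  unm <- which(!corr$mask & !is.na(pc1))
  if (length(unm) < 16) stop("too few bins: need >= 16 unmasked bins")
  k <- max(1L, ceiling(0.10 * length(unm)))
  ref <- unm[order(pc1[unm], decreasing = TRUE)][seq_len(k)]
  score <- rowMeans(corr$values[, ref, drop = FALSE], na.rm = TRUE)
  lab <- label_compartments(pc1)
  out <- rep(NA_character_, n)
  for (side in c("A", "B")) {
    idx <- unm[lab[unm] == side]
    if (!length(idx)) next
    s <- score[idx]
    hi <- s > stats::median(s)
    for (lev2 in c(TRUE, FALSE)) {
      sub <- idx[hi == lev2]
      if (!length(sub)) next
      s2 <- score[sub]
      hi2 <- s2 > stats::median(s2)
      out[sub[hi2]]  <- paste0(side, ".", if (lev2) "1.1" else "2.1")
      out[sub[!hi2]] <- paste0(side, ".", if (lev2) "1.2" else "2.2")
    }
  }
  out
}
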