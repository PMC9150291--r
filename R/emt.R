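#' Refine an EMT gene signature from multiple sources
#'
#' Combines tumor-derived and cell-line-derived epithelial/mesenchymal gene
#' lists with a hallmark EMT gene list. A gene enters the refined epithelial
#' set if it appears in at least `min_sources` of the three sources on the
#' epithelial side (tumor-E, line-E, hallmark), and likewise for the
#' mesenchymal set. Genes qualifying for both classes are dropped with a
#' warning.
#'
#' @param sig_tumor list with `E` and `M` character vectors.
#' @param sig_line list with `E` and `M` character vectors.
#' @param hallmark character vector of hallmark EMT genes (class-agnostic).
#' @param min_sources membership threshold (default 2 of 3).
#' @return object of class `emt_signature`: list with `epithelial`,
#'   `mesenchymal` gene sets.
#' @export
refine_signature <- function(sig_tumor, sig_line, hallmark, min_sources = 2) {
  count_in <- function(universe, sets) {
    vapply(universe, function(g) sum(vapply(sets, function(s) g %in% s, logical(1))),
           numeric(1))
  }
  e_univ <- unique(c(sig_tumor$E, sig_line$E, hallmark))
  m_univ <- unique(c(sig_tumor$M, sig_line$M, hallmark))
  E <- e_univ[count_in(e_univ, list(sig_tumor$E, sig_line$E, hallmark)) >= min_sources]
  M <- m_univ[count_in(m_univ, list(sig_tumor$M, sig_line$M, hallmark)) >= min_sources]
  both <- intersect(E, M)
  if (length(both)) {
    warning("dropping ", length(both), " gene(s) assigned to both classes: ",
            paste(both, collapse = ", "))
    E <- setdiff(E, both)
    M <- setdiff(M, both)
  }
  if (!length(E) || !length(M))
    stop("signature refinement left an empty class")
  structure(list(epithelial = E, mesenchymal = M), class = "emt_signature")
}

#' @export
print.emt_signature <- function(x, ...) {
  cat("emt_signature:", length(x$epithelial), "epithelial,",
      length(x$mesenchymal), "mesenchymal genes\n")
  invisible(x)
}

#' Per-gene expression z-scores across samples
#'
#' log2(FPKM + pseudocount), standardized per gene across samples. Genes
#' with zero variance get z = 0.
#'
#' @param fpkm gene x sample matrix of FPKM values.
#' @param pseudocount added before log2 (default 1).
#' @return gene x sample matrix of z-scores.
#' @export
expression_zscores <- function(fpkm, pseudocount = 1) {
  lg <- log2(fpkm + pseudocount)
  mu <- rowMeans(lg)
  sd <- apply(lg, 1, stats::sd)
  z <- (lg - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Scalar EMT score per sample
#'
#' Places each sample on the epithelial (negative) to mesenchymal (positive)
#' axis: half the difference between the mean expression z-score of the
#' mesenchymal signature genes and that of the epithelial genes, clipped to
#' \[-1, 1\]. Signature genes absent from the table are ignored (their count
#' is reported in attribute `"n_missing"`).
#'
#' @param z gene x sample z-score matrix (see [expression_zscores()]).
#' @param sig an [refine_signature()] signature (or any list with
#'   `epithelial`/`mesenchymal`).
#' @return named numeric vector of per-sample scores in \[-1, 1\].
#' @export
emt_score <- function(z, sig) {
  e <- intersect(sig$epithelial, rownames(z))
  m <- intersect(sig$mesenchymal, rownames(z))
  n_missing <- (length(sig$epithelial) - length(e)) +
    (length(sig$mesenchymal) - length(m))
  if (!length(e) && !length(m)) stop("no signature genes present in the table")
  me <- if (length(e)) colMeans(z[e, , drop = FALSE]) else 0
  mm <- if (length(m)) colMeans(z[m, , drop = FALSE]) else 0
  s <- (mm - me) / 2
  s <- stats::setNames(pmin(1, pmax(-1, s)), colnames(z))
  attr(s, "n_missing") <- n_missing
  s
}

#' Base-pair-weighted mean signal over intervals
#'
#' Mean bedGraph-style signal over each query interval, weighting by covered
#' bases; bases not covered by the track contribute value 0.
#'
#' @param track data.frame with `chrom`, `start`, `end`, `value` (0-based
#'   half-open, sorted, non-overlapping per chromosome).
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @return numeric vector of per-interval means.
#' @export
mean_signal_in_intervals <- function(track, intervals) {
  if (!nrow(intervals)) return(numeric(0))
  if (!nrow(track)) return(rep(0, nrow(intervals)))
  t_gr <- GenomicRanges::GRanges(track$chrom,
                                 IRanges::IRanges(track$start + 1, track$end))
  q_gr <- GenomicRanges::GRanges(intervals$chrom,
                                 IRanges::IRanges(intervals$start + 1, intervals$end))
  hits <- GenomicRanges::findOverlaps(q_gr, t_gr)
  qi <- S4Vectors::queryHits(hits); ti <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(q_gr)[qi],
                                           IRanges::ranges(t_gr)[ti]))
  tot <- numeric(nrow(intervals))
  if (length(qi)) {
    agg <- rowsum(ov * track$value[ti], qi)
    tot[as.integer(rownames(agg))] <- agg[, 1]
  }
  tot / (intervals$end - intervals$start)
}

#' Pearson correlation of a per-sample signal with the EMT score
#'
#' @param scores named per-sample EMT scores.
#' @param signals named per-sample mean signal values (same samples).
#' @return list with `r`, `p` (two-sided, t distribution with n-2 df), `n`.
#' @export
correlate_score_signal <- function(scores, signals) {
  if (!all(names(scores) %in% names(signals)) || length(scores) != length(signals))
    stop("sample ids of scores and signals do not match")
  signals <- signals[names(scores)]
  if (length(scores) < 3) stop("need at least 3 samples")
  if (stats::sd(scores) == 0 || stats::sd(signals) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(scores)))
  ct <- stats::cor.test(scores, signals, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(scores))
}

#' Two-group difference test
#'
#' Wilcoxon rank-sum (normal approximation with tie correction, no
#' continuity correction) or Welch two-sample t test; two-sided.
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @param kind `"wilcoxon"` or `"t"`.
#' @return list with `statistic` (W or t) and `p`.
#' @export
group_difference_test <- function(values_a, values_b, kind = c("wilcoxon", "t")) {
  kind <- match.arg(kind)
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 values")
  if (kind == "wilcoxon") {
    ht <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = FALSE, correct = FALSE))
    list(statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
    list(statistic = unname(ht$statistic), p = ht$p.value)
  }
}

#' Per-gene log2 expression fold change between two samples
#'
#' @param fpkm gene x sample FPKM matrix.
#' @param sample_a,sample_b column names; the fold change is a -> b.
#' @param pseudocount added to both FPKM values (default 1).
#' @return named per-gene log2((FPKM_b + c) / (FPKM_a + c)).
#' @export
expression_foldchange <- function(fpkm, sample_a, sample_b, pseudocount = 1) {
  if (!all(c(sample_a, sample_b) %in% colnames(fpkm)))
    stop("sample not present in expression table")
  log2((fpkm[, sample_b] + pseudocount) / (fpkm[, sample_a] + pseudocount))
}
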