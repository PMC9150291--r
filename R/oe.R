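#' Observed/expected transform
#'
#' Removes the distance-decay expectation. Per chromosome, the expected value
#' at separation `d` bins is the mean over all unmasked pixel positions on
#' diagonal `d` (implicit zeros included); each pixel is divided by its
#' diagonal's expectation. Diagonals with zero expectation are undefined and
#' masked in the output. Inter-chromosomal pixels are divided by a single
#' whole-matrix inter-chromosomal expectation.
#'
#' By construction the mean of every unmasked intra-chromosomal diagonal of
#' the output is exactly 1.
#'
#' @param cm a `balanced` [contact_matrix()] (a `raw` one is accepted with a
#'   warning).
#' @return an `oe` [contact_matrix()]; the per-chromosome expected-by-distance
#'   vectors are attached as attribute `"expected"`.
#' @export
observed_over_expected <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$state == "oe") stop("matrix is already in O/E state")
  if (cm$state == "raw")
    warning("computing O/E on an unbalanced matrix")
  g <- cm$genome
  e <- cm$entries
  mask <- cm$mask
  chrom_of_bin <- rep(g$chrom_names, g$n_bins_chrom)
  ci <- chrom_of_bin[e$i + 1L]
  cj <- chrom_of_bin[e$j + 1L]
  unmasked_pix <- !(mask[e$i + 1L] | mask[e$j + 1L])

  expected <- list()
  xout <- e$x
  for (chrom in g$chrom_names) {
    gb <- chrom_bins(g, chrom)
    nb <- length(gb)
    unm <- !mask[gb + 1L]
    sel <- which(ci == chrom & cj == chrom)
    d <- e$j[sel] - e$i[sel]
    # unmasked pixel positions per diagonal (zeros included in the mean)
    idx <- which(unm)
    npos <- vapply(0:(nb - 1L), function(dd) {
      if (length(idx) == 0) return(0L)
      sum(unm[seq_len(nb - dd)] & unm[seq_len(nb - dd) + dd])
    }, integer(1))
    ssum <- numeric(nb)
    okpix <- unmasked_pix[sel]
    if (length(sel)) {
      agg <- rowsum(e$x[sel][okpix], d[okpix])
      ssum[as.integer(rownames(agg)) + 1L] <- agg[, 1]
    }
    expd <- ifelse(npos > 0, ssum / npos, 0)
    expected[[chrom]] <- expd
    if (length(sel)) {
      denom <- expd[d + 1L]
      xout[sel] <- ifelse(denom > 0, e$x[sel] / denom, NA_real_)
    }
  }
  inter <- which(ci != cj)
  if (length(inter)) {
    # single genome-wide inter-chromosomal expectation over unmasked pixels
    unm_per_chrom <- vapply(g$chrom_names,
                            function(ch) sum(!mask[chrom_bins(g, ch) + 1L]), numeric(1))
    tot_unm <- sum(unm_per_chrom)
    n_inter_pos <- (tot_unm^2 - sum(unm_per_chrom^2)) / 2
    inter_sum <- sum(e$x[inter][unmasked_pix[inter]])
    inter_exp <- if (n_inter_pos > 0) inter_sum / n_inter_pos else 0
    xout[inter] <- if (inter_exp > 0) e$x[inter] / inter_exp else NA_real_
    attr(expected, "inter") <- inter_exp
  }
  keep <- !is.na(xout)
  out <- contact_matrix(g, data.frame(i = e$i[keep], j = e$j[keep], x = xout[keep]),
                        state = "raw", bias = cm$bias, mask = mask)
  out$state <- "oe"
  attr(out, "expected") <- expected
  out
}

#' Pearson correlation matrix of O/E rows
#'
#' Correlates every pair of O/E rows of one chromosome over the unmasked
#' columns, excluding the diagonal entries of the two rows being compared
#' (self-contact pixels would otherwise dominate). Masked bins yield masked
#' rows/columns.
#'
#' @param oe an `oe` [contact_matrix()].
#' @param chrom chromosome name.
#' @return object of class `correlation_matrix`: list with `chrom`, `values`
#'   (dense symmetric matrix, NA for masked), `mask` (per-bin, chromosome
#'   local).
#' @export
correlation_matrix <- function(oe, chrom) {
  stopifnot(inherits(oe, "contact_matrix"))
  if (oe$state != "oe") stop("correlation_matrix expects an O/E matrix")
  m <- chrom_dense(oe, chrom)
  n <- nrow(m)
  gb <- chrom_bins(oe$genome, chrom)
  mask <- oe$mask[gb + 1L]
  if (sum(!mask) < 8) stop("too few bins: need >= 8 unmasked bins")
  diag(m) <- NA_real_
  suppressWarnings(cv <- stats::cor(m, use = "pairwise.complete.obs"))
  diag(cv)[!mask] <- 1
  cv[mask, ] <- NA_real_
  cv[, mask] <- NA_real_
  structure(list(chrom = chrom, values = cv, mask = mask),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("correlation_matrix:", x$chrom, "-", nrow(x$values), "bins,",
      sum(!x$mask), "unmasked\n")
  invisible(x)
}
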