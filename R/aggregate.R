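#' Area-weighted rescaling of a square matrix
#'
#' Rescales an n x n matrix to `out` x `out` by averaging input pixels with
#' weights proportional to their area overlap with each output pixel; the
#' overall matrix mean is conserved. NA input pixels are dropped with weight
#' renormalization.
#'
#' @param m square numeric matrix.
#' @param out output side length.
#' @return `out` x `out` matrix.
#' @export
rescale_matrix <- function(m, out) {
  n <- nrow(m)
  stopifnot(n == ncol(m))
  # W[a, i] = overlap of output cell a with input cell i on the unit axis
  W <- matrix(0, out, n)
  for (a in seq_len(out)) {
    lo <- (a - 1) * n / out
    hi <- a * n / out
    i0 <- floor(lo) + 1
    i1 <- min(n, ceiling(hi))
    for (i in i0:i1) {
      ov <- min(hi, i) - max(lo, i - 1)
      if (ov > 0) W[a, i] <- ov
    }
  }
  W <- W / (n / out)  # rows sum to 1
  if (anyNA(m)) {
    ok <- !is.na(m)
    m0 <- ifelse(ok, m, 0)
    num <- W %*% m0 %*% t(W)
    den <- W %*% (ok + 0) %*% t(W)
    out_m <- ifelse(den > 0, num / den, NA_real_)
  } else {
    out_m <- W %*% m %*% t(W)
  }
  out_m
}

#' Aggregate TAD analysis
#'
#' Averages the rescaled O/E sub-matrix of every TAD (with 10% flanks) into
#' one aggregate matrix, and reports the mean interior O/E of each TAD
#' (excluding the first `exclude_diagonals` diagonals) for box-plot style
#' comparisons.
#'
#' @param oe an `oe` [contact_matrix()].
#' @param tads a [tad_set()] (TADs shorter than 5 bins, or whose flanked
#'   window leaves the chromosome, are skipped).
#' @param out_bins side length of the aggregate matrix (odd, >= 9;
#'   default 21).
#' @param exclude_diagonals diagonals dropped from the interior mean
#'   (default 2).
#' @param flank_fraction flank width as a fraction of TAD size (default 0.1).
#' @return object of class `aggregate_result`: `mean_matrix`,
#'   `interior_mean` (per TAD), `n`.
#' @export
aggregate_tads <- function(oe, tads, out_bins = 21, exclude_diagonals = 2,
                           flank_fraction = 0.1) {
  stopifnot(inherits(oe, "contact_matrix"), oe$state == "oe")
  if (out_bins < 9) stop("out_bins must be >= 9")
  if (out_bins %% 2 == 0) stop("out_bins must be odd")
  g <- oe$genome
  res <- g$resolution
  iv <- tads$intervals
  dense <- lapply(stats::setNames(nm = unique(iv$chrom)),
                  function(ch) chrom_dense(oe, ch))
  acc <- matrix(0, out_bins, out_bins)
  wacc <- matrix(0, out_bins, out_bins)
  interior <- numeric(0)
  n_used <- 0L
  for (k in seq_len(nrow(iv))) {
    sb <- iv$start[k] %/% res
    eb <- ceiling(iv$end[k] / res)
    L <- eb - sb
    if (L < 5) next
    f <- max(1L, round(flank_fraction * L))
    nb <- g$n_bins_chrom[[iv$chrom[k]]]
    if (sb - f < 0 || eb + f > nb) next
    m <- dense[[iv$chrom[k]]][(sb - f + 1):(eb + f), (sb - f + 1):(eb + f)]
    r <- rescale_matrix(m, out_bins)
    ok <- !is.na(r)
    acc[ok] <- acc[ok] + r[ok]
    wacc <- wacc + ok
    core <- dense[[iv$chrom[k]]][(sb + 1):eb, (sb + 1):eb]
    dmat <- abs(row(core) - col(core))
    interior <- c(interior, mean(core[dmat >= exclude_diagonals], na.rm = TRUE))
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no TADs >= 5 bins usable for aggregation")
  structure(list(mean_matrix = ifelse(wacc > 0, acc / wacc, NA_real_),
                 interior_mean = interior, n = n_used),
            class = "aggregate_result")
}

#' @export
print.aggregate_result <- function(x, ...) {
  cat("aggregate_result:", x$n, "instances,",
      nrow(x$mean_matrix), "x", ncol(x$mean_matrix), "aggregate matrix\n")
  invisible(x)
}

#' Locus pairs: EMT gene TSS vs other gene TSSs in the same TAD
#'
#' Enumerates pairs (signature-gene TSS, non-signature-gene TSS) whose TSSs
#' fall inside the same TAD and lie at least `min_sep_bins` bins apart.
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `name`, `strand`,
#'   `class` ("E"/"M"/other).
#' @param tads a [tad_set()].
#' @param genome a [binned_genome()].
#' @param emt_class which signature class anchors the pairs ("E" or "M").
#' @param min_sep_bins minimum TSS separation in bins (default 3).
#' @return data.frame of locus pairs: `name`, `chrom`, `pos_a`, `pos_b`
#'   (anchor = signature gene).
#' @export
pairs_within_tads <- function(genes, tads, genome, emt_class = c("M", "E"),
                              min_sep_bins = 3) {
  emt_class <- match.arg(emt_class)
  tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  iv <- tads$intervals
  out <- list()
  for (k in seq_len(nrow(iv))) {
    inside <- which(genes$chrom == iv$chrom[k] &
                      tss >= iv$start[k] & tss < iv$end[k])
    sig <- inside[genes$class[inside] == emt_class]
    oth <- inside[!(genes$class[inside] %in% c("E", "M"))]
    if (!length(sig) || !length(oth)) next
    for (a in sig) for (b in oth) {
      if (abs(bin_index(genome, genes$chrom[a], tss[a]) -
              bin_index(genome, genes$chrom[b], tss[b])) >= min_sep_bins) {
        out[[length(out) + 1L]] <- data.frame(
          name = paste(genes$name[a], genes$name[b], sep = "|"),
          chrom = genes$chrom[a], pos_a = tss[a], pos_b = tss[b])
      }
    }
  }
  if (!length(out)) return(data.frame(name = character(0), chrom = character(0),
                                      pos_a = numeric(0), pos_b = numeric(0)))
  do.call(rbind, out)
}

#' Aggregate contacts at locus pairs
#'
#' Stacks O/E sub-matrices of side `2 * half_window_bins + 1` centered on
#' each pair's bin coordinates, z-scores the pooled pixel distribution (one
#' global mean/sd over all windows, or per window with
#' `per_window = TRUE`), and returns the mean matrix together with each
#' pair's center-pixel z-score. Pairs whose window leaves the chromosome are
#' skipped with a message.
#'
#' @param oe an `oe` [contact_matrix()].
#' @param pairs data.frame from [pairs_within_tads()] (columns `name`,
#'   `chrom`, `pos_a`, `pos_b`).
#' @param half_window_bins window half-size in bins (default 5).
#' @param per_window z-score each window against its own mean/sd instead of
#'   the pooled distribution (default FALSE).
#' @return `aggregate_result` with `mean_matrix` (raw O/E), `mean_z`
#'   (z-scored aggregate), `center_z` (per pair), `n`.
#' @export
aggregate_pairs <- function(oe, pairs, half_window_bins = 5, per_window = FALSE) {
  stopifnot(inherits(oe, "contact_matrix"), oe$state == "oe")
  h <- half_window_bins
  side <- 2L * h + 1L
  g <- oe$genome
  dense <- lapply(stats::setNames(nm = unique(pairs$chrom)),
                  function(ch) chrom_dense(oe, ch))
  stack <- list()
  used <- character(0)
  for (k in seq_len(nrow(pairs))) {
    ch <- pairs$chrom[k]
    nb <- g$n_bins_chrom[[ch]]
    ba <- (pairs$pos_a[k] %/% g$resolution)
    bb <- (pairs$pos_b[k] %/% g$resolution)
    lo <- min(ba, bb); hi <- max(ba, bb)
    if (lo - h < 0 || hi + h >= nb) {
      message("skipping out-of-bounds pair ", pairs$name[k])
      next
    }
    stack[[length(stack) + 1L]] <-
      dense[[ch]][(lo - h + 1):(lo + h + 1), (hi - h + 1):(hi + h + 1)]
    used <- c(used, pairs$name[k])
  }
  if (!length(stack)) stop("zero usable pairs")
  arr <- array(unlist(stack), dim = c(side, side, length(stack)))
  if (per_window) {
    zarr <- arr
    for (k in seq_len(dim(arr)[3])) {
      w <- arr[, , k]
      zarr[, , k] <- (w - mean(w, na.rm = TRUE)) / stats::sd(w, na.rm = TRUE)
    }
  } else {
    mu <- mean(arr, na.rm = TRUE)
    sg <- stats::sd(arr, na.rm = TRUE)
    zarr <- (arr - mu) / sg
  }
  cz <- zarr[h + 1L, h + 1L, ]
  structure(list(
    mean_matrix = apply(arr, c(1, 2), mean, na.rm = TRUE),
    mean_z = apply(zarr, c(1, 2), mean, na.rm = TRUE),
    center_z = stats::setNames(cz, used),
    n = length(stack)
  ), class = "aggregate_result")
}

#' Extract O/E values at locus pairs
#'
#' Value of the O/E pixel containing the two anchor points of each pair;
#' masked pixels give NA. Symmetric in anchor order.
#'
#' @param oe an `oe` [contact_matrix()].
#' @param pairs data.frame with `name`, `chrom`, `pos_a`, `pos_b`.
#' @return named numeric vector of O/E values.
#' @export
extract_oe_pairs <- function(oe, pairs) {
  stopifnot(inherits(oe, "contact_matrix"), oe$state == "oe")
  g <- oe$genome
  out <- numeric(nrow(pairs))
  dense <- lapply(stats::setNames(nm = unique(pairs$chrom)),
                  function(ch) chrom_dense(oe, ch))
  for (k in seq_len(nrow(pairs))) {
    ba <- pairs$pos_a[k] %/% g$resolution
    bb <- pairs$pos_b[k] %/% g$resolution
    out[k] <- dense[[pairs$chrom[k]]][ba + 1L, bb + 1L]
  }
  stats::setNames(out, pairs$name)
}

#' Normalize 3C-qPCR interaction frequencies
#'
#' Relative interaction frequency from quantification cycles, assuming
#' perfect doubling per cycle: `2^(Ct_loading - Ct_target)` per replicate,
#' then averaged with the replicate standard deviation reported.
#'
#' @param ct data.frame with columns `pair`, `ct_target`, `ct_loading` (one
#'   row per replicate).
#' @return data.frame per pair: `frequency` (mean over replicates), `sd`,
#'   `n_rep`.
#' @export
normalize_3c <- function(ct) {
  stopifnot(all(c("pair", "ct_target", "ct_loading") %in% names(ct)))
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_loading)))
    stop("non-finite Ct value")
  f <- 2^(ct$ct_loading - ct$ct_target)
  pairs <- unique(ct$pair)
  do.call(rbind, lapply(pairs, function(p) {
    v <- f[ct$pair == p]
    data.frame(pair = p, frequency = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_rep = length(v))
  }))
}
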