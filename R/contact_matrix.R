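#' Sparse binned Hi-C contact matrix
#'
#' A symmetric contact matrix stored as upper-triangle triplets
#' (`i <= j`, global 0-based bin indices). `state` tracks the processing
#' stage: `"raw"` counts, `"balanced"` after iterative correction, or `"oe"`
#' after the observed/expected transform. `mask` marks bins excluded from
#' analysis (low coverage); `bias` holds cooler-style multiplicative
#' balancing weights (`balanced = raw * bias_i * bias_j`).
#'
#' @param genome a [binned_genome()].
#' @param entries data.frame with columns `i`, `j`, `x` (global 0-based bins,
#'   value); folded to the upper triangle with duplicates summed.
#' @param state one of `"raw"`, `"balanced"`, `"oe"`.
#' @param bias optional per-bin weight vector (length `n_bins`).
#' @param mask optional logical per-bin exclusion vector (TRUE = excluded).
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(genome, entries, state = "raw", bias = NULL, mask = NULL) {
  stopifnot(inherits(genome, "binned_genome"))
  state <- match.arg(state, c("raw", "balanced", "oe"))
  if (nrow(entries) > 0) {
    i <- as.integer(entries$i); j <- as.integer(entries$j); x <- as.numeric(entries$x)
    if (any(i < 0 | i >= genome$n_bins | j < 0 | j >= genome$n_bins))
      stop("bin index out of range for genome with ", genome$n_bins, " bins")
    if (state == "raw" && any(x < 0)) stop("negative count in contact entries")
    swap <- i > j
    ii <- ifelse(swap, j, i); jj <- ifelse(swap, i, j)
    key <- paste(ii, jj)
    agg <- rowsum(x, key, reorder = FALSE)
    first <- !duplicated(key)
    entries <- data.frame(i = ii[first], j = jj[first], x = as.numeric(agg[, 1]))
    entries <- entries[order(entries$i, entries$j), , drop = FALSE]
    rownames(entries) <- NULL
  } else {
    entries <- data.frame(i = integer(0), j = integer(0), x = numeric(0))
  }
  if (is.null(mask)) mask <- rep(FALSE, genome$n_bins)
  stopifnot(length(mask) == genome$n_bins)
  if (!is.null(bias)) stopifnot(length(bias) == genome$n_bins)
  structure(
    list(genome = genome, entries = entries, state = state, bias = bias, mask = mask),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix [", x$state, "]: ", nrow(x$entries), " non-zero pixels, ",
      sum(!x$mask), "/", x$genome$n_bins, " bins unmasked\n", sep = "")
  invisible(x)
}

#' Read a sparse triplet contact file
#'
#' Whitespace-separated lines `bin_i bin_j count` with global 0-based bin
#' indices. Lower-triangle triplets are folded to the upper triangle and
#' duplicate pairs are summed.
#'
#' @param path triplet file.
#' @param sizes_path chrom.sizes file (see [read_chrom_sizes()]).
#' @param resolution bin width in bp.
#' @return a `raw` [contact_matrix()].
#' @export
read_contact_matrix <- function(path, sizes_path, resolution) {
  genome <- binned_genome(read_chrom_sizes(sizes_path), resolution)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(contact_matrix(genome, data.frame(i = integer(0), j = integer(0), x = numeric(0))))
  }
  df <- utils::read.table(path, header = FALSE, col.names = c("i", "j", "x"))
  if (nrow(df) == 0)
    return(contact_matrix(genome, data.frame(i = integer(0), j = integer(0), x = numeric(0))))
  bad <- which(df$i < 0 | df$i >= genome$n_bins | df$j < 0 | df$j >= genome$n_bins)
  if (length(bad))
    stop("bin index out of range at line ", bad[1], ": ",
         df$i[bad[1]], " ", df$j[bad[1]], " ", df$x[bad[1]])
  bad <- which(df$x < 0)
  if (length(bad)) stop("negative count at line ", bad[1])
  contact_matrix(genome, data.frame(i = df$i, j = df$j, x = df$x))
}

#' Write a contact matrix as sparse triplets
#' @param cm a [contact_matrix()].
#' @param path output file.
#' @export
write_contact_matrix <- function(cm, path) {
  utils::write.table(cm$entries, path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Dense intra-chromosomal block of a contact matrix
#'
#' Returns the full symmetric dense matrix for one chromosome, with implicit
#' zeros filled in. Masked bins become NA rows/columns when `na_masked`.
#'
#' @param cm a [contact_matrix()].
#' @param chrom chromosome name.
#' @param na_masked set masked rows/columns to NA (default TRUE).
#' @return dense numeric matrix (n_chrom_bins x n_chrom_bins).
#' @export
chrom_dense <- function(cm, chrom, na_masked = TRUE) {
  gb <- chrom_bins(cm$genome, chrom)
  n <- length(gb)
  off <- gb[1]
  e <- cm$entries
  sel <- e$i >= gb[1] & e$i <= gb[n] & e$j >= gb[1] & e$j <= gb[n]
  m <- matrix(0, n, n)
  if (any(sel)) {
    ii <- e$i[sel] - off + 1L; jj <- e$j[sel] - off + 1L
    m[cbind(ii, jj)] <- e$x[sel]
    m[cbind(jj, ii)] <- e$x[sel]
  }
  if (cm$state == "oe") {
    # diagonals whose expected value was zero are undefined, not zero
    expd <- attr(cm, "expected")[[chrom]]
    if (!is.null(expd)) {
      for (d in which(expd == 0) - 1L) {
        idx <- seq_len(n - d)
        m[cbind(idx, idx + d)] <- NA_real_
        m[cbind(idx + d, idx)] <- NA_real_
      }
    }
  }
  if (na_masked) {
    mk <- cm$mask[gb + 1L]
    m[mk, ] <- NA_real_
    m[, mk] <- NA_real_
  }
  m
}

#' Per-bin marginals (symmetric row sums) of a contact matrix
#' @param cm a [contact_matrix()].
#' @return numeric vector of length `n_bins`.
#' @export
matrix_marginals <- function(cm) {
  n <- cm$genome$n_bins
  m <- numeric(n)
  e <- cm$entries
  if (nrow(e)) {
    add_i <- rowsum(e$x, e$i)
    m[as.integer(rownames(add_i)) + 1L] <- m[as.integer(rownames(add_i)) + 1L] + add_i[, 1]
    off <- e$i != e$j
    if (any(off)) {
      add_j <- rowsum(e$x[off], e$j[off])
      m[as.integer(rownames(add_j)) + 1L] <- m[as.integer(rownames(add_j)) + 1L] + add_j[, 1]
    }
  }
  m
}

#' Write a per-bin vector as bedGraph
#'
#' @param genome a [binned_genome()].
#' @param values per-bin numeric vector (NA bins are skipped).
#' @param path output file.
#' @export
write_bin_bedgraph <- function(genome, values, path) {
  stopifnot(length(values) == genome$n_bins)
  keep <- !is.na(values)
  df <- genome$bins[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end),
                               score = values[keep])
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}
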