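#' Binned genome
#'
#' Partition a genome into fixed-width bins. Bins tile each chromosome in
#' order, without gaps or overlap; the last bin of a chromosome may be short.
#' Global bin indices are 0-based and contiguous across chromosomes, matching
#' the sparse triplet file convention. Coordinates are 0-based half-open
#' throughout, as in BED.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp; the
#'   order of names fixes the chromosome order.
#' @param resolution bin width in bp.
#' @return An object of class `binned_genome` with fields `chrom_names`,
#'   `chrom_sizes`, `resolution`, `bins` (data.frame: chrom, start, end),
#'   `n_bins`, and `offset` (first global bin index per chromosome).
#' @export
binned_genome <- function(chrom_sizes, resolution) {
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == ""))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  if (resolution <= 0) stop("resolution must be positive")
  chrom_names <- names(chrom_sizes)
  nb <- as.integer(ceiling(chrom_sizes / resolution))
  offset <- c(0L, cumsum(nb))[seq_along(nb)]
  names(offset) <- chrom_names
  bins <- do.call(rbind, lapply(seq_along(chrom_names), function(k) {
    start <- seq(0, by = resolution, length.out = nb[k])
    data.frame(
      chrom = chrom_names[k],
      start = start,
      end = pmin(start + resolution, chrom_sizes[k]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(bins) <- NULL
  structure(
    list(
      chrom_names = chrom_names,
      chrom_sizes = chrom_sizes,
      resolution = resolution,
      bins = bins,
      n_bins = sum(nb),
      n_bins_chrom = stats::setNames(nb, chrom_names),
      offset = offset
    ),
    class = "binned_genome"
  )
}

#' @export
print.binned_genome <- function(x, ...) {
  cat("binned_genome:", length(x$chrom_names), "chromosome(s),",
      x$n_bins, "bins at", x$resolution, "bp\n")
  invisible(x)
}

#' Read a UCSC-style chrom.sizes file
#'
#' @param path two-column file: chromosome name, length in bp (tab or space
#'   separated).
#' @return named numeric vector of sizes.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chrom.sizes file needs two columns: chrom, length")
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Map genomic positions to global bin indices
#'
#' Bin index is `floor(pos / resolution)` within the chromosome, offset to the
#' global 0-based index.
#'
#' @param genome a [binned_genome()].
#' @param chrom chromosome names (recycled against `pos`).
#' @param pos 0-based positions in bp.
#' @return integer vector of global 0-based bin indices.
#' @export
bin_index <- function(genome, chrom, pos) {
  stopifnot(inherits(genome, "binned_genome"))
  bad <- !(chrom %in% genome$chrom_names)
  if (any(bad)) stop("unknown chromosome: ", paste(unique(chrom[bad]), collapse = ", "))
  sizes <- genome$chrom_sizes[chrom]
  if (any(pos < 0 | pos >= sizes))
    stop("position outside chromosome bounds")
  as.integer(genome$offset[chrom] + floor(pos / genome$resolution))
}

#' Global bin index range of one chromosome
#' @param genome a [binned_genome()].
#' @param chrom chromosome name.
#' @return integer vector of the chromosome's global 0-based bin indices.
#' @export
chrom_bins <- function(genome, chrom) {
  stopifnot(chrom %in% genome$chrom_names)
  off <- genome$offset[[chrom]]
  seq.int(off, off + genome$n_bins_chrom[[chrom]] - 1L)
}
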