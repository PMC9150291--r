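#' Filter single-cell Hi-C contacts
#'
#' Per cell and chromosome: drops self-pairs, pairs closer than
#' `min_separation_bins`, duplicate (unordered) pairs, and every contact of
#' any "promiscuous" bin whose contact count exceeds `promiscuity_factor`
#' times the median per-bin contact count (over bins with at least one
#' contact).
#'
#' @param contacts data.frame with `cell_id`, `chrom`, `bin_a`, `bin_b`
#'   (chromosome-local bin indices).
#' @param min_separation_bins minimum |bin_a - bin_b| (default 2).
#' @param promiscuity_factor multiple of the median per-bin count above
#'   which a bin's contacts are all removed (default 8).
#' @return filtered data.frame, same columns, with `bin_a < bin_b`.
#' @export
filter_sc_contacts <- function(contacts, min_separation_bins = 2,
                               promiscuity_factor = 8) {
  a <- pmin(contacts$bin_a, contacts$bin_b)
  b <- pmax(contacts$bin_a, contacts$bin_b)
  df <- data.frame(cell_id = contacts$cell_id, chrom = contacts$chrom,
                   bin_a = a, bin_b = b)
  df <- df[df$bin_b - df$bin_a >= min_separation_bins, , drop = FALSE]
  df <- df[!duplicated(df), , drop = FALSE]
  out <- list()
  for (key in unique(paste(df$cell_id, df$chrom))) {
    sub <- df[paste(df$cell_id, df$chrom) == key, , drop = FALSE]
    cnt <- table(c(sub$bin_a, sub$bin_b))
    med <- stats::median(as.numeric(cnt))
    promiscuous <- as.integer(names(cnt)[as.numeric(cnt) > promiscuity_factor * med])
    keep <- !(sub$bin_a %in% promiscuous | sub$bin_b %in% promiscuous)
    out[[key]] <- sub[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# pairwise Euclidean distance matrix via the Gram-matrix identity
.pdist <- function(X) {
  G <- tcrossprod(X)
  sq <- diag(G)
  D2 <- outer(sq, sq, "+") - 2 * G
  D2[D2 < 0] <- 0
  sqrt(D2)
}

# flat-bottom restraint loss; targets: backbone pairs at distance 1,
# contact pairs <= 1.5, all pairs >= 0.5
.structure_loss <- function(D, bb, ct) {
  l_bb <- sum((D[bb] - 1)^2)
  l_ct <- sum(pmax(0, D[ct] - 1.5)^2)
  l_rep <- sum(pmax(0, 0.5 - D[lower.tri(D)])^2)
  l_bb + l_ct + l_rep
}

.structure_grad <- function(X, D, bb, ct) {
  n <- nrow(X)
  Dsafe <- D + diag(n)
  Dsafe[Dsafe < 1e-9] <- 1e-9
  K <- matrix(0, n, n)
  K[bb] <- K[bb] + 2 * (D[bb] - 1) / Dsafe[bb]
  over <- D[ct] > 1.5
  if (any(over)) {
    ci <- ct[over, , drop = FALSE]
    K[ci] <- K[ci] + 2 * (D[ci] - 1.5) / Dsafe[ci]
  }
  close <- which(D < 0.5 & D > 0 & upper.tri(D), arr.ind = TRUE)
  if (nrow(close)) {
    K[close] <- K[close] + 2 * (D[close] - 0.5) / Dsafe[close]
  }
  K <- K + t(K)
  (diag(rowSums(K)) - K) %*% X
}

#' Embed a single-cell chromosome structure by distance geometry
#'
#' Builds a graph with backbone edges (i, i+1) of length 1 and contact edges
#' of length 1, completes the distance matrix by shortest paths, initializes
#' coordinates by classical multidimensional scaling, and refines them by
#' gradient descent on a flat-bottom restraint loss (backbone distances to
#' 1, contacts at most 1.5, all pairs at least 0.5). The best of several
#' restarts (by final loss) is kept; coordinates are centered and scaled to
#' unit radius of gyration. If the contact graph is disconnected, the
#' largest component is embedded and the remaining bins are masked (NA).
#'
#' @param contacts filtered contact data.frame for one cell (columns `chrom`,
#'   `bin_a`, `bin_b`).
#' @param chrom chromosome to embed.
#' @param n_bins number of bins (particles) on the chromosome.
#' @param seeds integer vector of restart seeds (default `1:5`; the first
#'   restart uses the unperturbed MDS initialization).
#' @param max_iter refinement iterations per restart (default 150).
#' @param cell_id optional cell label.
#' @return object of class `cell_structure`: `coords` (n_bins x 3, NA rows
#'   masked), `energy` (final loss), `cell_id`, `chrom`, `masked_bins`.
#' @export
embed_structure <- function(contacts, chrom, n_bins, seeds = 1:5,
                            max_iter = 150, cell_id = NULL) {
  sub <- contacts[contacts$chrom == chrom, , drop = FALSE]
  # coverage floor only meaningful beyond toy chain sizes
  if (n_bins > 10 && nrow(sub) / n_bins < 0.5)
    stop("insufficient contacts: need >= 0.5 contacts per bin")
  edges_bb <- cbind(seq_len(n_bins - 1), seq_len(n_bins - 1) + 1)
  edges_ct <- unique(cbind(pmin(sub$bin_a, sub$bin_b),
                           pmax(sub$bin_a, sub$bin_b))) + 1L
  g <- igraph::graph_from_edgelist(rbind(edges_bb, edges_ct), directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < n_bins)
    g <- igraph::add_vertices(g, n_bins - igraph::vcount(g))
  comp <- igraph::components(g)
  main <- which(comp$membership == which.max(comp$csize))
  masked <- setdiff(seq_len(n_bins), main)
  D <- igraph::distances(g, v = main, to = main)
  mds <- stats::cmdscale(D, k = min(3L, length(main) - 1L))
  if (ncol(mds) < 3) mds <- cbind(mds, matrix(0, nrow(mds), 3 - ncol(mds)))

  idx <- stats::setNames(seq_along(main), main)
  bb_pairs <- edges_bb[edges_bb[, 1] %in% main & edges_bb[, 2] %in% main, , drop = FALSE]
  bb <- cbind(idx[as.character(bb_pairs[, 1])], idx[as.character(bb_pairs[, 2])])
  ct_pairs <- edges_ct[edges_ct[, 1] %in% main & edges_ct[, 2] %in% main, , drop = FALSE]
  ct <- cbind(idx[as.character(ct_pairs[, 1])], idx[as.character(ct_pairs[, 2])])

  best <- NULL
  for (s in seq_along(seeds)) {
    set.seed(seeds[s])
    X <- mds
    if (s > 1) X <- X + matrix(stats::rnorm(length(X), sd = 0.1), nrow(X))
    D <- .pdist(X)
    loss <- .structure_loss(D, bb, ct)
    step <- 0.02
    for (it in seq_len(max_iter)) {
      Gr <- .structure_grad(X, D, bb, ct)
      repeat {
        Xn <- X - step * Gr
        Dn <- .pdist(Xn)
        ln <- .structure_loss(Dn, bb, ct)
        if (ln <= loss || step < 1e-8) break
        step <- step / 2
      }
      if (ln > loss) break
      converged <- loss - ln < 1e-8 * max(1, loss)
      X <- Xn; D <- Dn; loss <- ln
      if (converged) break
      step <- step * 1.2
    }
    if (is.null(best) || loss < best$loss) best <- list(X = X, loss = loss)
  }
  X <- scale(best$X, center = TRUE, scale = FALSE)
  rg <- sqrt(mean(rowSums(X^2)))
  if (rg > 0) X <- X / rg
  coords <- matrix(NA_real_, n_bins, 3)
  coords[main, ] <- X
  structure(list(coords = coords, energy = best$loss, cell_id = cell_id,
                 chrom = chrom, masked_bins = masked),
            class = "cell_structure")
}

#' @export
print.cell_structure <- function(x, ...) {
  cat("cell_structure:", x$chrom, "-", nrow(x$coords), "bins (",
      length(x$masked_bins), "masked ), loss", format(x$energy, digits = 4), "\n")
  invisible(x)
}

#' r.m.s.d between two superposed structures
#'
#' Both structures are restricted to their common unmasked bins, centered,
#' and normalized to unit radius of gyration; the optimal rotation is found
#' by the Kabsch (SVD) procedure. With `allow_mirror`, the reflected
#' superposition is also evaluated and the smaller r.m.s.d returned (contact
#' data cannot determine chirality).
#'
#' @param a,b [embed_structure()] results (or any `cell_structure`).
#' @param allow_mirror evaluate the mirror image too (default TRUE).
#' @return r.m.s.d (numeric scalar).
#' @export
align_structures <- function(a, b, allow_mirror = TRUE) {
  ok <- stats::complete.cases(a$coords) & stats::complete.cases(b$coords)
  if (sum(ok) < 3) stop("need at least 3 common unmasked bins")
  norm_rg <- function(X) {
    X <- scale(X, center = TRUE, scale = FALSE)
    rg <- sqrt(mean(rowSums(X^2)))
    if (rg > 0) X / rg else X
  }
  A <- norm_rg(a$coords[ok, , drop = FALSE])
  B <- norm_rg(b$coords[ok, , drop = FALSE])
  fit <- function(B) {
    sv <- svd(crossprod(B, A))        # minimizes ||A - B R|| over rotations
    d <- sign(det(sv$u %*% t(sv$v)))
    R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
    sqrt(mean(rowSums((A - B %*% R)^2)))
  }
  r <- fit(B)
  if (allow_mirror) {
    Bm <- B
    Bm[, 1] <- -Bm[, 1]
    r <- min(r, fit(Bm))
  }
  r
}

#' Pairwise cell-cell r.m.s.d matrix
#'
#' @param cells list of `cell_structure` objects for one chromosome.
#' @param allow_mirror passed to [align_structures()] (default TRUE).
#' @return object of class `rmsd_matrix`: symmetric matrix with zero
#'   diagonal, dimnames = cell ids.
#' @export
rmsd_matrix <- function(cells, allow_mirror = TRUE) {
  n <- length(cells)
  if (n < 2) stop("need at least 2 cells")
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- align_structures(cells[[i]], cells[[j]],
                                           allow_mirror = allow_mirror)
  }
  ids <- vapply(cells, function(c) {
    if (is.null(c$cell_id)) NA_character_ else as.character(c$cell_id)
  }, character(1))
  if (!anyNA(ids)) dimnames(m) <- list(ids, ids)
  structure(m, class = c("rmsd_matrix", "matrix"))
}

#' Hierarchical clustering of cells on the r.m.s.d matrix
#'
#' Agglomerative clustering (average linkage by default) on the precomputed
#' r.m.s.d dissimilarity, cut into `k` flat clusters.
#'
#' @param m an [rmsd_matrix()].
#' @param k number of clusters.
#' @param linkage linkage method (default "average").
#' @return list with `labels` (integer cluster per cell), `order`
#'   (dendrogram leaf order), `hclust` (the tree).
#' @export
cluster_cells <- function(m, k, linkage = "average") {
  hc <- stats::hclust(stats::as.dist(unclass(m)), method = linkage)
  list(labels = stats::cutree(hc, k = k), order = hc$order, hclust = hc)
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions, about 0
#' for independent ones. Invariant to label permutation.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  exp_idx <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(0)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
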