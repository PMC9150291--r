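#' Iterative-correction (ICE) balancing
#'
#' Removes multiplicative per-bin biases by iteratively equalizing bin
#' marginals (Imakaev-style matrix balancing). Bins whose raw marginal falls
#' below `coverage_floor` times the median marginal are masked and excluded.
#' Iteration stops when the coefficient of variation of the unmasked
#' marginals drops below `tol` or after `max_iter` rounds.
#'
#' The returned `bias` follows the cooler weight convention:
#' `balanced_ij = raw_ij * bias_i * bias_j`, so `1 / bias` estimates the
#' multiplicative bin bias present in the raw counts (up to scale).
#'
#' @param cm a `raw` [contact_matrix()].
#' @param max_iter maximum iterations (default 200).
#' @param tol marginal coefficient-of-variation target (default 1e-5).
#' @param coverage_floor fraction of the median marginal below which a bin is
#'   masked (default 0.1).
#' @return a `balanced` [contact_matrix()] with `bias` and `mask` populated.
#' @export
ice_balance <- function(cm, max_iter = 200, tol = 1e-5, coverage_floor = 0.1) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$state != "raw") stop("ice_balance expects a raw matrix")
  n <- cm$genome$n_bins
  marg0 <- matrix_marginals(cm)
  mask <- cm$mask | marg0 == 0 | marg0 < coverage_floor * stats::median(marg0)
  if (all(mask)) stop("matrix too sparse: all bins masked")

  e <- cm$entries
  keep <- !(mask[e$i + 1L] | mask[e$j + 1L])
  x <- e$x[keep]
  i1 <- e$i[keep] + 1L
  j1 <- e$j[keep] + 1L
  diag_pix <- i1 == j1
  bias <- rep(1, n)
  unm <- which(!mask)

  marginal_of <- function(x) {
    m <- numeric(n)
    a <- rowsum(x, i1)
    m[as.integer(rownames(a))] <- m[as.integer(rownames(a))] + a[, 1]
    off <- !diag_pix
    if (any(off)) {
      b <- rowsum(x[off], j1[off])
      m[as.integer(rownames(b))] <- m[as.integer(rownames(b))] + b[, 1]
    }
    m
  }

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m <- marginal_of(x)[unm]
    mu <- mean(m)
    cv <- stats::sd(m) / mu
    if (is.na(cv)) cv <- 0
    if (cv < tol) { converged <- TRUE; break }
    s <- rep(1, n)
    s[unm] <- m / mu
    x <- x / (s[i1] * s[j1])
    bias <- bias / s
  }
  bias[mask] <- NA_real_
  out <- contact_matrix(cm$genome,
                        data.frame(i = i1 - 1L, j = j1 - 1L, x = x),
                        state = "raw", bias = bias, mask = mask)
  out$state <- "balanced"
  attr(out, "converged") <- converged
  out
}
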