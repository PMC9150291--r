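# Shared fixtures and independent oracles for the test suite.
# The default panel (seed 1) is expensive to simulate, so it is built once
# per test run and memoized here.

.cache <- new.env(parent = emptyenv())

default_panel <- function() {
  if (is.null(.cache$panel)) {
    .cache$panel <- simulate_panel(panel_spec(seed = 1))
  }
  .cache$panel
}

# balanced + O/E matrices for one sample of the default panel, memoized
panel_oe <- function(s) {
  key <- paste0("oe", s)
  if (is.null(.cache[[key]])) {
    p <- default_panel()
    bal <- ice_balance(p$sims[[s]]$cm)
    .cache[[paste0("bal", s)]] <- bal
    .cache[[key]] <- observed_over_expected(bal)
  }
  .cache[[key]]
}

panel_balanced <- function(s) {
  panel_oe(s)  # populates the cache
  .cache[[paste0("bal", s)]]
}

# tiny genome helper
toy_genome <- function(n_bins = 10, resolution = 1000, n_chrom = 1) {
  sizes <- stats::setNames(rep(n_bins * resolution, n_chrom),
                           paste0("chr", seq_len(n_chrom)))
  binned_genome(sizes, resolution)
}

# contact matrix from a dense symmetric matrix (single chromosome)
cm_from_dense <- function(m, resolution = 1000, state = "raw") {
  n <- nrow(m)
  g <- toy_genome(n, resolution)
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  contact_matrix(g, data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                               x = m[idx]),
                 state = state)
}

# two-pass Pearson correlation, the brute-force oracle
pearson_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# nested-loop insulation oracle on a dense balanced matrix
insulation_oracle <- function(m, windows) {
  n <- nrow(m)
  zs <- sapply(windows, function(w) {
    val <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (i - w < 1 || i + w > n) next
      acc <- c()
      for (r in (i - w):(i - 1)) for (cc in (i + 1):(i + w))
        acc <- c(acc, m[r, cc])
      mu <- mean(acc, na.rm = TRUE)
      if (is.finite(mu) && mu > 0) val[i] <- log2(mu)
    }
    (val - mean(val, na.rm = TRUE)) / stats::sd(val, na.rm = TRUE)
  })
  rowMeans(zs)
}

# independent rule-table oracle for TAD change classes (offsets in bins,
# tolerance tau bins), written as explicit case analysis
tad_class_oracle <- function(ds, de, tau = 1) {
  s_in <- ds > tau        # start moved inward beyond tolerance
  s_out <- ds < -tau      # start moved outward
  e_in <- de < -tau
  e_out <- de > tau
  if (!s_in && !s_out && !e_in && !e_out) return("Stable")
  if ((s_out || e_out) && !s_in && !e_in) return("Expand")
  if ((s_in || e_in) && !s_out && !e_out) return("Shrink")
  "Shift"
}

# exhaustive Mann-Whitney U oracle: number of (a, b) pairs with a > b,
# counting ties as 1/2
u_statistic_oracle <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# exact permutation p for a Pearson correlation at n = 5 (all 120 orders)
perm_p_oracle <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  r0 <- abs(stats::cor(x, y))
  rs <- vapply(perms(seq_along(y)), function(p) abs(stats::cor(x, y[p])),
               numeric(1))
  mean(rs >= r0 - 1e-12)
}
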