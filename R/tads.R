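#' Multi-window insulation score
#'
#' For each window size `w` and bin `i`, the raw insulation value is the mean
#' of the contact pixels in the square upstream x downstream window
#' `(i-w .. i-1) x (i+1 .. i+w)`. Per window, log2 values are z-scored along
#' the chromosome; the score is the mean z across windows. Bins closer than
#' the largest window to a chromosome edge, masked bins, and bins whose
#' window mean is zero are NA.
#'
#' @param cm a `balanced` [contact_matrix()].
#' @param chrom chromosome name.
#' @param windows window sizes in bins (default `c(1, 3, 5)`, i.e. 50-250 kb
#'   at 50 kb resolution; the set must sit below the expected domain size,
#'   and the single-pixel window sharpens boundary localization).
#' @return object of class `insulation_profile`: list with `chrom`, `score`
#'   (per-bin), `windows`.
#' @export
insulation_profile <- function(cm, chrom, windows = c(1L, 3L, 5L)) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (cm$state != "balanced") stop("insulation_profile expects a balanced matrix")
  m <- chrom_dense(cm, chrom)
  n <- nrow(m)
  if (any(windows > n / 2)) stop("window larger than half the chromosome")
  zmat <- matrix(NA_real_, n, length(windows))
  for (k in seq_along(windows)) {
    w <- windows[k]
    val <- rep(NA_real_, n)
    for (i in (w + 1):(n - w)) {
      block <- m[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
      mu <- mean(block, na.rm = TRUE)
      if (is.finite(mu) && mu > 0) val[i] <- log2(mu)
    }
    mu_c <- mean(val, na.rm = TRUE)
    sd_c <- stats::sd(val, na.rm = TRUE)
    zmat[, k] <- if (!is.na(sd_c) && sd_c > 0) (val - mu_c) / sd_c else val * 0
  }
  score <- rowMeans(zmat)
  score[cm$mask[chrom_bins(cm$genome, chrom) + 1L]] <- NA_real_
  structure(list(chrom = chrom, score = score, windows = windows),
            class = "insulation_profile")
}

# topographic prominence of a local minimum of `score` at position `i`
.min_prominence <- function(score, i) {
  lo <- score[i]
  run_max <- function(idx) {
    m <- -Inf
    for (p in idx) {
      v <- score[p]
      if (is.na(v)) break
      if (v < lo) break
      if (v > m) m <- v
    }
    m
  }
  left <- run_max(rev(seq_len(i - 1)))
  right <- run_max(seq(i + 1, length(score)))
  min(left, right) - lo
}

#' Call TADs from insulation minima
#'
#' Boundaries are local minima of the insulation score with topographic
#' prominence at least `prominence` and a negative score. TADs are the
#' intervals between consecutive boundaries on a chromosome; chromosome ends
#' act as implicit boundaries. TADs shorter than 3 bins are discarded.
#'
#' @param profile an [insulation_profile()].
#' @param genome a [binned_genome()].
#' @param prominence minimum prominence (default 0.2).
#' @param sample_id optional sample label.
#' @return object of class `tad_set`: data.frame `intervals` with columns
#'   `chrom`, `start`, `end` (bp, 0-based half-open), plus `boundaries`
#'   (chromosome-local bin indices).
#' @export
call_tads <- function(profile, genome, prominence = 0.2, sample_id = NULL) {
  stopifnot(inherits(profile, "insulation_profile"))
  s <- profile$score
  n <- length(s)
  bnd <- integer(0)
  for (i in 2:(n - 1)) {
    v <- s[i]
    if (is.na(v) || v >= 0) next
    ln <- s[i - 1]; rn <- s[i + 1]
    if (is.na(ln) || is.na(rn)) next
    if (v <= ln && v <= rn && (v < ln || v < rn)) {
      if (.min_prominence(s, i) >= prominence) bnd <- c(bnd, i)
    }
  }
  # A boundary between bins b-1 and b gives a two-bin minimum plateau (both
  # flanking bins see pure cross-domain windows); place the edge on the
  # plateau's right element so the called start bin is the domain's first bin.
  edge_bin <- vapply(bnd, function(i) {
    right_lower <- !is.na(s[i + 1]) && !is.na(s[i - 1]) && s[i + 1] < s[i - 1]
    (i - 1L) + as.integer(right_lower)
  }, integer(1))
  res <- genome$resolution
  nb <- genome$n_bins_chrom[[profile$chrom]]
  edges <- unique(c(0L, edge_bin, nb))  # 0-based bin edges
  edges <- sort(edges)
  iv <- data.frame(
    chrom = profile$chrom,
    start = edges[-length(edges)] * res,
    end = pmin(edges[-1] * res, genome$chrom_sizes[[profile$chrom]])
  )
  iv <- iv[(edges[-1] - edges[-length(edges)]) >= 3, , drop = FALSE]
  rownames(iv) <- NULL
  tad_set(iv, sample_id = sample_id, boundaries = edge_bin)
}

#' Construct a TAD set
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (bp, 0-based
#'   half-open), sorted and non-overlapping within each chromosome.
#' @param sample_id optional sample label.
#' @param boundaries optional boundary bin indices.
#' @return object of class `tad_set`.
#' @export
tad_set <- function(intervals, sample_id = NULL, boundaries = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  if (any(intervals$end <= intervals$start)) stop("TAD end must exceed start")
  for (ch in unique(intervals$chrom)) {
    sub <- intervals[intervals$chrom == ch, ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("overlapping TAD intervals on ", ch)
  }
  structure(list(intervals = intervals, sample_id = sample_id,
                 boundaries = boundaries),
            class = "tad_set")
}

#' @export
print.tad_set <- function(x, ...) {
  cat("tad_set:", nrow(x$intervals), "TADs",
      if (!is.null(x$sample_id)) paste0("(", x$sample_id, ")"), "\n")
  invisible(x)
}

# classify one reference/query interval pair given tolerance in bp
.classify_pair <- function(s, e, qs, qe, tau) {
  ds <- qs - s; de <- qe - e
  if (abs(ds) <= tau && abs(de) <= tau) return("Stable")
  if (ds <= tau && de >= -tau && (ds < -tau || de > tau)) return("Expand")
  if (ds >= -tau && de <= tau && (ds > tau || de < -tau)) return("Shrink")
  "Shift"
}

#' Classify TAD boundary changes between two samples
#'
#' Each reference TAD is matched to the query TAD with the largest base-pair
#' overlap (ties broken toward the query TAD whose midpoint is nearest the
#' reference midpoint); no overlap gives category `Absent`. With tolerance
#' `tau = tol_bins * resolution`, a matched pair is `Stable` if both
#' boundaries moved at most `tau`; `Expand` if the query covers the reference
#' with at least one boundary moved outward beyond `tau`; `Shrink` if the
#' query lies inside the reference with at least one boundary moved inward
#' beyond `tau`; and `Shift` otherwise (one boundary outward, the other
#' inward). Category proportions are reported over non-Absent records.
#'
#' @param ref,query [tad_set()] objects on the same genome.
#' @param resolution bin width in bp.
#' @param tol_bins boundary tolerance in bins (default 1).
#' @return list with `records` (data.frame: reference interval, matched query
#'   interval, category, boundary offsets in bins) and `proportions` (over
#'   non-Absent categories).
#' @export
classify_tad_change <- function(ref, query, resolution, tol_bins = 1) {
  stopifnot(inherits(ref, "tad_set"), inherits(query, "tad_set"))
  tau <- tol_bins * resolution
  R <- ref$intervals
  Q <- query$intervals
  rec <- lapply(seq_len(nrow(R)), function(k) {
    s <- R$start[k]; e <- R$end[k]
    cand <- which(Q$chrom == R$chrom[k] & Q$start < e & Q$end > s)
    if (!length(cand)) {
      return(data.frame(ref_chrom = R$chrom[k], ref_start = s, ref_end = e,
                        q_start = NA_real_, q_end = NA_real_,
                        category = "Absent", off_start = NA_real_, off_end = NA_real_))
    }
    ov <- pmin(Q$end[cand], e) - pmax(Q$start[cand], s)
    best <- cand[ov == max(ov)]
    if (length(best) > 1) {
      midr <- (s + e) / 2
      dmid <- abs((Q$start[best] + Q$end[best]) / 2 - midr)
      best <- best[which.min(dmid)]
    } else best <- best[1]
    qs <- Q$start[best]; qe <- Q$end[best]
    data.frame(ref_chrom = R$chrom[k], ref_start = s, ref_end = e,
               q_start = qs, q_end = qe,
               category = .classify_pair(s, e, qs, qe, tau),
               off_start = (qs - s) / resolution, off_end = (qe - e) / resolution)
  })
  records <- do.call(rbind, rec)
  matched <- records$category != "Absent"
  prop <- if (any(matched)) {
    tab <- table(factor(records$category[matched],
                        levels = c("Stable", "Expand", "Shrink", "Shift")))
    as.numeric(tab) / sum(tab)
  } else rep(NA_real_, 4)
  names(prop) <- c("Stable", "Expand", "Shrink", "Shift")
  list(records = records, proportions = prop)
}

#' Flag epithelial and mesenchymal TADs
#'
#' A TAD containing the TSS of at least one epithelial signature gene is an
#' eTAD; one containing a mesenchymal gene TSS is an mTAD (a TAD can be
#' both). Containment uses the half-open interval rule: a TSS exactly at the
#' TAD end coordinate is outside.
#'
#' @param tads a [tad_set()].
#' @param genes data.frame with `chrom`, `start`, `end`, `name`, `strand`,
#'   `class` (one of "E", "M", or anything else for non-signature genes).
#' @return list with `flags` (data.frame per TAD: is_eTAD, is_mTAD, gene ids)
#'   and `outside` (signature genes whose TSS is in no TAD).
#' @export
assign_emt_tads <- function(tads, genes) {
  stopifnot(inherits(tads, "tad_set"))
  tss <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  iv <- tads$intervals
  g_gr <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(tss + 1, tss + 1))
  t_gr <- GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1, iv$end))
  hits <- GenomicRanges::findOverlaps(g_gr, t_gr)
  gi <- S4Vectors::queryHits(hits); ti <- S4Vectors::subjectHits(hits)
  is_e <- logical(nrow(iv)); is_m <- logical(nrow(iv))
  egenes <- vector("list", nrow(iv)); mgenes <- vector("list", nrow(iv))
  for (h in seq_along(gi)) {
    cls <- genes$class[gi[h]]
    if (identical(cls, "E")) {
      is_e[ti[h]] <- TRUE
      egenes[[ti[h]]] <- c(egenes[[ti[h]]], genes$name[gi[h]])
    } else if (identical(cls, "M")) {
      is_m[ti[h]] <- TRUE
      mgenes[[ti[h]]] <- c(mgenes[[ti[h]]], genes$name[gi[h]])
    }
  }
  sig <- genes$class %in% c("E", "M")
  covered <- seq_len(nrow(genes)) %in% gi
  list(
    flags = data.frame(iv, is_eTAD = is_e, is_mTAD = is_m,
                       e_genes = I(egenes), m_genes = I(mgenes)),
    outside = genes$name[sig & !covered]
  )
}
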