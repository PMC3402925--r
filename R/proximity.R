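# Gene-to-breakpoint proximity
# ----------------------------
# Distances are interval-to-interval gaps in nucleotides: 0 when gene and BPR
# overlap (a breakpoint falling inside a gene disrupts it -- distance 0), else
# the number of nucleotides strictly between the closer pair of facing
# boundaries.  With 0-based half-open intervals [s, e) and [b, en) that is
#   gap = max(0, b - e, s - en).
# A point mode (gene reduced to its midpoint) is also provided, since the
# null model treats genes as points.

gap_interval <- function(s, e, b, en) {
  pmax(0, b - e, s - en)
}

gap_point <- function(mid, b, en) {
  pmax(0, b - mid, mid - en)
}

#' Distance from one gene to its nearest breakpoint region
#'
#' @param gene A one-row `data.frame` (or list) with `start`, `end` (and
#'   optionally `name`, `chrom`).
#' @param bprs BPR `data.frame`, all on the gene's chromosome, sorted by
#'   `begin`.
#' @param point_mode If `TRUE`, measure from the gene midpoint instead of the
#'   gene interval.
#' @return A list with `x` (distance in nt, 0 on overlap) and `nearest` (the
#'   one-row BPR `data.frame`).  Ties are broken toward the lower-coordinate
#'   BPR.
#' @export
nearest_bpr_distance <- function(gene, bprs, point_mode = FALSE) {
  if (is.null(bprs) || nrow(bprs) == 0L) {
    stop("no breakpoint on chromosome", call. = FALSE)
  }
  if (is.unsorted(bprs$begin)) {
    bprs <- bprs[order(bprs$begin, bprs$end), , drop = FALSE]
  }
  gaps <- if (point_mode) {
    gap_point((gene$start + gene$end) / 2, bprs$begin, bprs$end)
  } else {
    gap_interval(gene$start, gene$end, bprs$begin, bprs$end)
  }
  i <- which.min(gaps)  # first minimum = lowest-coordinate BPR on ties
  list(x = gaps[i], nearest = bprs[i, , drop = FALSE])
}

#' Nearest-BPR distance for every gene
#'
#' Computes, for each gene whose chromosome carries at least one BPR, the
#' distance in nucleotides to the closest BPR and its log-distance
#' `z = ln(max(x, 1))` (the 1-nt floor keeps `z >= 0` and corresponds to the
#' null model's convention that raw distance is uniform on `[1, u]`).  Genes
#' on BPR-free chromosomes are excluded from all analyses and counted in the
#' `"excluded"` attribute.
#'
#' @param genes Gene `data.frame` from [read_gene_table()].
#' @param de_names Character vector of DE gene names (normalized symbols);
#'   sets the `is_de` flag.
#' @param bprs BPR `data.frame` (any chromosome mix).
#' @param point_mode Measure from gene midpoints instead of gene intervals.
#' @return A `data.frame` with one row per analyzable gene: `name`, `chrom`,
#'   `start`, `end`, `is_de`, `nearest_begin`, `nearest_end`,
#'   `nearest_branch`, `x`, `z`.  Attribute `"excluded"` is a named integer
#'   vector of per-chromosome exclusion counts (possibly empty).
#' @export
compute_all_distances <- function(genes, de_names, bprs, point_mode = FALSE) {
  de_names <- unique(normalize_gene_name(de_names))
  bpr_chroms <- unique(bprs$chrom)
  on_bpr_chrom <- genes$chrom %in% bpr_chroms
  excluded <- table(genes$chrom[!on_bpr_chrom])
  g <- genes[on_bpr_chrom, , drop = FALSE]
  out <- vector("list", length(bpr_chroms))
  for (k in seq_along(bpr_chroms)) {
    ch <- bpr_chroms[k]
    gi <- g[g$chrom == ch, , drop = FALSE]
    if (nrow(gi) == 0L) next
    bi <- bprs[bprs$chrom == ch, , drop = FALSE]
    bi <- bi[order(bi$begin, bi$end), , drop = FALSE]
    # m x n gap matrix; m (BPRs per chromosome) is small
    if (point_mode) {
      mid <- (gi$start + gi$end) / 2
      gm <- pmax(outer(bi$begin, mid, "-"), outer(-bi$end, mid, "+"), 0)
    } else {
      gm <- pmax(outer(bi$begin, gi$end, "-"), outer(-bi$end, gi$start, "+"), 0)
    }
    nearest <- apply(gm, 2L, which.min)
    x <- gm[cbind(nearest, seq_len(ncol(gm)))]
    out[[k]] <- data.frame(
      name = gi$name, chrom = gi$chrom, start = gi$start, end = gi$end,
      is_de = gi$name %in% de_names,
      nearest_begin = bi$begin[nearest], nearest_end = bi$end[nearest],
      nearest_branch = bi$branch[nearest],
      x = x, z = log(pmax(x, 1)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(name = character(), chrom = character(),
                      start = numeric(), end = numeric(), is_de = logical(),
                      nearest_begin = numeric(), nearest_end = numeric(),
                      nearest_branch = character(), x = numeric(),
                      z = numeric(), stringsAsFactors = FALSE)
  }
  res <- res[order_by_chrom(res$chrom, res$start, res$name), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Flanking breakpoint boundaries around each gene
#'
#' For each gene midpoint, finds the boundary position `a1` of the nearest
#' BPR at or left of the midpoint and `a2` of the nearest BPR at or right of
#' it, expressed as base positions (the last base of the left BPR, the first
#' base of the right BPR, in 1-based numbering).  Chromosome ends act as
#' pseudo-boundaries: `a1 = 0` when no BPR lies to the left, `a2` = the
#' chromosome length when none lies to the right, so every gene on a
#' BPR-bearing chromosome has a defined half-spacing `u = (a2 - a1)/2` and
#' `U = ln u`.  A midpoint strictly inside a BPR gives a degenerate interval
#' (`u = 0`, flagged).
#'
#' Assumes the BPRs within a chromosome do not overlap (true of published BPR
#' sets and of the synthetic generator).
#'
#' @param genes Gene `data.frame` (rows on any chromosome present in `bprs`).
#' @param bprs BPR `data.frame`.
#' @param chrom_lengths Named numeric vector of chromosome lengths in nt;
#'   must cover every chromosome in `genes` and be at least the maximum
#'   coordinate observed.
#' @return A `data.frame` aligned with the BPR-bearing rows of `genes`:
#'   `name`, `chrom`, `a1`, `a2`, `u`, `U` (`NA` when `u < 1`), `degenerate`,
#'   `has_left`, `has_right` (whether the boundary is a true BPR rather than
#'   a chromosome end).
#' @export
flanking_intervals <- function(genes, bprs, chrom_lengths) {
  bpr_chroms <- unique(bprs$chrom)
  g <- genes[genes$chrom %in% bpr_chroms, , drop = FALSE]
  out <- vector("list", length(bpr_chroms))
  ord <- vector("list", length(bpr_chroms))
  for (k in seq_along(bpr_chroms)) {
    ch <- bpr_chroms[k]
    idx <- which(g$chrom == ch)
    gi <- g[idx, , drop = FALSE]
    if (nrow(gi) == 0L) next
    ord[[k]] <- idx
    if (!ch %in% names(chrom_lengths)) {
      stop("no chromosome length supplied for ", ch, call. = FALSE)
    }
    L <- chrom_lengths[[ch]]
    bi <- bprs[bprs$chrom == ch, , drop = FALSE]
    bi <- bi[order(bi$begin, bi$end), , drop = FALSE]
    mid <- (gi$start + gi$end) / 2
    ends <- sort(bi$end)
    # left: rightmost BPR end <= midpoint
    ie <- findInterval(mid, ends)
    a1 <- ifelse(ie >= 1L, ends[pmax(ie, 1L)], 0)
    has_left <- ie >= 1L
    # right: leftmost BPR begin >= midpoint
    ib <- findInterval(mid, bi$begin)  # begins[ib] <= mid
    at_begin <- ib >= 1L & bi$begin[pmax(ib, 1L)] == mid
    iright <- ifelse(at_begin, ib, ib + 1L)
    has_right <- iright <= nrow(bi)
    a2 <- ifelse(has_right, bi$begin[pmin(iright, nrow(bi))] + 1, L)
    # midpoint strictly inside a BPR -> degenerate
    degenerate <- ib >= 1L & !at_begin & bi$end[pmax(ib, 1L)] > mid
    a1 <- ifelse(degenerate, mid, a1)
    a2 <- ifelse(degenerate, mid, a2)
    u <- (a2 - a1) / 2
    out[[k]] <- data.frame(
      name = gi$name, chrom = gi$chrom, a1 = a1, a2 = a2, u = u,
      U = ifelse(u >= 1, log(pmax(u, 1)), NA_real_),
      degenerate = degenerate, has_left = has_left, has_right = has_right,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(name = character(), chrom = character(), a1 = numeric(),
                      a2 = numeric(), u = numeric(), U = numeric(),
                      degenerate = logical(), has_left = logical(),
                      has_right = logical(), stringsAsFactors = FALSE)
  } else {
    # restore the order of the retained input rows
    res <- res[order(unlist(ord)), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Flanking interval for a single gene
#'
#' Single-gene convenience wrapper around [flanking_intervals()].
#'
#' @inheritParams nearest_bpr_distance
#' @param chrom_length Chromosome length in nt.
#' @return A one-row `data.frame` as in [flanking_intervals()].
#' @export
flanking_interval <- function(gene, bprs, chrom_length) {
  g <- as.data.frame(gene, stringsAsFactors = FALSE)
  if (is.null(g$name)) g$name <- "gene"
  if (is.null(g$chrom)) g$chrom <- bprs$chrom[1L]
  cl <- stats::setNames(chrom_length, g$chrom[1L])
  flanking_intervals(g, bprs[bprs$chrom == g$chrom[1L], , drop = FALSE], cl)
}
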