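# Shared fixtures and independent oracles for the test suite.

bpr_excerpt_path <- function() {
  system.file("extdata", "bpr_excerpt.tsv", package = "breakprox")
}

# exhaustive-scan oracle for the nearest-BPR distance: O(n * m) double loop,
# intentionally naive and independent of the package's vectorized path
oracle_gap <- function(s, e, b, en) {
  if (b < e && s < en) return(0)  # overlap (0-based half-open)
  if (b >= e) b - e else s - en
}

oracle_nearest <- function(gene, bprs) {
  best_x <- Inf
  best_i <- NA_integer_
  ord <- order(bprs$begin, bprs$end)
  for (i in ord) {
    g <- oracle_gap(gene$start, gene$end, bprs$begin[i], bprs$end[i])
    if (g < best_x) {  # strict: first (lowest-coordinate) BPR wins ties
      best_x <- g
      best_i <- i
    }
  }
  list(x = best_x, i = best_i)
}

# brute-force path labels between two tips of an ape tree: BFS on the edge
# matrix, then label each path edge by its child node
oracle_path_labels <- function(tree, tip_a, tip_b) {
  n_tip <- length(tree$tip.label)
  ia <- match(tip_a, tree$tip.label)
  ib <- match(tip_b, tree$tip.label)
  edges <- tree$edge
  adj <- list()
  for (r in seq_len(nrow(edges))) {
    p <- as.character(edges[r, 1]); c <- as.character(edges[r, 2])
    adj[[p]] <- c(adj[[p]], edges[r, 2])
    adj[[c]] <- c(adj[[c]], edges[r, 1])
  }
  # BFS
  prev <- list()
  queue <- ia
  seen <- as.character(ia)
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur == ib) break
    for (nb in adj[[as.character(cur)]]) {
      if (!as.character(nb) %in% seen) {
        seen <- c(seen, as.character(nb))
        prev[[as.character(nb)]] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  path <- ib
  while (path[1] != ia) {
    path <- c(prev[[as.character(path[1])]], path)
  }
  labs <- character()
  node_lab <- function(nd) {
    if (nd <= n_tip) tree$tip.label[nd] else tree$node.label[nd - n_tip]
  }
  for (k in seq_len(length(path) - 1)) {
    u <- path[k]; v <- path[k + 1]
    is_child <- any(edges[, 1] == u & edges[, 2] == v)
    labs <- c(labs, node_lab(if (is_child) v else u))
  }
  unique(labs[!is.na(labs) & nzchar(labs)])
}

make_genes <- function(name, chrom, start, end, strand = "+") {
  data.frame(name = name, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

make_bprs <- function(chrom, begin, end, branch = "lineage") {
  data.frame(chrom = chrom, begin = begin, end = end, branch = branch,
             stringsAsFactors = FALSE)
}

random_instance <- function(n_genes, n_bprs, L = 1e6) {
  gs <- floor(runif(n_genes, 0, L - 1000))
  bw <- pmax(1, floor(rexp(n_bprs, 1 / 500)))
  bb <- floor(runif(n_bprs, 0, L - max(bw)))
  list(
    genes = make_genes(sprintf("G%04d", seq_len(n_genes)), "chrT", gs,
                       gs + pmax(1, floor(rexp(n_genes, 1 / 300)))),
    bprs = make_bprs("chrT", bb, bb + bw)
  )
}
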