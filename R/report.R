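# Pipeline driver and reports
# ---------------------------
# Ties the stages together: read -> match -> branch-filter -> distances ->
# tests -> figures -> tables, writing every intermediate as TSV so a run can
# be audited, and returning a RunSummary whose counts must reconcile
# (matched + dropped = elements read).

#' Bin log-distances into unit-width log bins
#'
#' Histogram bins for `z = ln(distance)` with edges exactly at
#' `{0, 1, 2, ..., ceiling(max z)}`; a value on an interior edge falls in the
#' bin it opens, and the global maximum falls in the last bin.  Counts are
#' density-normalized within each group (bins have unit width, so density =
#' proportion), making the DE group comparable with the far larger
#' complement.
#'
#' @param records `data.frame` from [compute_all_distances()].
#' @param by_chrom Also split by chromosome.
#' @return A `data.frame` with `group` (`"DE"` / `"background"`), optional
#'   `chrom`, `bin_lo`, `bin_hi`, `count`, `density`.
#' @export
bin_log_distances <- function(records, by_chrom = FALSE) {
  if (nrow(records) == 0L) {
    stop("records must be non-empty", call. = FALSE)
  }
  n_bins <- max(ceiling(max(records$z)), 1)
  bin_of <- function(z) pmin(floor(z), n_bins - 1)
  split_vars <- if (by_chrom) {
    list(group = ifelse(records$is_de, "DE", "background"),
         chrom = records$chrom)
  } else {
    list(group = ifelse(records$is_de, "DE", "background"))
  }
  grid <- expand.grid(c(lapply(split_vars, unique),
                        list(bin_lo = 0:(n_bins - 1))),
                      stringsAsFactors = FALSE)
  key_rec <- do.call(paste, c(split_vars, list(bin_of(records$z))))
  key_grid <- do.call(paste, grid)
  counts <- table(factor(key_rec, levels = key_grid))
  grid$count <- as.integer(counts[key_grid])
  grid$bin_hi <- grid$bin_lo + 1
  # per-group (x chromosome) totals for density normalization
  gkey <- do.call(paste, grid[, setdiff(names(grid), c("bin_lo", "bin_hi",
                                                       "count")), drop = FALSE])
  totals <- tapply(grid$count, gkey, sum)
  grid$density <- ifelse(totals[gkey] > 0, grid$count / totals[gkey], 0)
  cols <- c(names(split_vars), "bin_lo", "bin_hi", "count", "density")
  out <- grid[do.call(order, grid[, c(names(split_vars), "bin_lo"),
                                  drop = FALSE]), cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Paired log-distance histograms for DE genes vs the gene complement
#'
#' Density-normalized histograms of `z = ln(distance to nearest BPR)` with
#' unit-width natural-log bins, DE genes against the rest of the gene
#' complement, genome-wide or faceted per chromosome.  An optional mixture
#' null (from [mixture_from_genes()]) is overlaid as a curve.  Panels where a
#' group is empty are annotated in the caption rather than dropped.
#'
#' @param records `data.frame` from [compute_all_distances()].
#' @param per_chromosome Facet by chromosome.
#' @param outpath Optional path (`.png`, `.svg`, `.pdf`); the figure is saved
#'   there with [ggplot2::ggsave()].
#' @param mixture Optional `mixture_null` overlay.
#' @return A list with `plot` (ggplot object) and `bins` (the
#'   [bin_log_distances()] table), invisibly.
#' @export
plot_log_histograms <- function(records, per_chromosome = FALSE,
                                outpath = NULL, mixture = NULL) {
  bins <- bin_log_distances(records, by_chrom = per_chromosome)
  bins$mid <- (bins$bin_lo + bins$bin_hi) / 2
  caption <- NULL
  if (per_chromosome) {
    present <- tapply(bins$count, paste(bins$group, "on", bins$chrom), sum)
    empty_panels <- names(present)[present == 0]
    if (length(empty_panels) > 0L) {
      caption <- paste("no", paste(empty_panels, collapse = "; "), "genes")
    }
  }
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = .data$mid, y = .data$density,
                                          fill = .data$group)) +
    ggplot2::geom_col(position = "identity", alpha = 0.55, width = 1,
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(x = "ln(distance to nearest breakpoint region) [nt]",
                  y = "density", fill = NULL, caption = caption) +
    ggplot2::theme_minimal()
  if (per_chromosome) {
    p <- p + ggplot2::facet_wrap(~chrom)
  }
  if (!is.null(mixture)) {
    zg <- seq(0, max(bins$bin_hi), length.out = 256)
    curve <- data.frame(z = zg, density = mixture_density(mixture, zg))
    p <- p + ggplot2::geom_line(
      data = curve, ggplot2::aes(x = .data$z, y = .data$density),
      inherit.aes = FALSE, colour = "black"
    )
  }
  if (!is.null(outpath)) {
    ggplot2::ggsave(outpath, p, width = 8, height = 5, dpi = 150)
  }
  invisible(list(plot = p, bins = bins))
}

#' Table of the DE genes closest to a breakpoint
#'
#' DE records sorted by ascending distance (ties broken by gene name, for
#' reproducibility), truncated either at the `k` closest or at distances
#' `x <= max_x`.
#'
#' @param records `data.frame` from [compute_all_distances()].
#' @param k Keep only the `k` closest DE genes.
#' @param max_x Keep only DE genes with `x <= max_x` nt.
#' @return A `data.frame` with columns `gene`, `chrom`, `x`, `z`,
#'   `nearest_begin`, `nearest_end`, `nearest_branch` (empty, with header,
#'   when there are no DE records).
#' @export
closest_de_table <- function(records, k = NULL, max_x = NULL) {
  de <- records[records$is_de, , drop = FALSE]
  de <- de[order(de$x, de$name), , drop = FALSE]
  if (!is.null(max_x)) {
    de <- de[de$x <= max_x, , drop = FALSE]
  }
  if (!is.null(k)) {
    de <- utils::head(de, k)
  }
  out <- data.frame(gene = de$name, chrom = de$chrom, x = de$x, z = de$z,
                    nearest_begin = de$nearest_begin,
                    nearest_end = de$nearest_end,
                    nearest_branch = de$nearest_branch,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full breakpoint-proximity pipeline
#'
#' Executes read -> name matching -> branch filtering -> distances ->
#' statistical tests -> reports, writing every intermediate table as TSV
#' under `outdir`.  Two runs with identical inputs and seed produce
#' byte-identical tables.
#'
#' @param bpr_file BPR table path.
#' @param gene_file Gene annotation path.
#' @param de_file DE element list path.
#' @param alias_file Optional alias-map path.
#' @param branches Character vector of branch labels to retain; alternatively
#'   give `pair` and `tree`.
#' @param pair Length-2 character vector of species names; the retained
#'   branches are those on the path between them in `tree`.
#' @param tree Newick file/string/`phylo` with edge labels (see
#'   [branches_on_path()]).
#' @param chrom_lengths_file Optional chromosome-lengths TSV; when absent,
#'   lengths are taken as the maximum coordinate observed per chromosome.
#' @param bpr_dialect,gene_dialect Input dialects (see [read_bpr_table()],
#'   [read_gene_table()]).
#' @param point_mode Use gene-midpoint distances.
#' @param n_sim Simulations for the Monte-Carlo test.
#' @param seed Integer seed for the Monte-Carlo test.
#' @param outdir Output directory (created if needed).
#' @param make_plots Write histogram figures (PNG).
#' @param closest_max_x Distance cutoff for the closest-DE-gene table, nt.
#' @return An object of class `run_summary`.
#' @export
run_pipeline <- function(bpr_file, gene_file, de_file, alias_file = NULL,
                         branches = NULL, pair = NULL, tree = NULL,
                         chrom_lengths_file = NULL,
                         bpr_dialect = "bpr_tsv", gene_dialect = "bed",
                         point_mode = FALSE, n_sim = 1000, seed = 1L,
                         outdir = tempfile("breakprox_run"),
                         make_plots = FALSE, closest_max_x = 1e5) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  stage <- "read inputs"
  result <- tryCatch({
    bprs <- read_bpr_table(bpr_file, dialect = bpr_dialect)
    genes <- read_gene_table(gene_file, dialect = gene_dialect)
    elements <- read_de_list(de_file)
    aliases <- if (!is.null(alias_file)) read_alias_map(alias_file) else NULL

    stage <- "branch selection"
    if (is.null(branches)) {
      if (is.null(pair) || is.null(tree)) {
        stop("supply either `branches` or both `pair` and `tree`")
      }
      branches <- branches_on_path(tree, pair[1L], pair[2L])
    }
    retained <- select_breakpoints(bprs, branches)
    branch_summary <- attr(retained, "summary")

    stage <- "name matching"
    match_res <- match_expression_to_genes(elements, genes, aliases)
    de_names <- unique(match_res$matched$matched_gene)

    stage <- "distances"
    if (is.null(chrom_lengths_file)) {
      top <- c(tapply(genes$end, genes$chrom, max),
               tapply(retained$end, retained$chrom, max))
      chrom_lengths <- tapply(top, names(top), max)
      chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                       names(chrom_lengths))
    } else {
      chrom_lengths <- read_chrom_lengths(chrom_lengths_file)
    }
    records <- compute_all_distances(genes, de_names, retained,
                                     point_mode = point_mode)

    stage <- "statistical tests"
    n_de_rec <- sum(records$is_de)
    if (n_de_rec > 0L && n_de_rec < nrow(records)) {
      ks <- two_sample_compare(records$z[records$is_de],
                               records$z[!records$is_de])
      mc <- monte_carlo_test(genes, de_names, retained, chrom_lengths,
                             n_sim = n_sim, seed = seed,
                             point_mode = point_mode)
    } else {
      ks <- NULL
      mc <- NULL
    }

    stage <- "reports"
    closest <- closest_de_table(records, max_x = closest_max_x)
    paths <- c(
      distances = file.path(outdir, "distances.tsv"),
      closest_de = file.path(outdir, "closest_de.tsv"),
      dropped = file.path(outdir, "dropped_elements.tsv"),
      branch_summary = file.path(outdir, "branch_summary.tsv"),
      tests = file.path(outdir, "test_results.tsv")
    )
    write_tsv(records, paths[["distances"]])
    write_tsv(closest, paths[["closest_de"]])
    write_drop_report(match_res$drop_report, paths[["dropped"]])
    write_tsv(branch_summary, paths[["branch_summary"]])
    tests_df <- data.frame(
      method = c("ks_two_sample", "monte_carlo_median_z"),
      statistic = c(if (is.null(ks)) NA_real_ else ks$D,
                    if (is.null(mc)) NA_real_ else mc$statistic),
      p = c(if (is.null(ks)) NA_real_ else ks$p,
            if (is.null(mc)) NA_real_ else mc$empirical_p),
      n_de = n_de_rec, n_rest = nrow(records) - n_de_rec,
      n_sim = c(NA_integer_, if (is.null(mc)) NA_integer_ else mc$n_sim),
      seed = c(NA_integer_, seed),
      stringsAsFactors = FALSE
    )
    write_tsv(tests_df, paths[["tests"]])
    if (make_plots) {
      fig <- file.path(outdir, "log_histogram.png")
      plot_log_histograms(records, outpath = fig)
      fig_chr <- file.path(outdir, "log_histogram_per_chromosome.png")
      plot_log_histograms(records, per_chromosome = TRUE, outpath = fig_chr)
      paths <- c(paths, figure = fig, figure_per_chromosome = fig_chr)
    }

    excluded <- attr(records, "excluded")
    structure(list(
      counts = list(
        elements_read = nrow(elements),
        matched = nrow(match_res$matched),
        dropped = length(match_res$unmatched),
        bprs_total = nrow(bprs),
        bprs_retained = nrow(retained),
        genes_total = nrow(genes),
        genes_analyzed = nrow(records),
        genes_excluded_no_bpr_chrom = sum(excluded),
        de_genes_analyzed = n_de_rec
      ),
      branch_summary = branch_summary,
      tests = list(ks = ks, monte_carlo = mc),
      paths = paths,
      seed = seed,
      settings = list(branches = branches, point_mode = point_mode,
                      n_sim = n_sim, closest_max_x = closest_max_x)
    ), class = "run_summary")
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Breakpoint-proximity pipeline run\n")
  cat("  elements read:", x$counts$elements_read,
      "| matched:", x$counts$matched,
      "| dropped:", x$counts$dropped, "\n")
  cat("  BPRs retained:", x$counts$bprs_retained, "of", x$counts$bprs_total,
      "( branches:", paste(x$settings$branches, collapse = ", "), ")\n")
  cat("  genes analyzed:", x$counts$genes_analyzed, "of",
      x$counts$genes_total,
      "(", x$counts$genes_excluded_no_bpr_chrom,
      "on BPR-free chromosomes )\n")
  if (!is.null(x$tests$ks)) {
    cat("  KS two-sample: D =", format(x$tests$ks$D, digits = 4),
        ", p =", format(x$tests$ks$p, digits = 4), "\n")
    cat("  Monte-Carlo median-z: observed =",
        format(x$tests$monte_carlo$statistic, digits = 6),
        ", p =", format(x$tests$monte_carlo$empirical_p, digits = 4),
        "( n_sim =", x$tests$monte_carlo$n_sim, ")\n")
  } else {
    cat("  tests skipped (no analyzable DE genes)\n")
  }
  invisible(x)
}
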