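# Synthetic genome generator
# --------------------------
# Emulates the statistical structure the analysis assumes: a few chromosomes
# of stated length; non-overlapping BPR intervals with widths spanning 1 nt
# to the Mb scale (log-uniform, echoing the 1 .. ~2.9e6 nt range of published
# BPR sets); genes scattered uniformly with log-normal widths; a DE-flagged
# subset; and an optional planted proximity effect in which a fraction of DE
# genes is placed within a set gap of a breakpoint boundary.  Expression
# values themselves are never simulated: the analysis consumes only the
# DE / non-DE partition.

#' Configuration of the synthetic genome generator
#'
#' Defaults describe a small genome sized for simulation studies: three
#' 100-Mb chromosomes, 5000 genes of ~20 kb median span, 40 BPRs with
#' log-uniform widths between 1 nt and ~2.9 Mb, and 250 DE genes with no
#' planted effect.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (nt).
#' @param n_genes Number of genes.
#' @param gene_width Median gene span in nt (log-normal widths).
#' @param gene_width_sdlog Geometric spread (sd of log-width).
#' @param n_bprs Number of breakpoint regions.
#' @param bpr_width_max Maximum BPR width in nt (widths log-uniform on
#'   `[1, bpr_width_max]`).
#' @param branch_labels Pool of evolutionary-branch labels.
#' @param branch_probs Probabilities over `branch_labels` (must sum to 1).
#' @param n_de Number of DE genes (`<= n_genes`).
#' @param effect_fraction Proportion of DE genes planted near BPRs (0 = null).
#' @param effect_radius Maximum planted gap to a BPR boundary, nt.
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(chrom_lengths = c(chr1 = 1e8, chr2 = 1e8,
                                               chr3 = 1e8),
                             n_genes = 5000,
                             gene_width = 20000,
                             gene_width_sdlog = 1,
                             n_bprs = 40,
                             bpr_width_max = 2887673,
                             branch_labels = c("human", "human-chimp",
                                               "macaque", "primates",
                                               "rodents"),
                             branch_probs = NULL,
                             n_de = 250,
                             effect_fraction = 0,
                             effect_radius = 10000,
                             seed = 1L) {
  if (is.null(branch_probs)) {
    branch_probs <- rep(1 / length(branch_labels), length(branch_labels))
  }
  cfg <- list(chrom_lengths = chrom_lengths, n_genes = n_genes,
              gene_width = gene_width, gene_width_sdlog = gene_width_sdlog,
              n_bprs = n_bprs, bpr_width_max = bpr_width_max,
              branch_labels = branch_labels, branch_probs = branch_probs,
              n_de = n_de, effect_fraction = effect_fraction,
              effect_radius = effect_radius, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(
    length(cfg$chrom_lengths) >= 1L, all(cfg$chrom_lengths > 0),
    !is.null(names(cfg$chrom_lengths)),
    cfg$n_genes >= 1L, cfg$n_de <= cfg$n_genes, cfg$n_de >= 0L,
    cfg$effect_fraction >= 0, cfg$effect_fraction <= 1,
    cfg$effect_radius >= 0, cfg$bpr_width_max >= 1,
    length(cfg$branch_probs) == length(cfg$branch_labels)
  )
  if (abs(sum(cfg$branch_probs) - 1) > 1e-8) {
    stop("branch_probs must sum to 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a genome, breakpoint set and DE gene list
#'
#' Places `n_bprs` non-overlapping BPR intervals (rejection sampling with a
#' bounded retry budget), scatters `n_genes` gene intervals uniformly, flags
#' `n_de` of them as differentially expressed, and plants
#' `ceiling(effect_fraction * n_de)` of the DE genes within a gap of at most
#' `effect_radius` nt of a uniformly chosen BPR boundary (measured from the
#' boundary, matching the gap definition used for distances).  Fully
#' reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list with `genes` (gene `data.frame`), `bprs` (BPR
#'   `data.frame`), `de_names` (character), `chrom_lengths`, and `config`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  chroms <- names(cfg$chrom_lengths)
  L <- cfg$chrom_lengths

  # --- BPRs: non-overlapping within each chromosome ---
  p_chrom <- L / sum(L)
  bpr_chrom <- sample(chroms, cfg$n_bprs, replace = TRUE, prob = p_chrom)
  widths <- round(exp(stats::runif(cfg$n_bprs, 0, log(cfg$bpr_width_max))))
  widths <- pmax(widths, 1)
  begin <- numeric(cfg$n_bprs)
  end <- numeric(cfg$n_bprs)
  placed <- rep(FALSE, cfg$n_bprs)
  max_tries <- 1000L
  for (ch in chroms) {
    idx <- which(bpr_chrom == ch)
    have_b <- numeric(0); have_e <- numeric(0)
    for (i in idx) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        b <- floor(stats::runif(1, 0, L[[ch]] - widths[i]))
        e <- b + widths[i]
        if (!any(b < have_e & have_b < e)) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("chromosome ", ch, " too crowded to place non-overlapping BPRs",
             call. = FALSE)
      }
      begin[i] <- b; end[i] <- e
      have_b <- c(have_b, b); have_e <- c(have_e, e)
      placed[i] <- TRUE
    }
  }
  bprs <- data.frame(
    chrom = bpr_chrom, begin = begin, end = end,
    branch = sample(cfg$branch_labels, cfg$n_bprs, replace = TRUE,
                    prob = cfg$branch_probs),
    stringsAsFactors = FALSE
  )
  bprs <- bprs[order_by_chrom(bprs$chrom, bprs$begin), , drop = FALSE]
  rownames(bprs) <- NULL

  # --- genes: uniform positions, log-normal widths ---
  gene_chrom <- sample(chroms, cfg$n_genes, replace = TRUE, prob = p_chrom)
  gw <- pmax(round(stats::rlnorm(cfg$n_genes, log(cfg$gene_width),
                                 cfg$gene_width_sdlog)), 1)
  gw <- pmin(gw, L[gene_chrom] - 1)
  gstart <- floor(stats::runif(cfg$n_genes, 0, L[gene_chrom] - gw))
  genes <- data.frame(
    name = sprintf("GENE%05d", seq_len(cfg$n_genes)),
    chrom = gene_chrom, start = gstart, end = gstart + gw,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )

  # --- DE subset, with optional planted proximity effect ---
  de_idx <- sample.int(cfg$n_genes, cfg$n_de)
  n_planted <- ceiling(cfg$effect_fraction * cfg$n_de)
  if (n_planted > 0L && nrow(bprs) > 0L) {
    planted <- de_idx[seq_len(n_planted)]
    for (i in planted) {
      k <- sample.int(nrow(bprs), 1L)
      side <- sample(c("left", "right"), 1L)
      gap <- floor(stats::runif(1, 0, cfg$effect_radius + 1))
      w <- genes$end[i] - genes$start[i]
      Lk <- L[[bprs$chrom[k]]]
      if (side == "left") {
        e <- bprs$begin[k] - gap
        s <- e - w
      } else {
        s <- bprs$end[k] + gap
        e <- s + w
      }
      # clamp inside the chromosome; clamping can only shrink the gap
      if (s < 0) { s <- 0; e <- w }
      if (e > Lk) { e <- Lk; s <- Lk - w }
      genes$chrom[i] <- bprs$chrom[k]
      genes$start[i] <- s
      genes$end[i] <- e
    }
  }
  list(genes = genes, bprs = bprs,
       de_names = sort(genes$name[de_idx]),
       chrom_lengths = cfg$chrom_lengths, config = cfg)
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits files readable by the package's own readers without modification:
#' `genes.bed` (BED), `bprs.tsv` (browser-style 1-based BPR table),
#' `de_list.tsv`, and `chrom_lengths.tsv`.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(dataset, outdir) {
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  paths <- c(
    genes = file.path(outdir, "genes.bed"),
    bprs = file.path(outdir, "bprs.tsv"),
    de = file.path(outdir, "de_list.tsv"),
    chrom_lengths = file.path(outdir, "chrom_lengths.tsv")
  )
  write_gene_bed(dataset$genes, paths[["genes"]])
  write_bpr_table(dataset$bprs, paths[["bprs"]], dialect = "bpr_tsv")
  writeLines(c("raw_name", dataset$de_names), paths[["de"]])
  cl <- dataset$chrom_lengths
  writeLines(c("chrom\tlength",
               paste(names(cl), format(cl, scientific = FALSE, trim = TRUE),
                     sep = "\t")),
             paths[["chrom_lengths"]])
  invisible(paths)
}

#' Read a chromosome-lengths table
#'
#' @param path Two-column TSV (`chrom`, `length`), header optional.
#' @return Named numeric vector.
#' @export
read_chrom_lengths <- function(path) {
  src <- read_tsv_lines(path)
  fields <- strsplit(src$lines, "[\t ]+")
  if (length(fields) > 0L && !is_integer_like(fields[[1L]][2L])) {
    fields <- fields[-1L]
  }
  stats::setNames(
    as.numeric(vapply(fields, `[[`, character(1), 2L)),
    vapply(fields, `[[`, character(1), 1L)
  )
}
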