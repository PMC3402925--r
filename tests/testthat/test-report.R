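test_that("log-distance bins have unit edges and match a brute-force binning", {
  ds <- simulate_dataset(synthetic_config(n_genes = 800, n_de = 60, seed = 44))
  rec <- compute_all_distances(ds$genes, ds$de_names, ds$bprs)
  bins <- bin_log_distances(rec)
  expect_equal(sort(unique(c(bins$bin_lo, bins$bin_hi))),
               0:max(bins$bin_hi))
  # brute-force per-value binning oracle
  n_bins <- max(bins$bin_hi)
  for (grp in c("DE", "background")) {
    z <- rec$z[xor(grp == "background", rec$is_de)]
    for (bl in 0:(n_bins - 1)) {
      manual <- sum(vapply(z, function(v) {
        v >= bl & (v < bl + 1 | (bl == n_bins - 1 & v <= n_bins))
      }, logical(1)))
      expect_equal(bins$count[bins$group == grp & bins$bin_lo == bl], manual)
    }
    # counts sum to group size, densities to 1
    expect_equal(sum(bins$count[bins$group == grp]), length(z))
    expect_equal(sum(bins$density[bins$group == grp]), 1)
  }
  # per-chromosome counts sum to the genome-wide count
  bc <- bin_log_distances(rec, by_chrom = TRUE)
  agg <- tapply(bc$count, paste(bc$group, bc$bin_lo), sum)
  expect_equal(as.integer(agg[paste(bins$group, bins$bin_lo)]), bins$count)
})

test_that("histogram figures render genome-wide and per chromosome", {
  ds <- simulate_dataset(synthetic_config(n_genes = 500, n_de = 50, seed = 3))
  rec <- compute_all_distances(ds$genes, ds$de_names, ds$bprs)
  fl <- flanking_intervals(make_genes(rec$name, rec$chrom, rec$start,
                                      rec$end), ds$bprs, ds$chrom_lengths)
  mix <- suppressWarnings(mixture_from_genes(fl))
  out <- withr::local_tempfile(fileext = ".png")
  res <- plot_log_histograms(rec, outpath = out, mixture = mix)
  expect_true(file.exists(out))
  expect_s3_class(res$plot, "ggplot")
  res2 <- plot_log_histograms(rec, per_chromosome = TRUE)
  expect_true("chrom" %in% names(res2$bins))
})

test_that("DE genes planted at x = 0 concentrate all DE mass in the first bin", {
  bprs <- make_bprs("chrT", c(1e5, 5e5), c(1e5 + 50, 5e5 + 50))
  de <- make_genes(c("D1", "D2"), "chrT", c(1e5 - 20, 5e5 - 20),
                   c(1e5 + 20, 5e5 + 20))
  bg <- make_genes(c("B1", "B2"), "chrT", c(2e5, 3e5), c(2e5 + 100, 3e5 + 100))
  rec <- compute_all_distances(rbind(de, bg), de$name, bprs)
  bins <- bin_log_distances(rec)
  de_bins <- bins[bins$group == "DE", ]
  expect_equal(de_bins$density[de_bins$bin_lo == 0], 1)
})

test_that("the closest-DE-gene table sorts, truncates and tie-breaks as documented", {
  ds <- simulate_dataset(synthetic_config(n_genes = 600, n_de = 50,
                                          effect_fraction = 0.1,
                                          effect_radius = 5e4, seed = 15))
  rec <- compute_all_distances(ds$genes, ds$de_names, ds$bprs)
  tab <- closest_de_table(rec)
  expect_true(all(diff(tab$x) >= 0))
  top1 <- closest_de_table(rec, k = 1)
  expect_equal(nrow(top1), 1L)
  expect_equal(top1$x, min(rec$x[rec$is_de]))
  cut <- closest_de_table(rec, max_x = 1e5)
  expect_equal(nrow(cut), sum(rec$is_de & rec$x <= 1e5))
  # brute-force sort oracle with lexicographic gene-name tie-break
  de <- rec[rec$is_de, ]
  want <- de[order(de$x, de$name), "name"]
  expect_equal(closest_de_table(rec)$gene, want)
  # no DE records -> empty table with header
  rec0 <- compute_all_distances(ds$genes, character(), ds$bprs)
  empty <- closest_de_table(rec0)
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("gene", "chrom", "x", "z", "nearest_begin",
                        "nearest_end", "nearest_branch"))
})

test_that("the pipeline runs end-to-end on a synthetic fixture with reconciled counts", {
  ds <- simulate_dataset(synthetic_config(n_genes = 800, n_bprs = 20,
                                          n_de = 60, seed = 10))
  fixdir <- withr::local_tempdir()
  paths <- write_fixture(ds, fixdir)
  outdir <- withr::local_tempdir()
  smry <- run_pipeline(
    bpr_file = paths[["bprs"]], gene_file = paths[["genes"]],
    de_file = paths[["de"]], branches = unique(ds$bprs$branch),
    chrom_lengths_file = paths[["chrom_lengths"]],
    n_sim = 100, seed = 4, outdir = outdir
  )
  expect_s3_class(smry, "run_summary")
  cnt <- smry$counts
  expect_equal(cnt$matched + cnt$dropped, cnt$elements_read)
  expect_equal(cnt$genes_analyzed + cnt$genes_excluded_no_bpr_chrom,
               cnt$genes_total)
  expect_equal(cnt$bprs_retained, nrow(ds$bprs))
  expect_true(all(file.exists(smry$paths)))
  expect_output(print(smry), "pipeline run")
})

test_that("identical config and seed give byte-identical pipeline outputs", {
  ds <- simulate_dataset(synthetic_config(n_genes = 400, n_bprs = 15,
                                          n_de = 40, seed = 6))
  fixdir <- withr::local_tempdir()
  paths <- write_fixture(ds, fixdir)
  run_once <- function(outdir) {
    run_pipeline(
      bpr_file = paths[["bprs"]], gene_file = paths[["genes"]],
      de_file = paths[["de"]], branches = unique(ds$bprs$branch),
      chrom_lengths_file = paths[["chrom_lengths"]],
      n_sim = 100, seed = 4, outdir = outdir
    )
  }
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  s1 <- run_once(o1); s2 <- run_once(o2)
  for (f in basename(s1$paths)) {
    expect_identical(readLines(file.path(o1, f)), readLines(file.path(o2, f)),
                     label = f)
  }
  expect_equal(s1$tests$monte_carlo$empirical_p,
               s2$tests$monte_carlo$empirical_p)
})

test_that("the pipeline reproduces hand-computed distances on the bundled excerpt", {
  genedir <- withr::local_tempdir()
  gene_file <- file.path(genedir, "genes.bed")
  writeLines(c(
    "chr3\t127500000\t127501000\tGENEA\t0\t+",
    "chr1\t10382300\t10382400\tGENEB\t0\t-",
    "chr9\t1000\t2000\tGENEC\t0\t+"
  ), gene_file)
  de_file <- file.path(genedir, "de.tsv")
  writeLines(c("raw_name", "GENEA", "GENEB"), de_file)
  outdir <- withr::local_tempdir()
  smry <- run_pipeline(
    bpr_file = bpr_excerpt_path(), gene_file = gene_file, de_file = de_file,
    branches = c("dog", "chimp", "macaque", "primates", "rodents", "mouse",
                 "rat"),
    n_sim = 100, seed = 1, outdir = outdir
  )
  rec <- read.delim(file.path(outdir, "distances.tsv"))
  expect_equal(rec$x[rec$name == "GENEA"], 292184)
  expect_equal(rec$x[rec$name == "GENEB"], 0)
  expect_false("GENEC" %in% rec$name)  # chr9 carries no breakpoint
  expect_equal(smry$counts$genes_excluded_no_bpr_chrom, 1L)
})

test_that("a stage failure is reported with its stage name", {
  expect_error(
    run_pipeline(bpr_file = "does-not-exist.tsv", gene_file = "x",
                 de_file = "y", branches = "rat",
                 outdir = withr::local_tempdir()),
    "stage 'read inputs'"
  )
})
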