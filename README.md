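# breakprox

Do genes that changed expression between two species sit closer to the
breakpoints of evolutionary chromosomal rearrangements than the rest of the
gene complement?

When a rearrangement (inversion, translocation, fusion/fission) creates a
breakpoint, it can sever a gene from its regulatory neighbourhood. If that
matters in evolution, differentially expressed (DE) genes should crowd the
breakpoint regions (BPRs) of the genome. `breakprox` implements a genome-wide
test of this question: it links an unpositioned DE gene list to a positional
gene annotation by name, selects the breakpoints on the evolutionary branches
that actually separate the two species, computes every gene's distance to its
nearest BPR, and compares the DE distance distribution against the background
under an exact spatial null model.

## The null model

Let a gene lie between flanking breakpoint boundaries at positions *a₁* and
*a₂*, with half-spacing *u* = |*a₁* − *a₂*|/2. If breakpoint creation is
independent of expression change, the gene's position is uniform in the
interval, so its distance *x* to the nearer boundary is uniform on [0, *u*].
Because intergenic distances span orders of magnitude, the analysis works
with *z* = ln *x* (taking *x* uniform on [1, *u*] so *z* ≥ 0), whose density
is a truncated positive exponential:

    p(z) = e^(z − U),   0 ≤ z ≤ U,   U = ln u.

Genome-wide, each gene has its own *u*, so the predicted distribution of *z*
is a mixture of such components (equal weights by default). On top of the
exact density/CDF/sampler the package provides two quantitative tests:

* a **two-sample Kolmogorov–Smirnov** comparison of DE vs background
  log-distances, and
* a **Monte-Carlo position-resampling test**: each DE gene is repeatedly
  redrawn uniformly inside its flanking interval (width preserved), distances
  are recomputed, and the observed median *z* is ranked against the simulated
  medians.

## Worked example

A small published excerpt of a human multi-species BPR table ships with the
package. Reading it, picking the branches separating human from macaque via
an edge-labelled phylogeny, and filtering:

```r
library(breakprox)
bprs <- read_bpr_table(system.file("extdata", "bpr_excerpt.tsv",
                                   package = "breakprox"))
nrow(bprs)
#> [1] 13
branches_on_path("((human,chimp)human-chimp,macaque)root;",
                 "human", "macaque")
#> [1] "human"       "human-chimp" "macaque"
```

The excerpt contains 2 records on those branches' labels that it uses
(`macaque`); a full BPR table would carry all three. Distances are plain
interval gaps — for a gene at chr3:127,500,000–127,501,000 the nearest of the
two chr3 BPRs lies 292,184 nt away, and its flanking half-spacing is
*u* = 539,642.5 nt:

```r
gene <- data.frame(name = "GENEA", chrom = "chr3",
                   start = 127500000, end = 127501000, strand = "+")
nearest_bpr_distance(gene, bprs[bprs$chrom == "chr3", ])$x
#> [1] 292184
flanking_interval(gene, bprs, 199501827)$u
#> [1] 539642.5
```

An end-to-end run on a synthetic genome (three 100-Mb chromosomes, 5000
genes, 40 BPRs, 250 DE genes, half of them planted within 10 kb of a
breakpoint boundary):

```r
ds  <- simulate_dataset(synthetic_config(effect_fraction = 0.5, seed = 7))
fix <- write_fixture(ds, tempfile("fix"))
run_pipeline(bpr_file = fix[["bprs"]], gene_file = fix[["genes"]],
             de_file = fix[["de"]], branches = unique(ds$bprs$branch),
             chrom_lengths_file = fix[["chrom_lengths"]],
             n_sim = 1000, seed = 42, outdir = tempfile("out"))
#> Breakpoint-proximity pipeline run
#>   elements read: 250 | matched: 250 | dropped: 0
#>   BPRs retained: 40 of 40 ( branches: rodents, human-chimp, primates, macaque, human )
#>   genes analyzed: 5000 of 5000 ( 0 on BPR-free chromosomes )
#>   KS two-sample: D = 0.496 , p = 0
#>   Monte-Carlo median-z: observed = 9.1636 , p = 0.000999 ( n_sim = 1000 )
```

Both tests detect the planted proximity effect: the DE median log-distance
(9.16, i.e. ~9.5 kb) is far below anything the 1000 position-resampling
simulations produce, so the empirical p attains its minimum 1/(n_sim+1).
The run directory holds every intermediate as TSV (`distances.tsv`,
`closest_de.tsv`, `dropped_elements.tsv`, `branch_summary.tsv`,
`test_results.tsv`) plus optional log-scale histogram figures
(`plot_log_histograms()`).

A thin command-line front end with `simulate`, `distances`, `test`,
`report` and `run` subcommands is installed at
`system.file("scripts", "breakprox.R", package = "breakprox")`.

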