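# The log-distance null model
# ---------------------------
# Under no association between breakpoint creation and expression change, a
# gene falls uniformly in the interval between the two breakpoint boundaries
# flanking it (positions a1, a2; half-spacing u = |a1 - a2| / 2).  Its
# distance x to the nearer boundary is then uniform on [0, u]; on the log
# scale z = ln x (with x taken uniform on [1, u] so that z >= 0) the density
# is a truncated positive exponential
#     p(z) = e^(z - U),   0 <= z <= U,   U = ln u.
# This density integrates to 1 - e^(-U): the missing e^(-U) is the mass of
# x < 1 nt under the un-floored model, negligible for genomic u.  Genome-wide,
# each gene has its own u, so the predicted empirical distribution is a
# mixture of such components.

#' Truncated-exponential log-distance null density
#'
#' The density of `z = ln x` when the distance `x` to the nearest breakpoint
#' boundary is uniform on `[1, u]` with `U = ln u`: `e^(z - U)` on
#' `[0, U]`, 0 outside.  Its integral over `[0, U]` is `1 - e^(-U)` (the mass
#' of sub-nucleotide distances under the continuous model).
#'
#' @param z Numeric vector of log-distances.
#' @param U Upper truncation point `ln u` (scalar, > 0).
#' @return Density values, same length as `z`.
#' @export
null_density <- function(z, U) {
  check_U(U)
  ifelse(z >= 0 & z <= U, exp(z - U), 0)
}

check_U <- function(U) {
  if (length(U) != 1L || !is.finite(U) || U <= 0) {
    stop("U must be a single positive finite number", call. = FALSE)
  }
}

#' Null-model cumulative distribution of the log distance
#'
#' Exact CDF of `z = ln x` for `x` uniform on `[1, u]`:
#' `F(z) = (e^z - 1) / (e^U - 1)` on `[0, U]`, clamped to 0 / 1 outside.
#'
#' @inheritParams null_density
#' @return Probabilities, same length as `z`.
#' @export
null_cdf <- function(z, U) {
  check_U(U)
  p <- expm1(pmin(pmax(z, 0), U)) / expm1(U)
  ifelse(z < 0, 0, ifelse(z > U, 1, p))
}

#' Null-model quantile function
#'
#' Inverse of [null_cdf()]: `z(p) = log(1 + p (e^U - 1))`.
#'
#' @param p Probabilities in `[0, 1]`.
#' @inheritParams null_density
#' @return Log-distance quantiles.
#' @export
null_quantile <- function(p, U) {
  check_U(U)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  log1p(p * expm1(U))
}

#' Draw from the log-distance null
#'
#' Inverse-CDF sampling on a seeded uniform stream; reproducible given
#' `seed`.  The exponential of the draws is uniform on `[1, e^U]`.
#'
#' @param n Number of draws.
#' @inheritParams null_density
#' @param seed Optional integer seed; when supplied the draw leaves the
#'   global RNG state untouched.
#' @return Numeric vector of `n` log-distances in `[0, U]`.
#' @export
sample_null <- function(n, U, seed = NULL) {
  check_U(U)
  draw <- function() null_quantile(stats::runif(n), U)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Per-genome mixture prediction of the log-distance distribution
#'
#' Each gene contributes a truncated-exponential component with its own
#' truncation `U_i = ln u_i` taken from its flanking half-spacing.
#' Components with `u < 1` nt (degenerate flanks) are dropped with a warning.
#' Weights are equal (`1/n`) by default; `"interval"` weights components
#' proportionally to `u_i` instead.
#'
#' @param flanks `data.frame` from [flanking_intervals()], or a numeric
#'   vector of `U` values.
#' @param weights `"equal"` (default) or `"interval"`.
#' @return An object of class `mixture_null`: list with `U` (component
#'   truncations) and `w` (weights summing to 1).
#' @export
mixture_from_genes <- function(flanks, weights = c("equal", "interval")) {
  weights <- match.arg(weights)
  if (is.data.frame(flanks)) {
    ok <- !is.na(flanks$U) & flanks$u >= 1
    if (any(!ok)) {
      warning(sum(!ok), " flanking interval(s) with u < 1 nt dropped")
    }
    U <- flanks$U[ok]
    u <- flanks$u[ok]
  } else {
    U <- as.numeric(flanks)
    u <- exp(U)
  }
  if (length(U) == 0L) {
    stop("all flanking intervals are degenerate; no mixture can be formed",
         call. = FALSE)
  }
  w <- if (weights == "equal") rep(1 / length(U), length(U)) else u / sum(u)
  structure(list(U = U, w = w), class = "mixture_null")
}

#' Evaluate a mixture-null density
#'
#' @param mixture A `mixture_null` from [mixture_from_genes()].
#' @param z Numeric vector of log-distances.
#' @return Mixture density `sum_i w_i e^(z - U_i) [0 <= z <= U_i]` at each
#'   `z`.
#' @export
mixture_density <- function(mixture, z) {
  stopifnot(inherits(mixture, "mixture_null"))
  vapply(z, function(zz) {
    sum(mixture$w * ifelse(zz >= 0 & zz <= mixture$U, exp(zz - mixture$U), 0))
  }, numeric(1))
}

#' @export
print.mixture_null <- function(x, ...) {
  cat("Log-distance mixture null:", length(x$U), "components, U in [",
      format(min(x$U), digits = 4), ",", format(max(x$U), digits = 4), "]\n")
  invisible(x)
}

#' Two-sample comparison of DE and background log-distances
#'
#' Standard two-sample Kolmogorov-Smirnov comparison of the log-distance
#' samples of differentially expressed genes and of the rest of the gene
#' complement.  This is a quantitative formalization of the side-by-side
#' histogram comparison the scientific question calls for.
#'
#' @param z_de Log-distances of DE genes.
#' @param z_rest Log-distances of the remaining gene complement.
#' @return A list with `D` (KS statistic), `p` (asymptotic p-value), `n_de`,
#'   `n_rest`.  A warning is issued when either sample has fewer than 5
#'   observations.
#' @export
two_sample_compare <- function(z_de, z_rest) {
  if (length(z_de) == 0L || length(z_rest) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (min(length(z_de), length(z_rest)) < 5L) {
    warning("a sample has fewer than 5 observations; p-value is unreliable")
  }
  ks <- suppressWarnings(stats::ks.test(z_de, z_rest, exact = FALSE))
  list(D = unname(ks$statistic), p = unname(ks$p.value),
       n_de = length(z_de), n_rest = length(z_rest))
}

#' Monte-Carlo position-resampling test of DE proximity to breakpoints
#'
#' Operationalizes the null hypothesis that a gene's position is uniform in
#' its flanking interval: in each simulation every DE gene is redrawn
#' uniformly within its flanking breakpoint boundaries (gene width preserved,
#' clamped inside), distances are recomputed with the same distance operator
#' as the observed data, and the test statistic (median of `z` over DE genes
#' by default) is recorded.  The one-sided empirical p-value is
#' `(1 + #\{sims with statistic <= observed\}) / (n_sim + 1)`: small when DE
#' genes sit closer to breakpoints than chance placement allows.
#'
#' Genes whose flanking interval is degenerate (midpoint inside a BPR) or
#' narrower than the gene keep their observed distance in every simulation.
#'
#' @param genes Gene `data.frame`.
#' @param de_names Character vector of DE gene names; must select at least
#'   one analyzable gene.
#' @param bprs BPR `data.frame` (already branch-filtered).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param n_sim Number of simulations (>= 100 recommended).
#' @param seed Optional integer seed (global RNG state preserved).
#' @param stat `"median"` (default) or `"mean"` of DE log-distances.
#' @param point_mode Use gene-midpoint distances throughout.
#' @return An object of class `mc_test`: list with `statistic` (observed),
#'   `stat`, `empirical_p`, `n_sim`, `n_de`, `seed`, `sim_stats`.
#' @export
monte_carlo_test <- function(genes, de_names, bprs, chrom_lengths,
                             n_sim = 1000, seed = NULL,
                             stat = c("median", "mean"), point_mode = FALSE) {
  stat <- match.arg(stat)
  run <- function() {
    mc_test_impl(genes, de_names, bprs, chrom_lengths, n_sim, stat,
                 point_mode, seed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

mc_test_impl <- function(genes, de_names, bprs, chrom_lengths, n_sim, stat,
                         point_mode, seed) {
  records <- compute_all_distances(genes, de_names, bprs, point_mode)
  de <- records[records$is_de, , drop = FALSE]
  if (nrow(de) == 0L) {
    stop("DE set is empty after matching to BPR-bearing chromosomes",
         call. = FALSE)
  }
  stat_fun <- if (stat == "median") stats::median else mean
  observed <- stat_fun(de$z)
  fl <- flanking_intervals(de, bprs, chrom_lengths)
  w <- if (point_mode) rep(0, nrow(de)) else de$end - de$start
  lb <- fl$a1                                   # 0-based left boundary
  rb <- ifelse(fl$has_right, fl$a2 - 1, fl$a2)  # 0-based right boundary
  lo <- lb + w / 2
  hi <- rb - w / 2
  fixed <- fl$degenerate | hi < lo
  n_de <- nrow(de)
  um <- matrix(stats::runif(n_de * n_sim), nrow = n_de)
  midm <- lo + um * pmax(hi - lo, 0)  # vectors recycle down columns
  ldist <- midm - w / 2 - lb
  rdist <- rb - (midm + w / 2)
  ldist[!fl$has_left, ] <- Inf
  rdist[!fl$has_right, ] <- Inf
  xm <- pmin(ldist, rdist)
  xm[fixed, ] <- de$x[fixed]
  zm <- log(pmax(xm, 1))
  sim_stats <- apply(zm, 2L, stat_fun)
  p <- (1 + sum(sim_stats <= observed)) / (n_sim + 1)
  structure(list(statistic = observed, stat = stat, empirical_p = p,
                 n_sim = n_sim, n_de = n_de, seed = seed,
                 sim_stats = sim_stats),
            class = "mc_test")
}

#' @export
print.mc_test <- function(x, ...) {
  cat("Monte-Carlo position-resampling test\n")
  cat("  observed", x$stat, "z over", x$n_de, "DE genes:",
      format(x$statistic, digits = 6), "\n")
  cat("  empirical p =", format(x$empirical_p, digits = 4),
      "(", x$n_sim, "simulations )\n")
  invisible(x)
}
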