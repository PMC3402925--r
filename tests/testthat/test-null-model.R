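test_that("the truncated-exponential density has its stated closed form", {
  U <- 16
  expect_equal(null_density(U, U), 1)
  expect_equal(null_density(U - 1, U), exp(-1))
  expect_equal(null_density(-0.5, U), 0)
  expect_equal(null_density(U + 0.5, U), 0)
  # total mass 1 - e^(-U): the sub-nucleotide tail of the continuous model
  q <- integrate(function(z) null_density(z, U), 0, U, rel.tol = 1e-10)
  expect_equal(q$value, 1 - exp(-U), tolerance = 1e-7)
  expect_error(null_density(1, 0), "positive")
})

test_that("the CDF is exact, clamps outside its support, and inverts", {
  U <- 16
  expect_equal(null_cdf(0, U), 0)
  expect_equal(null_cdf(U, U), 1)
  expect_equal(null_cdf(-3, U), 0)
  expect_equal(null_cdf(U + 3, U), 1)
  z <- seq(0.5, U - 0.5, by = 0.5)
  expect_equal(null_quantile(null_cdf(z, U), U), z, tolerance = 1e-9)
  # numerical derivative of the CDF matches the density on a grid
  h <- 1e-7
  grid <- seq(0.5, U - 0.5, length.out = 50)
  deriv <- (null_cdf(grid + h, U) - null_cdf(grid - h, U)) / (2 * h)
  expect_equal(deriv, null_density(grid, U), tolerance = 1e-5)
})

test_that("seeded draws reproduce and follow the closed-form law", {
  U <- 16
  z1 <- sample_null(1000, U, seed = 11)
  z2 <- sample_null(1000, U, seed = 11)
  expect_identical(z1, z2)
  z <- sample_null(1e5, U, seed = 42)
  expect_true(all(z >= 0 & z <= U))
  ks <- suppressWarnings(ks.test(z, function(q) null_cdf(q, U)))
  expect_lt(unname(ks$statistic), 0.01)
  # exp(z) is uniform on [1, e^U]: mean within 3 standard errors
  m <- exp(U)
  se <- (m - 1) / sqrt(12 * length(z))
  expect_lt(abs(mean(exp(z)) - (m + 1) / 2), 3 * se)
})

test_that("the equal-weight mixture has its closed-form value and unit mass", {
  mix <- mixture_from_genes(c(15, 16, 17))
  expect_equal(mixture_density(mix, 15), (1 + exp(-1) + exp(-2)) / 3,
               tolerance = 1e-9)
  expect_equal(sum(mix$w), 1)
  q <- integrate(function(z) mixture_density(mix, z), 0, 17,
                 rel.tol = 1e-9, subdivisions = 500)
  expect_equal(q$value, 1, tolerance = 1e-6)
  # a single component reduces to the plain null density
  single <- mixture_from_genes(16)
  zg <- seq(0, 16, length.out = 30)
  expect_equal(mixture_density(single, zg), null_density(zg, 16))
})

test_that("mixtures are built from flanking intervals, dropping degenerate flanks", {
  fl <- data.frame(u = c(exp(15), exp(16), 0.5),
                   U = c(15, 16, NA), stringsAsFactors = FALSE)
  expect_warning(mix <- mixture_from_genes(fl), "dropped")
  expect_length(mix$U, 2L)
  expect_equal(mix$w, c(0.5, 0.5))
  # interval-proportional weighting as the alternative convention
  expect_warning(mix2 <- mixture_from_genes(fl, weights = "interval"))
  expect_equal(mix2$w, c(exp(15), exp(16)) / (exp(15) + exp(16)))
  expect_error(suppressWarnings(mixture_from_genes(fl[3, ])), "degenerate")
})

test_that("the two-sample comparison behaves at its boundaries and detects shifts", {
  z <- sample_null(500, 16, seed = 5)
  same <- two_sample_compare(z, z)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  withr::local_seed(9)
  z_rest <- sample_null(10000, 16)
  z_de <- sample_null(250, 16) - 5  # planted proximity: 5 log-units closer
  shifted <- two_sample_compare(z_de, z_rest)
  expect_lt(shifted$p, 0.001)
  expect_warning(two_sample_compare(z[1:3], z_rest), "fewer than 5")
})

test_that("the KS statistic equals the brute-force maximum ECDF difference", {
  withr::local_seed(13)
  for (rep in 1:10) {
    a <- round(runif(20, 0, 10), 2)
    b <- round(runif(35, 0, 10), 2)
    pts <- c(a, b)
    d_brute <- max(vapply(pts, function(t) {
      abs(mean(a <= t) - mean(b <= t))
    }, numeric(1)))
    expect_equal(two_sample_compare(a, b)$D, d_brute)
  }
})

test_that("DE genes planted at distance zero give the smallest possible empirical p", {
  # genes overlapping a BPR edge: observed distance 0, resampled positions
  # essentially never reproduce a median of 0
  bprs <- make_bprs("chrT", c(2e5, 6e5), c(2e5 + 100, 6e5 + 100))
  de <- make_genes(sprintf("DE%02d", 1:8), "chrT",
                   rep(c(2e5 - 50, 6e5 - 50), 4),
                   rep(c(2e5 + 50, 6e5 + 50), 4))
  bg <- make_genes(sprintf("BG%02d", 1:20), "chrT",
                   seq(1e4, 9e5, length.out = 20),
                   seq(1e4, 9e5, length.out = 20) + 1000)
  res <- monte_carlo_test(rbind(de, bg), de$name, bprs, c(chrT = 1e6),
                          n_sim = 200, seed = 3)
  expect_equal(res$statistic, 0)
  expect_equal(res$empirical_p, 1 / 201)
})

test_that("Monte-Carlo p-values are stable across n_sim on a fixed seed", {
  ds <- simulate_dataset(synthetic_config(n_genes = 1000, n_de = 100,
                                          seed = 21))
  p1 <- monte_carlo_test(ds$genes, ds$de_names, ds$bprs, ds$chrom_lengths,
                         n_sim = 100, seed = 8)$empirical_p
  p2 <- monte_carlo_test(ds$genes, ds$de_names, ds$bprs, ds$chrom_lengths,
                         n_sim = 1000, seed = 8)$empirical_p
  # Monte-Carlo error of a p around p1 at n = 100
  expect_lt(abs(p1 - p2), 3 * sqrt(p1 * (1 - p1) / 100) + 0.02)
  expect_error(
    monte_carlo_test(ds$genes, character(), ds$bprs, ds$chrom_lengths,
                     n_sim = 100, seed = 1),
    "DE set is empty"
  )
})
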