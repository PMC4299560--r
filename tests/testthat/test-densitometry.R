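test_that("fibrosis fraction matches direct voxel counting", {
  cases <- list(
    list(values = rep(-850, 100), ff = 0),       # all nonfibrotic
    list(values = rep(-600, 100), ff = 100),     # all fibrotic
    list(values = c(rep(-600, 300), rep(-850, 700)), ff = 30))
  for (cs in cases) {
    f <- volume_with_values(cs$values)
    r <- fibrosis_fraction(f$volume, f$mask)
    expect_equal(r$fibrosis_fraction_pct, cs$ff)
    expect_equal(r$n_total_voxels, length(cs$values))
  }
})

test_that("a voxel at exactly -700 HU counts as nonfibrotic", {
  f <- volume_with_values(c(rep(-700, 40), rep(-699, 60)))
  r <- fibrosis_fraction(f$volume, f$mask)
  expect_equal(r$fibrosis_fraction_pct, 60)
  expect_equal(r$n_nonfibrotic_voxels, 40L)
})

test_that("band decomposition is exact and FF is bounded", {
  set.seed(4)
  for (i in 1:5) {
    f <- volume_with_values(sample(-1100:100, 500, replace = TRUE))
    r <- fibrosis_fraction(f$volume, f$mask)
    hu <- f$volume$voxels[f$mask$mask]
    n_fib <- sum(hu > -700 & hu <= -200)
    expect_identical(r$n_total_voxels - r$n_nonfibrotic_voxels, n_fib)
    expect_gte(r$fibrosis_fraction_pct, 0)
    expect_lte(r$fibrosis_fraction_pct, 100)
  }
})

test_that("raising a voxel from -850 to -600 never decreases FF", {
  set.seed(5)
  vals <- sample(c(-850, -600), 200, replace = TRUE)
  f <- volume_with_values(vals)
  ff0 <- fibrosis_fraction(f$volume, f$mask)$fibrosis_fraction_pct
  idx <- which(vals == -850)[1]
  vals[idx] <- -600
  f2 <- volume_with_values(vals)
  expect_gte(fibrosis_fraction(f2$volume, f2$mask)$fibrosis_fraction_pct, ff0)
})

test_that("noise-free phantom FF equals ground truth exactly", {
  for (f in c(0, 0.3, 1)) {
    ph <- generate_phantom(small_phantom_spec(fraction = f, noise_sd = 0))
    m <- segment_lungs(ph$volume)
    r <- fibrosis_fraction(ph$volume, m)
    expect_equal(r$fibrosis_fraction_pct, ph$truth_fibrotic_fraction)
  }
})

test_that("an empty masked band is an error, not a silent zero", {
  f <- volume_with_values(rep(40, 10))
  expect_error(fibrosis_fraction(f$volume, f$mask),
               class = "ctild_undefined_fraction_error")
})

test_that("symmetric two-point histogram has zero skewness and MLA at the midpoint", {
  f <- volume_with_values(c(rep(-900, 50), rep(-800, 50)))
  d <- histogram_descriptors(f$volume, f$mask)
  expect_equal(d$mla_hu, -850)
  expect_equal(d$skewness, 0)
  expect_equal(d$kurtosis, 1)  # two equal point masses
  expect_equal(histogram_descriptors(f$volume, f$mask, excess = TRUE)$kurtosis,
               -2)
})

test_that("kurtosis of truncated-normal draws matches the analytic value", {
  mu <- -850; sig <- 100; a <- -1024; b <- -200
  # independent oracle: central moments of the truncated normal by
  # numerical integration of the density
  z <- function(x) dnorm(x, mu, sig) / (pnorm(b, mu, sig) - pnorm(a, mu, sig))
  m1 <- integrate(function(x) x * z(x), a, b)$value
  mk <- function(k) integrate(function(x) (x - m1)^k * z(x), a, b)$value
  kurt_true <- mk(4) / mk(2)^2
  set.seed(8)
  draws <- rnorm(2e6, mu, sig)
  draws <- draws[draws >= a & draws <= b][1:1e6]
  f <- volume_with_values(draws)  # rounded to integer HU on construction
  d <- histogram_descriptors(f$volume, f$mask)
  expect_lt(abs(d$kurtosis - kurt_true), 0.05)
  expect_lt(abs(d$mla_hu - m1), 1)
})

test_that("constant histograms raise a zero-variance error that carries MLA", {
  f <- volume_with_values(rep(-850, 1))
  err <- tryCatch(histogram_descriptors(f$volume, f$mask),
                  condition = function(e) e)
  expect_s3_class(err, "ctild_zero_variance_error")
  expect_equal(err$mla, -850)
  r <- fibrosis_fraction(f$volume, f$mask)  # FF itself is still defined
  expect_equal(r$fibrosis_fraction_pct, 0)
  expect_true(is.na(r$skewness) && is.na(r$kurtosis))
})

test_that("band validation enforces nesting and the shared floor", {
  expect_error(density_bands(nonfibrotic = c(-1000, -700)),
               class = "ctild_config_error")
  expect_error(density_bands(total = c(-1024, -800)),
               class = "ctild_config_error")
})
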