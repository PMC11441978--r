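test_that("pixel statistics match hand-computed cases", {
  s <- compute_pixel_stats(c(5, 5, 5, 5))
  expect_equal(s$raw_mean, 5)
  expect_equal(s$variance, 0)
  expect_equal(s$cv, 0)
  expect_equal(s$fano, 0)

  s2 <- compute_pixel_stats(c(2, 4, 6))
  expect_equal(s2$sub_mean, 4)
  expect_equal(s2$variance, 4)     # sample (n-1) variance
  expect_equal(s2$cv, 0.5)
  expect_equal(s2$fano, 1)

  # shifting pixels and background together changes nothing
  s3 <- compute_pixel_stats(c(12, 14, 16), background_mean = 10)
  expect_equal(s3$sub_mean, 4)
  expect_equal(s3$variance, 4)
  expect_equal(s3$cv, 0.5)
  expect_equal(s3$fano, 1)

  expect_error(compute_pixel_stats(5), "at least 2")
  u <- compute_pixel_stats(c(1, 2, 3), background_mean = 10)
  expect_true(u$undefined)
  expect_true(is.na(u$cv) && is.na(u$fano))
})

test_that("pixel statistics agree with the brute-force oracle", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    px <- runif(n, 0, 1000)
    bg <- runif(1, 0, 100)
    s <- compute_pixel_stats(px, bg)
    o <- o_pixel_stats(px, bg)
    expect_equal(s$variance, o$variance)
    if (!s$undefined) {
      expect_equal(s$cv, o$cv)
      expect_equal(s$fano, o$fano)
      # algebraic identity to machine precision
      expect_equal(s$fano, s$cv^2 * s$sub_mean, tolerance = 1e-12)
    }
  }
})

test_that("cv and fano are invariant to a matched constant offset", {
  set.seed(55)
  for (i in 1:20) {
    px <- runif(50, 10, 500)
    shift <- runif(1, 0, 200)
    a <- compute_pixel_stats(px, 0)
    b <- compute_pixel_stats(px + shift, shift)
    expect_equal(a$cv, b$cv, tolerance = 1e-9)
    expect_equal(a$fano, b$fano, tolerance = 1e-9)
  }
})

test_that("fano normalization pins the reference mean at exactly 1", {
  nf <- normalize_fano(4, c(1, 2, 3))
  expect_equal(nf$values, 2)
  ref <- c(0.9, 1.1, 1.4, 0.8)
  self <- normalize_fano(ref, ref)
  expect_identical(self$mean, 1)               # exact, not approximate
  expect_equal(self$sem, sd(ref / mean(ref)) / 2)
  expect_error(normalize_fano(c(1, 2), numeric(0)), "empty")
  expect_error(normalize_fano(c(1, 2), c(-2, 1)), "positive")
})

test_that("pixel colocalization reproduces Pearson r", {
  expect_equal(pixel_colocalization(c(1, 2, 3), c(1, 2, 3))$pearson_r, 1)
  expect_equal(pixel_colocalization(c(1, 2, 3), c(3, 2, 1))$pearson_r, -1)
  # oracle-computed value for the asymmetric case
  r <- pixel_colocalization(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$pearson_r, o_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)))
  expect_equal(r$pearson_r, 0.8)   # cov 4 / sqrt(5 * 5)
  z <- pixel_colocalization(c(2, 2, 2), c(1, 2, 3))
  expect_true(z$undefined)
  expect_error(pixel_colocalization(1:3, 1:4), "equal length")
  expect_error(pixel_colocalization(1:2, 1:2), "at least 3")
})

test_that("pearson r is invariant to affine rescaling of either channel", {
  set.seed(77)
  for (i in 1:25) {
    x <- rnorm(60); y <- 0.5 * x + rnorm(60)
    g <- runif(2, 0.1, 10); o <- runif(2, -5, 5)
    r0 <- pixel_colocalization(x, y)$pearson_r
    r1 <- pixel_colocalization(g[1] * x + o[1], g[2] * y + o[2])$pearson_r
    expect_equal(r0, r1, tolerance = 1e-9)
  }
})

test_that("group comparison matches the pooled-variance formula and stars", {
  g <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$t, 0)
  expect_equal(g$p, 1)
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  g2 <- compare_groups(a, b)
  o <- o_t_test(a, b)
  expect_equal(g2$t, o$t)
  expect_equal(g2$df, o$df)
  expect_equal(g2$p, o$p)
  expect_identical(condquant:::star_label(0.0005), "***")
  expect_identical(condquant:::star_label(0.005), "**")
  expect_identical(condquant:::star_label(0.03), "*")
  expect_identical(condquant:::star_label(0.2), "ns")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("mean Fano rises with puncta fraction and coloc contrast holds", {
  fractions <- c(0, 0.2, 0.4)
  means <- vapply(fractions, function(f) {
    pop <- simulate_population(
      scene_config(n_puncta = c(1L, 3L), puncta_fraction = f,
                   noise = "none", cell_intensity_sdlog = 0), 12,
      seed = 900 + round(100 * f))
    mean(vapply(pop, function(s)
      nucleus_pixel_stats(s$stack, channel = "gfp")$fano[1], 0), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(means) > 0))
  shared <- simulate_coloc_population(15, 0.75, seed = 41)
  indep <- simulate_coloc_population(15, 0.75, seed = 42, mode = "independent")
  r_sh <- mean(vapply(shared, function(x)
    pixel_colocalization(x$ch1, x$ch2)$pearson_r, 0))
  r_in <- mean(vapply(indep, function(x)
    pixel_colocalization(x$ch1, x$ch2)$pearson_r, 0))
  expect_gt(r_sh, r_in)
  expect_gt(r_sh, 0.6)
  expect_lt(abs(r_in), 0.2)
})
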