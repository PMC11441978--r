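make_stack <- function(arr) {
  image_stack(arr, pixel_size_um = 0.1,
              z_step_um = if (dim(arr)[1] > 1) 0.4 else NA,
              channel_names = paste0("ch", seq_len(dim(arr)[2])))
}

test_that("dot detection finds the brightest voxel with stated tie-breaks", {
  a <- array(0, dim = c(6, 1, 20, 20))
  a[3, 1, 10, 12] <- 100
  d <- detect_dot(make_stack(a), "ch1",
                  run_config(dot_sigma = 0.5, dot_min_prominence = 1))
  expect_equal(d$best_z, 3L)
  expect_equal(unname(d$center), c(10, 12))
  expect_true(d$pass)
  # equal peaks at z = 2 and z = 5: lowest z wins
  b <- array(0, dim = c(6, 1, 20, 20))
  b[2, 1, 8, 8] <- 50; b[5, 1, 8, 8] <- 50
  d2 <- detect_dot(make_stack(b), "ch1",
                   run_config(dot_sigma = 0.5, dot_min_prominence = 1))
  expect_equal(d2$best_z, 2L)
  # within-plane ties: row-major (smallest y, then x)
  cc <- array(0, dim = c(1, 1, 10, 10))
  cc[1, 1, 4, 7] <- 5; cc[1, 1, 6, 2] <- 5
  d3 <- detect_dot(make_stack(cc), "ch1",
                   run_config(dot_sigma = 1e-9, dot_min_prominence = 1))
  expect_equal(unname(d3$center), c(4, 7))
  # all-zero channel: no-dot failure
  d4 <- detect_dot(make_stack(array(0, dim = c(2, 1, 10, 10))), "ch1")
  expect_false(d4$pass)
  expect_true(is.na(d4$best_z))
})

test_that("dot detection lands within 1 px of ground truth on scenes", {
  for (seed in 1:6) {
    sc <- quiet_scene(seed = seed, n_z = 10L, dot_mode = "independent")
    d <- detect_dot(sc$stack, "mcherry")
    tr <- sc$truth$nuclei[[1]]$dot
    expect_true(d$pass)
    expect_lte(abs(d$best_z - tr$z), 1)
    expect_lt(sqrt((d$center[["y"]] - tr$y)^2 + (d$center[["x"]] - tr$x)^2), 1)
  }
})

test_that("same-z extraction and MIP behave as defined", {
  set.seed(31)
  a <- array(runif(5 * 2 * 12 * 9), dim = c(5, 2, 12, 9))
  s <- make_stack(a)
  # same-z equals direct indexing; out-of-range z errors
  for (z in c(1, 3, 5))
    expect_equal(extract_same_z(s, "ch2", z), matrix(a[z, 2, , ], 12))
  expect_error(extract_same_z(s, "ch1", 6), "out of range")
  expect_error(extract_same_z(s, "ch1", 0), "out of range")
  # single-plane stack returns its only plane
  s1 <- make_stack(array(a[1, , , , drop = FALSE], dim = c(1, 2, 12, 9)))
  expect_equal(extract_same_z(s1, "ch1", 1), matrix(a[1, 1, , ], 12))
  # MIP equals the brute-force per-pixel max and dominates every plane
  m <- extract_mip(s, "ch1")
  expect_equal(m, o_mip(a, 1))
  for (z in 1:5) expect_true(all(m >= extract_same_z(s, "ch1", z)))
  # monotone-in-z stack: MIP is the top plane
  b <- array(0, dim = c(4, 1, 6, 6))
  for (z in 1:4) b[z, 1, , ] <- z
  expect_true(all(extract_mip(make_stack(b), "ch1") == 4))
})

test_that("alignment and averaging match the pad-and-mask oracle", {
  # one interior center: output is the plain cropped window
  img <- matrix(seq_len(30 * 30), 30, 30)
  av <- align_and_average(list(img), rbind(c(15, 15)), w = 4)
  expect_equal(av$average, img[11:19, 11:19])
  expect_true(all(av$count == 1))
  # two delta images aligned on their own deltas: all mass at offset (0,0)
  i1 <- matrix(0, 20, 20); i1[5, 7] <- 3
  i2 <- matrix(0, 20, 20); i2[12, 12] <- 5
  av2 <- align_and_average(list(i1, i2), rbind(c(5, 7), c(12, 12)), w = 3)
  expect_equal(av2$average[4, 4], 4)
  expect_equal(sum(av2$average != 0), 1L)
  # centers near the border: reduced counts, matching the oracle
  set.seed(91)
  imgs <- lapply(1:6, function(i) matrix(runif(18 * 22), 18, 22))
  ctrs <- cbind(sample(c(2, 3, 16), 6, TRUE), sample(c(3, 11, 20), 6, TRUE))
  av3 <- align_and_average(imgs, ctrs, w = 5)
  o <- o_align(imgs, ctrs, 5)
  expect_equal(av3$count, o$count)
  expect_equal(av3$average, o$average)
  expect_error(align_and_average(list(), matrix(0, 0, 2), 3), "empty")
  expect_error(align_and_average(list(i1), rbind(c(100, 100)), 3),
               "outside")
})

test_that("line profiles cut the center row/column with correct layout", {
  set.seed(17)
  imgs <- lapply(1:5, function(i) matrix(runif(40 * 40), 40, 40))
  ctrs <- cbind(sample(15:25, 5, TRUE), sample(15:25, 5, TRUE))
  av <- align_and_average(imgs, ctrs, w = 6, pixel_size_um = 0.1)
  pr <- line_profile(av)
  expect_equal(nrow(pr), 13L)
  expect_equal(pr$offset_px, -6:6)
  expect_equal(pr$offset_um, (-6:6) * 0.1)
  expect_equal(pr$mean, av$average[7, ])
  prv <- line_profile(av, "vertical")
  expect_equal(prv$mean, av$average[, 7])
  # profiling the average commutes with averaging per-cell profiles
  per_cell_rows <- t(vapply(1:5, function(i) av$windows[i, 7, ], numeric(13)))
  expect_equal(pr$mean, colMeans(per_cell_rows, na.rm = TRUE))
  # uniform field: flat profile; single central peak: maximum at offset 0
  flat <- align_and_average(list(matrix(2, 30, 30)), rbind(c(15, 15)), w = 4)
  expect_true(all(line_profile(flat)$mean == 2))
  peaked <- align_and_average(list(i1 <- {m <- matrix(0, 30, 30); m[15, 15] <- 9; m}),
                              rbind(c(15, 15)), w = 4)
  ppr <- line_profile(peaked)
  expect_equal(which.max(ppr$mean), 5L)
})

test_that("coupled-dot populations are center-enriched; matched ones are not", {
  run_cond <- function(mode, n, seed) {
    cfg <- scene_config(n_z = 6L, dot_mode = mode, n_puncta = c(1L, 3L),
                        puncta_fraction = 0.4, cell_intensity_sdlog = 0)
    pop <- simulate_population(cfg, n, seed = seed)
    dets <- lapply(pop, function(s) detect_dot(s$stack, "mcherry"))
    keep <- vapply(dets, function(d) d$pass, TRUE)
    align_and_average(lapply(pop[keep], function(s) extract_mip(s$stack, "gfp")),
                      t(vapply(dets[keep], function(d) d$center, numeric(2))),
                      w = 10)
  }
  ac <- run_cond("coupled", 25, 61)
  ai <- run_cond("independent", 25, 62)
  g <- center_enrichment(center_values(ac), center_values(ai))
  expect_gt(g$means[["a"]], g$means[["b"]])
  expect_lt(g$p, 0.01)
  # matched conditions: no systematic enrichment
  a1 <- run_cond("independent", 25, 63)
  a2 <- run_cond("independent", 25, 64)
  g0 <- center_enrichment(center_values(a1), center_values(a2))
  expect_gt(g0$p, 0.01)
  expect_error(center_enrichment(1, 2), "at least 2")
})
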