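test_that("a zero-puncta noise-free nucleus is uniform away from its rim", {
  # a 4 px margin puts the interior > 4 PSF sigmas inside the rim
  sc <- quiet_scene(seed = 2, n_puncta = 0L, puncta_fraction = 0,
                    interior_margin_px = 4)
  nuc <- sc$truth$nuclei[[1]]
  vals <- get_plane(sc$stack, "gfp", 1)[nuc$interior]
  expect_gt(length(vals), 100)
  # interior pixels sit within 1% of the plateau (PSF edge roll-off excluded)
  expect_lt(diff(range(vals)) / mean(vals), 0.01)
  # and exactly constant with the PSF disabled
  sc0 <- quiet_scene(seed = 2, n_puncta = 0L, puncta_fraction = 0,
                     psf_sigma_px = 0)
  v0 <- get_plane(sc0$stack, "gfp", 1)[sc0$truth$nuclei[[1]]$mask]
  expect_equal(diff(range(v0)), 0)
})

test_that("noise-free images conserve the configured photon totals", {
  for (seed in 1:3) {
    sc <- quiet_scene(seed = seed, n_puncta = c(1L, 5L), puncta_fraction = 0.4,
                      dot_mode = "coupled")
    tot1 <- sum(sc$stack$pixels[, 1, , ])
    tot2 <- sum(sc$stack$pixels[, 2, , ])
    expect_equal(tot1, sc$truth$nuclei[[1]]$photons[["ch1"]],
                 tolerance = 0.01)
    expect_equal(tot2, sc$truth$nuclei[[1]]$photons[["ch2"]],
                 tolerance = 0.01)
  }
})

test_that("a single punctum carries its configured intensity fraction", {
  # fraction 0.5 in one punctum: puncta-attributable photons / total = 0.5.
  # The punctum share is isolated by subtracting the zero-puncta expected
  # image at matched diffuse level (the generative model is additive).
  sc <- quiet_scene(seed = 4, n_puncta = 1L, puncta_fraction = 0.5)
  sc0 <- quiet_scene(seed = 4, n_puncta = 0L, puncta_fraction = 0)
  img <- get_plane(sc$stack, "gfp", 1)
  img0 <- get_plane(sc0$stack, "gfp", 1)   # same placement stream: same nucleus
  pun <- sc$truth$nuclei[[1]]$puncta
  excess <- img - 0.5 * img0               # diffuse part of sc is 0.5 * N
  sig_eff <- sqrt(pun$sigma_px[1]^2 + 1^2) # punctum sigma + PSF sigma
  dy2 <- (seq_len(nrow(img)) - pun$y[1])^2
  dx2 <- (seq_len(ncol(img)) - pun$x[1])^2
  region <- outer(dy2, dx2, "+") <= (4 * sig_eff)^2
  tot <- sum(img)
  expect_equal(sum(excess[region]) / tot, 0.5, tolerance = 0.02)
})

test_that("seeded simulation is reproducible and seeds differ", {
  cfg <- scene_config(noise = "poisson")
  a <- simulate_nucleus_scene(cfg, seed = 7)
  b <- simulate_nucleus_scene(cfg, seed = 7)
  c <- simulate_nucleus_scene(cfg, seed = 8)
  expect_identical(a$stack$pixels, b$stack$pixels)
  expect_false(identical(a$stack$pixels, c$stack$pixels))
  p1 <- simulate_population(cfg, 4, seed = 11)
  p2 <- simulate_population(cfg, 4, seed = 11)
  expect_identical(lapply(p1, function(s) s$stack$pixels),
                   lapply(p2, function(s) s$stack$pixels))
})

test_that("population size is respected and degenerate inputs error", {
  expect_error(simulate_population(scene_config(), 0, seed = 1), "n_cells")
  pop <- simulate_population(scene_config(), 65, seed = 1)
  expect_length(pop, 65)
  expect_error(scene_config(photons = 0), "zero nuclear intensity")
  # nuclei that cannot fit are reported, not silently dropped
  expect_error(
    simulate_nucleus_scene(scene_config(img_size = c(40L, 40L), n_nuclei = 8L),
                           seed = 1),
    "placed|too small")
})

test_that("scene truth respects its geometric invariants", {
  for (seed in 1:5) {
    sc <- quiet_scene(seed = seed, n_puncta = c(1L, 5L), puncta_fraction = 0.6,
                      dot_mode = "coupled", n_z = 5L)
    nuc <- sc$truth$nuclei[[1]]
    expect_lte(sum(nuc$puncta$fraction), 1)
    d <- sqrt((nuc$puncta$y - nuc$center[["y"]])^2 +
              (nuc$puncta$x - nuc$center[["x"]])^2)
    expect_true(all(d <= nuc$radius_px))
    expect_true(nuc$dot$z >= 1 && nuc$dot$z <= 5)
  }
})

test_that("FRAP series match the closed-form recovery", {
  tr <- frap_truth(half_time_s = 60, plateau_pct = 80, bleach_depth_pct = 20,
                   noise_sd_pct = 0)
  ser <- simulate_frap(tr)
  # frame layout: 3 pre-bleach + 270/3 post-bleach frames
  expect_length(ser$raw, 3 + 90)
  expect_equal(ser$bleach_index, 4L)
  expect_equal(ser$normalized[1:3], rep(100, 3))
  expect_equal(ser$normalized[4], 20)          # bleach frame = depth
  # at t = half_time the curve is exactly midway between depth and plateau
  i60 <- ser$bleach_index + 60 / 3
  expect_equal(ser$normalized[i60], (20 + 80) / 2)
  # the last frame (t = 267 s) matches the closed form exactly
  expect_equal(tail(ser$normalized, 1),
               20 + 60 * (1 - 2^(-267 / 60)))
  expect_error(frap_truth(half_time_s = -1), "half_time")
  expect_error(frap_truth(bleach_depth_pct = 90, plateau_pct = 80),
               "bleach_depth")
})

test_that("droplet fields realize their configured partition ratios", {
  # ratio 1 in channel 2, noise off: channel 2 is constant
  dd <- simulate_droplet_field(
    droplet_config(partition_ratios = c(5, 1), noise = "none"), seed = 3)
  ch2 <- get_plane(dd$stack, "gfp", 1)
  expect_lt(diff(range(ch2)) / mean(ch2), 1e-6)
  # one droplet, ratio 5, noise and PSF off: in/out mean ratio is exactly 5
  d1 <- simulate_droplet_field(
    droplet_config(n_droplets = 1L, partition_ratios = c(5, 5),
                   noise = "none", psf_sigma_px = 0), seed = 4)
  img <- get_plane(d1$stack, "mcherry", 1)
  m <- disk_in <- img == max(img)
  expect_equal(mean(img[disk_in]) / mean(img[!disk_in]), 5)
  # seeded rerun identical
  expect_identical(simulate_droplet_field(droplet_config(), seed = 5)$stack$pixels,
                   simulate_droplet_field(droplet_config(), seed = 5)$stack$pixels)
  expect_error(droplet_config(radius_px = c(1, 3)), "radii")
  expect_error(droplet_config(partition_ratios = c(-1, 2)), "ratios")
})
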