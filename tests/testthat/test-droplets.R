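test_that("droplet segmentation recovers counts and diameters", {
  dd <- simulate_droplet_field(droplet_config(noise = "none"), seed = 2)
  ds <- segment_droplets(dd$stack, "mcherry")
  expect_equal(nrow(ds$table), length(dd$truth$radii_px))
  est <- sort(ds$table$equiv_diameter_px)
  tru <- sort(2 * dd$truth$radii_px)
  expect_true(all(abs(est - tru) / tru < 0.15))
  # droplet and dilute masks are disjoint, with a guard band between them
  expect_false(any(ds$droplet_mask & ds$dilute_mask))
  expect_gt(sum(!ds$droplet_mask & !ds$dilute_mask), 0)
})

test_that("uniform images give zero droplets; merged truth gives one object", {
  flat <- image_stack(matrix(10, 64, 64), 0.1, channel_names = "mcherry")
  expect_equal(nrow(segment_droplets(flat, "mcherry")$table), 0L)
  # two overlapping disks are labeled as a single droplet (no splitting)
  img <- matrix(5, 80, 80)
  img[condquant:::disk_mask(80, 80, 40, 36, 6)] <- 50
  img[condquant:::disk_mask(80, 80, 40, 44, 6)] <- 50
  s <- image_stack(img, 0.1, channel_names = "mcherry")
  expect_equal(nrow(segment_droplets(s, "mcherry")$table), 1L)
})

test_that("partition coefficients recover generative ratios", {
  # constructed case: droplet mean 10, dilute 2 -> ratio 5
  img <- matrix(2, 64, 64)
  img[condquant:::disk_mask(64, 64, 32, 32, 6)] <- 10
  s <- image_stack(img, 0.1, channel_names = "mcherry")
  ds <- segment_droplets(s, "mcherry")
  pc <- partition_coefficient(ds)
  expect_equal(pc$pooled_ratio, 5, tolerance = 1e-6)
  # uniform channel measured over a segmentation from another channel: ratio 1
  px2 <- array(0, dim = c(1, 2, 64, 64))
  px2[1, 1, , ] <- img
  px2[1, 2, , ] <- 7
  s2 <- image_stack(px2, 0.1, channel_names = c("mcherry", "gfp"))
  ds2 <- segment_droplets(s2, "mcherry")
  expect_equal(partition_coefficient(ds2, "gfp")$pooled_ratio, 1)
  # simulated fields under Poisson noise: pooled estimate within 10%
  for (seed in 1:3) {
    dd <- simulate_droplet_field(droplet_config(), seed = seed)
    ds3 <- segment_droplets(dd$stack, "mcherry")
    est <- partition_coefficient(ds3, "gfp")$pooled_ratio
    expect_equal(est, dd$truth$partition_ratios[["gfp"]], tolerance = 0.10)
  }
})

test_that("partition coefficient is invariant to global intensity scaling", {
  dd <- simulate_droplet_field(droplet_config(noise = "none"), seed = 9)
  ds <- segment_droplets(dd$stack, "mcherry")
  p1 <- partition_coefficient(ds, "gfp")$pooled_ratio
  scaled <- dd$stack
  scaled$pixels <- scaled$pixels * 12.5
  ds2 <- segment_droplets(scaled, "mcherry")
  p2 <- partition_coefficient(ds2, "gfp")$pooled_ratio
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("droplet overlap fractions are symmetric, bounded and exact", {
  dd <- simulate_droplet_field(droplet_config(noise = "none"), seed = 4)
  ds <- segment_droplets(dd$stack, "mcherry")
  self <- droplet_colocalization(ds, ds)
  expect_equal(self$a_in_b, 1)
  expect_equal(self$b_in_a, 1)
  # disjoint constructed sets
  imgA <- matrix(1, 60, 60); imgA[condquant:::disk_mask(60, 60, 15, 15, 5)] <- 20
  imgB <- matrix(1, 60, 60); imgB[condquant:::disk_mask(60, 60, 45, 45, 5)] <- 20
  dA <- segment_droplets(image_stack(imgA, 0.1, channel_names = "a"), "a")
  dB <- segment_droplets(image_stack(imgB, 0.1, channel_names = "b"), "b")
  dis <- droplet_colocalization(dA, dB)
  expect_equal(dis$a_in_b, 0)
  expect_equal(dis$b_in_a, 0)
  # half-overlapping droplets match a brute-force pixel intersection
  imgC <- matrix(1, 60, 60); imgC[condquant:::disk_mask(60, 60, 30, 28, 6)] <- 20
  imgD <- matrix(1, 60, 60); imgD[condquant:::disk_mask(60, 60, 30, 36, 6)] <- 20
  dC <- segment_droplets(image_stack(imgC, 0.1, channel_names = "c"), "c")
  dD <- segment_droplets(image_stack(imgD, 0.1, channel_names = "d"), "d")
  ov <- droplet_colocalization(dC, dD)
  inter <- sum(dC$droplet_mask & dD$droplet_mask)
  expect_equal(ov$a_in_b, inter / sum(dC$droplet_mask))
  expect_equal(ov$b_in_a, inter / sum(dD$droplet_mask))
  expect_true(ov$a_in_b >= 0 && ov$a_in_b <= 1)
  # geometry mismatch is rejected
  small <- segment_droplets(image_stack(matrix(1, 30, 30), 0.1,
                                        channel_names = "x"), "x")
  expect_error(droplet_colocalization(dA, small), "geometry mismatch")
})

test_that("partition-ratio ordering is preserved across conditions", {
  # full-length vs truncated client: true ratios 5 vs 2 in the client channel
  pooled <- function(ratio, seed) {
    dd <- simulate_droplet_field(
      droplet_config(partition_ratios = c(5, ratio)), seed = seed)
    ds <- segment_droplets(dd$stack, "mcherry")
    partition_coefficient(ds, "gfp")$per_droplet$partition_ratio
  }
  full <- unlist(lapply(1:3, function(s) pooled(5, s)))
  redu <- unlist(lapply(1:3, function(s) pooled(2, 10 + s)))
  expect_gte(length(full), 30 - 5)
  # bootstrap intervals of the condition means do not overlap
  set.seed(123)
  bs <- function(x) quantile(replicate(500, mean(sample(x, replace = TRUE))),
                             c(0.025, 0.975))
  expect_gt(bs(full)[1], bs(redu)[2])
})
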