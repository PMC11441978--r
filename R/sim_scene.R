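#' Configuration for synthetic nuclear scenes
#'
#' Parameters of the generative model behind \code{\link{simulate_nucleus_scene}}.
#' A scene holds one or more yeast nuclei (circles in 2D, spheres sampled at
#' z planes in 3D mode) carrying a diffuse nuclear signal plus a configurable
#' fraction of total intensity concentrated in Gaussian-profile puncta, an
#' optional diffraction-limited chromatin dot in a second channel (a
#' tetO/tetR-type locus tag), Gaussian PSF blur, and Poisson/Gaussian camera
#' noise.
#'
#' Defaults follow the imaging geometry of yeast condensate studies: 2.0 um
#' nucleus diameter at 0.1 um/pixel, 0.4 um z step, 10-plane stacks in 3D
#' mode; puncta counts/sizes (1--5 puncta, 2--4 px radius) are fixture
#' choices. "Intensity fraction" is the fraction of total nuclear photons
#' assigned to puncta; it maps monotonically onto the downstream Fano
#' number.
#'
#' @param img_size image size in pixels, \code{c(ny, nx)}.
#' @param n_nuclei nuclei per scene.
#' @param nucleus_diameter_um nucleus diameter (um).
#' @param pixel_size_um pixel size (um).
#' @param n_z number of z planes (1 = single-plane 2D mode).
#' @param z_step_um z spacing (um); planes are centered on the nucleus.
#' @param photons expected total nuclear photons per cell in channel 1.
#' @param n_puncta puncta per nucleus: a scalar, or \code{c(min, max)} to
#'   draw uniformly.
#' @param puncta_fraction total intensity fraction carried by puncta
#'   (in [0, 1]); split among puncta by normalized Gamma(1) weights.
#' @param puncta_radius_px per-punctum radius range (px); the Gaussian blob
#'   sigma is radius/2.
#' @param puncta_sigma_z_um axial sigma of a punctum (um, 3D mode).
#' @param dot_mode chromatin dot in channel 2: \code{"none"},
#'   \code{"coupled"} (placed at a punctum center) or \code{"independent"}
#'   (uniform in the nucleus).
#' @param photons_ch2 expected total channel-2 photons per cell.
#' @param dot_fraction fraction of channel-2 photons in the dot (rest is
#'   diffuse nucleoplasmic signal).
#' @param dot_sigma_px lateral sigma of the diffraction-limited dot (px).
#' @param dot_sigma_z_um axial sigma of the dot (um).
#' @param psf_sigma_px Gaussian PSF sigma applied to every plane (px);
#'   0 disables blur.
#' @param noise \code{"poisson"} (photon shot noise, pixel units are
#'   photons) or \code{"none"}.
#' @param read_noise_sd additive Gaussian read noise SD (photons); results
#'   are clamped at 0.
#' @param cell_intensity_sdlog sdlog of the lognormal cell-to-cell total
#'   intensity multiplier (mean 1); 0 disables.
#' @param interior_margin_px margin used for the truth interior mask (the
#'   nucleus disk shrunk by this many pixels), matching the analysis-side
#'   interior erosion.
#' @param min_separation_px minimum gap between nucleus rims.
#' @param max_place_tries placement retries before giving up.
#' @return an object of class \code{scene_config}.
#' @export
scene_config <- function(img_size = c(64L, 64L), n_nuclei = 1L,
                         nucleus_diameter_um = 2.0, pixel_size_um = 0.1,
                         n_z = 1L, z_step_um = 0.4,
                         photons = 20000,
                         n_puncta = c(1L, 5L), puncta_fraction = 0.4,
                         puncta_radius_px = c(2, 4), puncta_sigma_z_um = 0.3,
                         dot_mode = c("none", "coupled", "independent"),
                         photons_ch2 = 8000, dot_fraction = 0.7,
                         dot_sigma_px = 1, dot_sigma_z_um = 0.2,
                         psf_sigma_px = 1,
                         noise = c("poisson", "none"), read_noise_sd = 0,
                         cell_intensity_sdlog = 0.1,
                         interior_margin_px = 2,
                         min_separation_px = 3, max_place_tries = 500L) {
  cfg <- structure(list(
    img_size = as.integer(img_size), n_nuclei = as.integer(n_nuclei),
    nucleus_diameter_um = nucleus_diameter_um, pixel_size_um = pixel_size_um,
    n_z = as.integer(n_z), z_step_um = z_step_um,
    photons = photons,
    n_puncta = as.integer(n_puncta), puncta_fraction = puncta_fraction,
    puncta_radius_px = puncta_radius_px, puncta_sigma_z_um = puncta_sigma_z_um,
    dot_mode = match.arg(dot_mode),
    photons_ch2 = photons_ch2, dot_fraction = dot_fraction,
    dot_sigma_px = dot_sigma_px, dot_sigma_z_um = dot_sigma_z_um,
    psf_sigma_px = psf_sigma_px,
    noise = match.arg(noise), read_noise_sd = read_noise_sd,
    cell_intensity_sdlog = cell_intensity_sdlog,
    interior_margin_px = interior_margin_px,
    min_separation_px = min_separation_px,
    max_place_tries = as.integer(max_place_tries)), class = "scene_config")
  validate_scene_config(cfg)
  cfg
}

#' @rdname scene_config
#' @param cfg a \code{scene_config}.
#' @export
validate_scene_config <- function(cfg) {
  stopifnot(length(cfg$img_size) == 2L, all(cfg$img_size >= 16L),
            cfg$n_nuclei >= 1L, cfg$nucleus_diameter_um > 0,
            cfg$pixel_size_um > 0, cfg$n_z >= 1L)
  if (cfg$n_z > 1L && cfg$z_step_um <= 0) stop("z_step_um must be > 0")
  if (cfg$photons <= 0) stop("zero nuclear intensity: 'photons' must be > 0")
  if (cfg$puncta_fraction < 0 || cfg$puncta_fraction > 1)
    stop("puncta_fraction must be in [0, 1]")
  if (any(cfg$n_puncta < 0)) stop("n_puncta must be >= 0")
  if (cfg$dot_mode != "none" && cfg$photons_ch2 <= 0)
    stop("zero nuclear intensity: 'photons_ch2' must be > 0")
  if (cfg$dot_fraction < 0 || cfg$dot_fraction > 1)
    stop("dot_fraction must be in [0, 1]")
  if (cfg$psf_sigma_px < 0 || cfg$read_noise_sd < 0 ||
      cfg$cell_intensity_sdlog < 0)
    stop("sigmas and noise SDs must be >= 0")
  invisible(cfg)
}

# 2D Gaussian kernel over the full image grid, normalized to sum 1 so that
# photon totals are conserved exactly.
gauss2d <- function(ny, nx, cy, cx, sigma) {
  gy <- exp(-((seq_len(ny) - cy)^2) / (2 * sigma^2))
  gx <- exp(-((seq_len(nx) - cx)^2) / (2 * sigma^2))
  k <- gy %o% gx
  k / sum(k)
}

disk_mask <- function(ny, nx, cy, cx, r) {
  dy2 <- (seq_len(ny) - cy)^2
  dx2 <- (seq_len(nx) - cx)^2
  outer(dy2, dx2, "+") <= r^2
}

# uniform point in a 3D ball of radius r (z collapsed to 0 when flat = TRUE)
runif_ball <- function(r, flat = FALSE) {
  repeat {
    p <- runif(3L, -1, 1)
    if (flat) p[3L] <- 0
    if (sum(p^2) <= 1) return(p * r)
  }
}

place_centers <- function(n, ny, nx, r_px, min_sep, max_tries) {
  margin <- r_px + 3
  if (2 * margin >= min(ny, nx) && n >= 1L)
    stop("image too small to hold the requested nuclei")
  centers <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      cand <- c(runif(1, margin, ny - margin), runif(1, margin, nx - margin))
      if (i == 1L || all(sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                                       matrix(cand, i - 1L, 2L, byrow = TRUE))^2)) >=
                         2 * r_px + min_sep)) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("nuclei cannot be placed without overlap after bounded retries")
  }
  centers
}

# Core scene generator. Consumes the current RNG stream (callers seed it),
# so populations advance one stream deterministically across cells.
simulate_scene_ <- function(cfg) {
  ny <- cfg$img_size[1L]; nx <- cfg$img_size[2L]
  nz <- cfg$n_z
  r_px <- cfg$nucleus_diameter_um / 2 / cfg$pixel_size_um
  r_um <- cfg$nucleus_diameter_um / 2
  two_ch <- cfg$dot_mode != "none"
  nc <- if (two_ch) 2L else 1L
  zpos <- if (nz > 1L) (seq_len(nz) - (nz + 1) / 2) * cfg$z_step_um else 0

  centers <- place_centers(cfg$n_nuclei, ny, nx, r_px,
                           cfg$min_separation_px, cfg$max_place_tries)
  expected <- array(0, dim = c(nz, nc, ny, nx))
  nuclei <- vector("list", cfg$n_nuclei)

  # per-plane diffuse weights: sphere cross-section areas
  wz <- pmax(0, r_um^2 - zpos^2)
  if (all(wz == 0)) wz[which.min(abs(zpos))] <- 1
  wz <- wz / sum(wz)
  plane_r_px <- sqrt(pmax(0, r_um^2 - zpos^2)) / cfg$pixel_size_um

  for (i in seq_len(cfg$n_nuclei)) {
    cy <- centers[i, 1L]; cx <- centers[i, 2L]
    mult <- if (cfg$cell_intensity_sdlog > 0)
      rlnorm(1, -cfg$cell_intensity_sdlog^2 / 2, cfg$cell_intensity_sdlog) else 1
    n1 <- cfg$photons * mult

    npun <- if (length(cfg$n_puncta) == 2L && cfg$n_puncta[1L] != cfg$n_puncta[2L])
      sample(seq.int(cfg$n_puncta[1L], cfg$n_puncta[2L]), 1L) else cfg$n_puncta[1L]
    f_tot <- if (npun > 0L) cfg$puncta_fraction else 0
    puncta <- NULL
    if (npun > 0L && f_tot > 0) {
      w <- rgamma(npun, 1)
      fr <- f_tot * w / sum(w)
      pos <- t(vapply(seq_len(npun), function(j)
        runif_ball(0.7 * r_um, flat = (nz == 1L)), numeric(3L)))
      puncta <- data.frame(
        y = cy + pos[, 1L] / cfg$pixel_size_um,
        x = cx + pos[, 2L] / cfg$pixel_size_um,
        z_um = pos[, 3L],
        sigma_px = runif(npun, cfg$puncta_radius_px[1L],
                         cfg$puncta_radius_px[2L]) / 2,
        fraction = fr)
    }

    # channel 1: diffuse + puncta
    f_eff <- if (is.null(puncta)) 0 else sum(puncta$fraction)
    for (zi in seq_len(nz)) {
      if (wz[zi] > 0 && plane_r_px[zi] > 0) {
        m <- disk_mask(ny, nx, cy, cx, plane_r_px[zi])
        expected[zi, 1L, , ] <- expected[zi, 1L, , ] +
          (1 - f_eff) * n1 * wz[zi] * m / sum(m)
      }
    }
    if (!is.null(puncta)) {
      for (j in seq_len(nrow(puncta))) {
        k2 <- gauss2d(ny, nx, puncta$y[j], puncta$x[j], puncta$sigma_px[j])
        zw <- if (nz > 1L) {
          u <- exp(-(zpos - puncta$z_um[j])^2 / (2 * cfg$puncta_sigma_z_um^2))
          u / sum(u)
        } else 1
        for (zi in seq_len(nz))
          expected[zi, 1L, , ] <- expected[zi, 1L, , ] +
            puncta$fraction[j] * n1 * zw[zi] * k2
      }
    }

    # channel 2: locus dot + diffuse nucleoplasmic signal
    dot <- NULL
    if (two_ch) {
      n2 <- cfg$photons_ch2 * mult
      if (cfg$dot_mode == "coupled" && !is.null(puncta)) {
        j <- sample(nrow(puncta), 1L)
        dot_yxz <- c(puncta$y[j], puncta$x[j], puncta$z_um[j])
      } else {
        p <- runif_ball(0.7 * r_um, flat = (nz == 1L))
        dot_yxz <- c(cy + p[1L] / cfg$pixel_size_um,
                     cx + p[2L] / cfg$pixel_size_um, p[3L])
      }
      for (zi in seq_len(nz)) {
        if (wz[zi] > 0 && plane_r_px[zi] > 0) {
          m <- disk_mask(ny, nx, cy, cx, plane_r_px[zi])
          expected[zi, 2L, , ] <- expected[zi, 2L, , ] +
            (1 - cfg$dot_fraction) * n2 * wz[zi] * m / sum(m)
        }
      }
      kd <- gauss2d(ny, nx, dot_yxz[1L], dot_yxz[2L], cfg$dot_sigma_px)
      zw <- if (nz > 1L) {
        u <- exp(-(zpos - dot_yxz[3L])^2 / (2 * cfg$dot_sigma_z_um^2))
        u / sum(u)
      } else 1
      for (zi in seq_len(nz))
        expected[zi, 2L, , ] <- expected[zi, 2L, , ] +
          cfg$dot_fraction * n2 * zw[zi] * kd
      dot <- list(z = if (nz > 1L) which.min(abs(zpos - dot_yxz[3L])) else 1L,
                  y = dot_yxz[1L], x = dot_yxz[2L], z_um = dot_yxz[3L])
    }

    nuclei[[i]] <- list(
      center = c(y = cy, x = cx), radius_px = r_px,
      mask = disk_mask(ny, nx, cy, cx, r_px),
      interior = disk_mask(ny, nx, cy, cx,
                           max(1, r_px - cfg$interior_margin_px)),
      puncta = puncta, dot = dot,
      coupled = identical(cfg$dot_mode, "coupled"),
      photons = c(ch1 = n1,
                  ch2 = if (two_ch) cfg$photons_ch2 * mult else NA_real_),
      intensity_multiplier = mult)
  }

  # PSF blur per plane, then camera noise
  if (cfg$psf_sigma_px > 0) {
    for (zi in seq_len(nz)) for (ci in seq_len(nc))
      expected[zi, ci, , ] <- EBImage::gblur(
        matrix(expected[zi, ci, , ], ny), sigma = cfg$psf_sigma_px)
    expected[expected < 0] <- 0   # gblur ringing guard (negligible)
  }
  pixels <- expected
  if (cfg$noise == "poisson")
    pixels <- array(rpois(length(pixels), pixels), dim = dim(pixels))
  if (cfg$read_noise_sd > 0)
    pixels <- pmax(0, pixels + array(rnorm(length(pixels), 0,
                                           cfg$read_noise_sd),
                                     dim = dim(pixels)))

  ch_names <- if (two_ch) c("gfp", "mcherry") else "gfp"
  stack <- image_stack(pixels, cfg$pixel_size_um,
                       if (nz > 1L) cfg$z_step_um else NA_real_, ch_names)
  truth <- structure(list(nuclei = nuclei, expected = expected,
                          config = cfg), class = "scene_truth")
  validate_scene_truth(truth)
  list(stack = stack, truth = truth)
}

#' Simulate a nuclear scene with known ground truth
#'
#' Generates one image stack under the generative model of
#' \code{\link{scene_config}}: per cell, diffuse nuclear intensity plus
#' Gaussian-profile puncta carrying the stated intensity fractions (and an
#' optional channel-2 locus dot), convolved with a Gaussian PSF, then
#' Poisson photon noise and/or additive Gaussian read noise. Identical
#' \code{(config, seed)} pairs give identical stacks.
#'
#' @param config a \code{\link{scene_config}}.
#' @param seed integer seed.
#' @return a list with elements \code{stack} (an \code{\link{image_stack}})
#'   and \code{truth} (a \code{scene_truth}: per-nucleus centers, radii,
#'   masks, interior masks, puncta table, dot position, photon totals, plus
#'   the noise-free expected image and the config).
#' @export
simulate_nucleus_scene <- function(config = scene_config(), seed = 1L) {
  validate_scene_config(config)
  set.seed(seed)
  out <- simulate_scene_(config)
  out$truth$seed <- seed
  out
}

#' @rdname simulate_nucleus_scene
#' @param x a \code{scene_truth}.
#' @export
validate_scene_truth <- function(x) {
  for (nuc in x$nuclei) {
    if (!is.null(nuc$puncta)) {
      fr <- nuc$puncta$fraction
      if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-9)
        stop("puncta intensity fractions must lie in [0, 1] and sum <= 1")
      d <- sqrt((nuc$puncta$y - nuc$center["y"])^2 +
                (nuc$puncta$x - nuc$center["x"])^2)
      if (any(d > nuc$radius_px + 1e-9))
        stop("puncta centers must lie inside their nucleus")
    }
    if (!is.null(nuc$dot)) {
      d <- sqrt((nuc$dot$y - nuc$center["y"])^2 +
                (nuc$dot$x - nuc$center["x"])^2)
      if (d > nuc$radius_px + 1e-9)
        stop("dot position must lie inside the nucleus")
    }
  }
  invisible(x)
}

#' Simulate a population of independent scenes
#'
#' Draws \code{n_cells} scenes from one seeded random stream; the cell index
#' advances the stream deterministically, so a fixed \code{(config, n_cells,
#' seed)} triple is bit-reproducible. Cell-level total intensity varies
#' lognormally per \code{cell_intensity_sdlog}.
#'
#' @param config a \code{\link{scene_config}}.
#' @param n_cells number of cells (>= 1).
#' @param seed integer seed.
#' @return a list of \code{n_cells} scene lists (\code{stack}, \code{truth}).
#' @export
simulate_population <- function(config = scene_config(), n_cells, seed = 1L) {
  validate_scene_config(config)
  if (!is.numeric(n_cells) || n_cells < 1)
    stop("n_cells must be >= 1")
  set.seed(seed)
  lapply(seq_len(n_cells), function(i) simulate_scene_(config))
}

#' Simulate two-channel nuclei with an analytically set pixel correlation
#'
#' Builds per-cell pixel-value pairs for co-localization validation: both
#' channels share one punctate spatial signal (the noise-free channel-1
#' scene over the nucleus interior) plus independent Gaussian noise whose
#' variance is solved per cell so the theoretical Pearson correlation equals
#' \code{target_r}: for equal noise in both channels,
#' r = var(S) / (var(S) + sigma_n^2), hence
#' sigma_n = sd(S) * sqrt(1/r - 1). In \code{"independent"} mode channel 2
#' uses its own independently drawn spatial signal (theoretical r = 0),
#' giving the negative-control contrast.
#'
#' @param n_cells number of cells.
#' @param target_r target pixel correlation in (0, 1].
#' @param config a \code{\link{scene_config}}; noise is forced off and
#'   puncta must carry a positive intensity fraction.
#' @param seed integer seed.
#' @param mode \code{"shared"} or \code{"independent"} spatial signal.
#' @return a list of per-cell lists with elements \code{ch1}, \code{ch2}
#'   (equal-length pixel vectors) and \code{n}.
#' @export
simulate_coloc_population <- function(n_cells, target_r = 0.75,
                                      config = scene_config(noise = "none"),
                                      seed = 1L,
                                      mode = c("shared", "independent")) {
  mode <- match.arg(mode)
  if (target_r <= 0 || target_r > 1) stop("target_r must be in (0, 1]")
  config$noise <- "none"; config$read_noise_sd <- 0
  if (config$puncta_fraction <= 0 || all(config$n_puncta == 0L))
    stop("coloc simulation needs a punctate signal (puncta_fraction > 0)")
  validate_scene_config(config)
  set.seed(seed)
  sig_n <- function(s, r) if (r >= 1) 0 else sd(s) * sqrt(1 / r - 1)
  lapply(seq_len(n_cells), function(i) {
    sc <- simulate_scene_(config)
    nuc <- sc$truth$nuclei[[1L]]
    s1 <- matrix(sc$truth$expected[1L, 1L, , ],
                 nrow = dim(sc$truth$expected)[3L])[nuc$interior]
    sn <- sig_n(s1, target_r)
    ch1 <- s1 + rnorm(length(s1), 0, sn)
    if (mode == "shared") {
      ch2 <- s1 + rnorm(length(s1), 0, sn)
    } else {
      # unrelated spatial signal: its own scene, its own nucleus interior
      sc2 <- simulate_scene_(config)
      nuc2 <- sc2$truth$nuclei[[1L]]
      s2 <- matrix(sc2$truth$expected[1L, 1L, , ],
                   nrow = dim(sc2$truth$expected)[3L])[nuc2$interior]
      ch2 <- s2 + rnorm(length(s2), 0, sig_n(s2, target_r))
      n <- min(length(ch1), length(ch2))
      ch1 <- ch1[seq_len(n)]; ch2 <- ch2[seq_len(n)]
    }
    list(ch1 = ch1, ch2 = ch2, n = length(ch1))
  })
}
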