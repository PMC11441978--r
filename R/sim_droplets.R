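#' Configuration for synthetic in vitro droplet fields
#'
#' Disks of elevated intensity on a dilute-phase background, emulating
#' two-channel images of phase-separated protein droplets: the droplet
#' level in each channel is partition_ratio x dilute level, followed by
#' Gaussian PSF blur and optional Poisson noise.
#'
#' @param img_size field size in pixels \code{c(ny, nx)}.
#' @param n_droplets number of droplets.
#' @param radius_px droplet radius range in pixels (radii >= 2 required).
#' @param dilute_level per-channel dilute-phase intensity (photons/px).
#' @param partition_ratios per-channel in-droplet / dilute intensity ratio.
#' @param pixel_size_um pixel size (um).
#' @param psf_sigma_px Gaussian PSF sigma (px); 0 disables blur.
#' @param noise \code{"poisson"} or \code{"none"}.
#' @param channel_names channel labels; droplets are typically segmented on
#'   the first (scaffold) channel and partitioning of a client protein is
#'   measured on the second.
#' @param min_separation_px minimum gap between droplet rims.
#' @param max_place_tries placement retries before giving up.
#' @return an object of class \code{droplet_config}.
#' @export
droplet_config <- function(img_size = c(128L, 128L), n_droplets = 10L,
                           radius_px = c(3, 6),
                           dilute_level = c(20, 20),
                           partition_ratios = c(5, 5),
                           pixel_size_um = 0.1, psf_sigma_px = 1,
                           noise = c("poisson", "none"),
                           channel_names = c("mcherry", "gfp"),
                           min_separation_px = 4, max_place_tries = 500L) {
  cfg <- structure(list(img_size = as.integer(img_size),
                        n_droplets = as.integer(n_droplets),
                        radius_px = radius_px,
                        dilute_level = dilute_level,
                        partition_ratios = partition_ratios,
                        pixel_size_um = pixel_size_um,
                        psf_sigma_px = psf_sigma_px,
                        noise = match.arg(noise),
                        channel_names = channel_names,
                        min_separation_px = min_separation_px,
                        max_place_tries = as.integer(max_place_tries)),
                   class = "droplet_config")
  validate_droplet_config(cfg)
  cfg
}

#' @rdname droplet_config
#' @param cfg a \code{droplet_config}.
#' @export
validate_droplet_config <- function(cfg) {
  stopifnot(length(cfg$img_size) == 2L, cfg$n_droplets >= 0L,
            cfg$pixel_size_um > 0, cfg$psf_sigma_px >= 0)
  if (any(cfg$radius_px < 2)) stop("droplet radii must be >= 2 px")
  if (any(cfg$partition_ratios < 0)) stop("partition ratios must be >= 0")
  if (any(cfg$dilute_level <= 0)) stop("dilute_level must be > 0")
  if (length(cfg$dilute_level) != length(cfg$channel_names) ||
      length(cfg$partition_ratios) != length(cfg$channel_names))
    stop("dilute_level and partition_ratios need one value per channel")
  invisible(cfg)
}

#' Simulate a droplet field with known ground truth
#'
#' @param config a \code{\link{droplet_config}}.
#' @param seed integer seed.
#' @return a list with \code{stack} (single-z, multi-channel
#'   \code{\link{image_stack}}) and \code{truth} (droplet centers/radii,
#'   per-channel dilute level and partition ratios, config, seed).
#' @export
simulate_droplet_field <- function(config = droplet_config(), seed = 1L) {
  validate_droplet_config(config)
  set.seed(seed)
  ny <- config$img_size[1L]; nx <- config$img_size[2L]
  nc <- length(config$channel_names)
  radii <- runif(config$n_droplets, config$radius_px[1L], config$radius_px[2L])
  centers <- matrix(NA_real_, config$n_droplets, 2L)
  for (i in seq_len(config$n_droplets)) {
    placed <- FALSE
    for (k in seq_len(config$max_place_tries)) {
      m <- radii[i] + 3
      cand <- c(runif(1, m, ny - m), runif(1, m, nx - m))
      ok <- i == 1L || all(sqrt(rowSums(
        (centers[seq_len(i - 1L), , drop = FALSE] -
         matrix(cand, i - 1L, 2L, byrow = TRUE))^2)) >=
        radii[i] + radii[seq_len(i - 1L)] + config$min_separation_px)
      if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop("droplets cannot be placed without overlap after bounded retries")
  }
  expected <- array(0, dim = c(1L, nc, ny, nx))
  for (ci in seq_len(nc)) {
    img <- matrix(config$dilute_level[ci], ny, nx)
    lvl <- config$partition_ratios[ci] * config$dilute_level[ci]
    for (i in seq_len(config$n_droplets))
      img[disk_mask(ny, nx, centers[i, 1L], centers[i, 2L], radii[i])] <- lvl
    if (config$psf_sigma_px > 0)
      img <- EBImage::gblur(img, sigma = config$psf_sigma_px)
    expected[1L, ci, , ] <- pmax(img, 0)
  }
  pixels <- expected
  if (config$noise == "poisson")
    pixels <- array(rpois(length(pixels), pixels), dim = dim(pixels))
  stack <- image_stack(pixels, config$pixel_size_um,
                       channel_names = config$channel_names)
  truth <- list(centers = centers, radii_px = radii,
                dilute_level = setNames(config$dilute_level,
                                        config$channel_names),
                partition_ratios = setNames(config$partition_ratios,
                                            config$channel_names),
                config = config, seed = seed)
  list(stack = stack, truth = truth)
}
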