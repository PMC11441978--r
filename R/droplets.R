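#' Segment in vitro droplets from one channel
#'
#' Same smoothed-threshold labeling as nucleus segmentation, with droplet
#' defaults: minimum area \code{droplet_min_area}, no interior erosion and
#' no splitting of touching droplets (fusing droplets are biologically
#' real objects). The dilute-phase mask is the complement of all droplets
#' minus a guard band of \code{droplet_guard_px} pixels around them, so PSF
#' leakage from droplet rims does not inflate the dilute mean.
#'
#' @param stack an \code{\link{image_stack}} (single z) or a 2D matrix.
#' @param channel channel to segment on (the scaffold protein's channel).
#' @param params a \code{\link{run_config}}.
#' @return an object of class \code{droplet_set}: \code{table} (data.frame:
#'   \code{droplet_id}, \code{area_px}, \code{area_um2},
#'   \code{equiv_diameter_px}, \code{equiv_diameter_um}, centroid),
#'   \code{regions} (pixel sets), \code{droplet_mask}, \code{dilute_mask},
#'   \code{stack}, \code{segmentation_channel}. An image without droplets
#'   yields an empty set (not an error).
#' @export
segment_droplets <- function(stack, channel = 1L, params = run_config()) {
  validate_run_config(params)
  if (is.matrix(stack)) stack <- image_stack(stack, pixel_size_um = 1)
  if (n_z(stack) > 1L) stop("droplet fields must be single-z images")
  img <- get_plane(stack, channel, 1L)
  regions <- label_regions(img, sigma = params$seg_sigma,
                           min_area = params$droplet_min_area,
                           erode_px = 0, source_z = 1L, mode = "otsu")
  ny <- nrow(img); nx <- ncol(img)
  droplet_mask <- matrix(FALSE, ny, nx)
  for (r in regions) droplet_mask[r$pixels] <- TRUE
  guard <- params$droplet_guard_px
  dil <- if (any(droplet_mask) && guard > 0) {
    grown <- EBImage::dilate(droplet_mask,
                             EBImage::makeBrush(2L * guard + 1L,
                                                shape = "disc")) > 0
    !grown
  } else !droplet_mask
  # intensity measurements use the droplet interior (mask eroded by the
  # guard band) so the PSF-blurred rim biases neither phase; small droplets
  # whose interior vanishes fall back to their full pixel set
  if (any(droplet_mask) && guard > 0) {
    shrunk <- EBImage::erode(droplet_mask,
                             EBImage::makeBrush(2L * guard + 1L,
                                                shape = "disc")) > 0
    regions <- lapply(regions, function(r) {
      inl <- r$pixels[shrunk[r$pixels], , drop = FALSE]
      r$interior <- if (nrow(inl) > 0L) inl else r$pixels
      r
    })
  }
  px_um <- stack$pixel_size_um
  tab <- if (length(regions) == 0L) {
    data.frame(droplet_id = integer(), area_px = integer(),
               area_um2 = numeric(), equiv_diameter_px = numeric(),
               equiv_diameter_um = numeric(), centroid_y = numeric(),
               centroid_x = numeric())
  } else {
    do.call(rbind, lapply(regions, function(r)
      data.frame(droplet_id = r$region_id, area_px = r$area,
                 area_um2 = r$area * px_um^2,
                 equiv_diameter_px = 2 * sqrt(r$area / pi),
                 equiv_diameter_um = 2 * sqrt(r$area / pi) * px_um,
                 centroid_y = r$centroid[["y"]],
                 centroid_x = r$centroid[["x"]])))
  }
  structure(list(table = tab, regions = regions,
                 droplet_mask = droplet_mask, dilute_mask = dil,
                 stack = stack, segmentation_channel = channel),
            class = "droplet_set")
}

#' @export
print.droplet_set <- function(x, ...) {
  cat(sprintf("<droplet_set> %d droplet(s), dilute phase %d px\n",
              nrow(x$table), sum(x$dilute_mask)))
  invisible(x)
}

#' Partition coefficient of a channel into droplets
#'
#' Enrichment of a protein in the condensed phase: the ratio of mean
#' in-droplet intensity to the dilute-phase mean, per droplet and pooled.
#' The pooled ratio is area-weighted (total in-droplet intensity over total
#' droplet area, divided by the dilute mean).
#'
#' @param droplets a \code{\link{segment_droplets}} result.
#' @param channel channel to measure (may differ from the segmentation
#'   channel — e.g. the client protein's channel).
#' @return an object of class \code{partition_result}: \code{per_droplet}
#'   (data.frame with droplet means and ratios), \code{dilute_mean},
#'   \code{pooled_ratio}, \code{channel}.
#' @export
partition_coefficient <- function(droplets, channel = NULL) {
  channel <- channel %||% droplets$segmentation_channel
  img <- get_plane(droplets$stack, channel, 1L)
  if (!any(droplets$dilute_mask)) stop("empty dilute-phase mask")
  dil <- mean(img[droplets$dilute_mask])
  if (dil <= 0) stop("dilute-phase mean must be positive")
  per <- droplets$table
  if (nrow(per) > 0L) {
    per$mean_intensity <- vapply(droplets$regions, function(r)
      mean(img[r$interior]), 0)
    per$partition_ratio <- per$mean_intensity / dil
    n_int <- vapply(droplets$regions, function(r) nrow(r$interior), 0L)
    pooled <- sum(vapply(droplets$regions, function(r)
      sum(img[r$interior]), 0)) / sum(n_int) / dil
  } else {
    per$mean_intensity <- numeric(0)
    per$partition_ratio <- numeric(0)
    pooled <- NA_real_
  }
  structure(list(per_droplet = per, dilute_mean = dil,
                 pooled_ratio = pooled, channel = channel),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> channel %s: pooled ratio %.4g (dilute mean %.4g, %d droplet(s))\n",
              as.character(x$channel), x$pooled_ratio, x$dilute_mean,
              nrow(x$per_droplet)))
  invisible(x)
}

#' Pixel overlap between two droplet sets
#'
#' Fraction of one set's droplet area overlapped by the other's — the
#' two-channel droplet co-localization readout.
#'
#' @param set_a,set_b \code{\link{segment_droplets}} results on the same
#'   image geometry.
#' @return a list with \code{a_in_b} (fraction of set_a droplet pixels
#'   inside set_b droplets) and \code{b_in_a} (the reciprocal); NA for an
#'   empty set.
#' @export
droplet_colocalization <- function(set_a, set_b) {
  if (!identical(dim(set_a$droplet_mask), dim(set_b$droplet_mask)))
    stop("geometry mismatch: droplet sets come from different image sizes")
  na <- sum(set_a$droplet_mask); nb <- sum(set_b$droplet_mask)
  inter <- sum(set_a$droplet_mask & set_b$droplet_mask)
  list(a_in_b = if (na > 0) inter / na else NA_real_,
       b_in_a = if (nb > 0) inter / nb else NA_real_)
}
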