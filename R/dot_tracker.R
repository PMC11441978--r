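#' Detect the chromatin locus dot in a z-stack
#'
#' Finds the tetO/tetR-type locus tag: after Gaussian smoothing of every z
#' plane of the dot channel, the global maximum over (z, y, x) defines the
#' best z plane and the dot center ("dot intensity" is the smoothed
#' single-pixel maximum). Ties are broken by lowest z, then row-major
#' (y, x). The detection fails the prominence check when the ratio of the
#' smoothed peak to the smoothed stack median falls below
#' \code{dot_min_prominence} — cells without a visible array dot are
#' excluded from downstream averaging.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param channel dot channel (e.g. \code{"mcherry"}).
#' @param params a \code{\link{run_config}} (\code{dot_sigma},
#'   \code{dot_min_prominence}).
#' @param cell_id optional identifier carried through.
#' @return an object of class \code{dot_detection}: \code{cell_id},
#'   \code{best_z}, \code{center} (y, x), \code{peak}, \code{prominence},
#'   \code{pass}. An all-zero channel gives \code{pass = FALSE} with NA
#'   coordinates (no-dot failure).
#' @export
detect_dot <- function(stack, channel, params = run_config(), cell_id = NA) {
  validate_run_config(params)
  ci <- channel_index(stack, channel)
  nz <- n_z(stack)
  if (max(stack$pixels[, ci, , ]) <= 0) {
    return(structure(list(cell_id = cell_id, best_z = NA_integer_,
                          center = c(y = NA_real_, x = NA_real_),
                          peak = 0, prominence = NA_real_, pass = FALSE),
                     class = "dot_detection"))
  }
  best <- list(val = -Inf, z = NA_integer_, y = NA_integer_, x = NA_integer_)
  all_vals <- numeric(0)
  for (zi in seq_len(nz)) {
    pl <- get_plane(stack, ci, zi)
    sm <- if (params$dot_sigma > 0)
      EBImage::gblur(pl, sigma = params$dot_sigma) else pl
    all_vals <- c(all_vals, as.vector(sm))
    mx <- max(sm)
    if (mx > best$val) {            # strict >: earlier z wins ties
      idx <- which(sm == mx, arr.ind = TRUE)
      idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]  # row-major
      best <- list(val = mx, z = zi, y = idx[1L, 1L], x = idx[1L, 2L])
    }
  }
  med <- median(all_vals)
  prom <- if (med > 0) best$val / med else Inf
  structure(list(cell_id = cell_id, best_z = best$z,
                 center = c(y = as.numeric(best$y), x = as.numeric(best$x)),
                 peak = best$val, prominence = prom,
                 pass = prom >= params$dot_min_prominence),
            class = "dot_detection")
}

#' Extract a single z plane
#'
#' The "same z" image: the plane of the signal channel at the z position
#' where the locus dot is sharpest.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param channel channel name or index.
#' @param z 1-based z index.
#' @return the (y, x) matrix of that plane, unmodified.
#' @export
extract_same_z <- function(stack, channel, z) {
  if (z < 1L || z > n_z(stack)) stop("z index out of range")
  get_plane(stack, channel, as.integer(z))
}

#' Maximum intensity projection over z
#'
#' @param stack an \code{\link{image_stack}}.
#' @param channel channel name or index.
#' @return the (y, x) matrix of per-pixel maxima across all z planes.
#' @export
extract_mip <- function(stack, channel) {
  ci <- channel_index(stack, channel)
  apply(stack$pixels[, ci, , , drop = FALSE], c(3L, 4L), max)
}

#' Align per-cell images on their dot centers and average
#'
#' Each cell's image is cropped to a (2w+1) x (2w+1) window about its dot
#' center (integer-pixel alignment — the camera grid is averaged as-is, no
#' subpixel interpolation) and the windows are averaged pixelwise across
#' cells. Window pixels falling outside an image contribute nothing: the
#' mean at each offset uses only the cells that cover it (missing-aware),
#' and the per-pixel contributing-cell count is returned. Offset (0, 0) —
#' the window center — is the dot position by construction.
#'
#' @param images list of per-cell 2D matrices (e.g. GFP MIPs).
#' @param centers n x 2 matrix (or list) of per-cell (y, x) dot centers,
#'   integer pixels within each image.
#' @param w window radius in pixels.
#' @param pixel_size_um optional calibration carried into line profiles.
#' @param mode label recorded on the result (\code{"mip"} or
#'   \code{"same_z"}).
#' @return an object of class \code{aligned_average}: \code{average}
#'   ((2w+1) x (2w+1), NA where no cell contributes), \code{count}
#'   (contributing cells per pixel), \code{n_cells}, \code{windows}
#'   (n x (2w+1) x (2w+1) array of the individual cropped windows, NA
#'   outside image bounds), \code{w}, \code{mode}, \code{pixel_size_um}.
#' @export
align_and_average <- function(images, centers, w = 10L,
                              pixel_size_um = NA_real_,
                              mode = c("mip", "same_z")) {
  mode <- match.arg(mode)
  if (length(images) == 0L) stop("empty input: no cells to average")
  if (is.list(centers)) centers <- do.call(rbind, centers)
  centers <- matrix(as.numeric(centers), ncol = 2L)
  if (nrow(centers) != length(images))
    stop("one center per image is required")
  w <- as.integer(w)
  size <- 2L * w + 1L
  n <- length(images)
  windows <- array(NA_real_, dim = c(n, size, size))
  for (i in seq_len(n)) {
    img <- images[[i]]
    cy <- as.integer(round(centers[i, 1L]))
    cx <- as.integer(round(centers[i, 2L]))
    if (cy < 1L || cx < 1L || cy > nrow(img) || cx > ncol(img))
      stop(sprintf("center of cell %d lies outside its image", i))
    ys <- (cy - w):(cy + w); xs <- (cx - w):(cx + w)
    yok <- ys >= 1L & ys <= nrow(img)
    xok <- xs >= 1L & xs <= ncol(img)
    windows[i, which(yok), which(xok)] <- img[ys[yok], xs[xok]]
  }
  count <- apply(windows, c(2L, 3L), function(v) sum(!is.na(v)))
  avg <- apply(windows, c(2L, 3L), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  structure(list(average = avg, count = count, n_cells = n, windows = windows,
                 w = w, mode = mode, pixel_size_um = pixel_size_um),
            class = "aligned_average")
}

#' @export
print.aligned_average <- function(x, ...) {
  cat(sprintf("<aligned_average> mode=%s, %d cells, window %dx%d (w=%d)\n",
              x$mode, x$n_cells, 2 * x$w + 1, 2 * x$w + 1, x$w))
  invisible(x)
}

#' Intensity line profile through the dot center of an averaged image
#'
#' Cuts the center row (horizontal) or column (vertical) of an
#' \code{\link{aligned_average}}: offset 0 is the dot center. The per-offset
#' SEM comes from the individual cells' values at that offset
#' (missing-aware).
#'
#' @param avg an \code{\link{aligned_average}}.
#' @param orientation \code{"horizontal"} (center row, offsets along x) or
#'   \code{"vertical"} (center column).
#' @return a data.frame of class \code{line_profile}: \code{offset_px}
#'   (-w..w), \code{offset_um} (NA without calibration), \code{mean},
#'   \code{sem}, \code{n}; attribute \code{"orientation"}.
#' @export
line_profile <- function(avg, orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  w <- avg$w
  c0 <- w + 1L
  if (orientation == "horizontal") {
    vals <- avg$windows[, c0, , drop = FALSE]   # n x 1 x (2w+1)
  } else {
    vals <- avg$windows[, , c0, drop = FALSE]
  }
  vals <- matrix(vals, nrow = avg$n_cells)      # n x (2w+1)
  nn <- colSums(!is.na(vals))
  mu <- ifelse(nn > 0, colMeans(vals, na.rm = TRUE), NA_real_)
  sem <- vapply(seq_len(ncol(vals)), function(j)
    if (nn[j] > 1) sd(vals[, j], na.rm = TRUE) / sqrt(nn[j]) else NA_real_, 0)
  out <- data.frame(offset_px = -w:w,
                    offset_um = (-w:w) * avg$pixel_size_um,
                    mean = mu, sem = sem, n = nn)
  attr(out, "orientation") <- orientation
  class(out) <- c("line_profile", "data.frame")
  out
}

#' Per-cell mean intensity in the window center
#'
#' The center readout behind dot-centered enrichment tests: for each cell,
#' the mean of its aligned window over offsets |dy| <= h and |dx| <= h
#' (missing-aware).
#'
#' @param avg an \code{\link{aligned_average}}.
#' @param halfwidth center-window half-width h in pixels.
#' @return numeric vector, one value per cell.
#' @export
center_values <- function(avg, halfwidth = 2L) {
  c0 <- avg$w + 1L
  idx <- (c0 - halfwidth):(c0 + halfwidth)
  vapply(seq_len(avg$n_cells), function(i)
    mean(avg$windows[i, idx, idx], na.rm = TRUE), 0)
}

#' Compare dot-center enrichment between two conditions
#'
#' Two-sided Student's t-test on per-cell center-window mean intensities —
#' the test behind "GFP intensity near the dot center is significantly
#' higher at target loci".
#'
#' @param values_a,values_b per-cell center values
#'   (\code{\link{center_values}}) of the two conditions.
#' @param welch use Welch's test.
#' @return a \code{\link{compare_groups}} result.
#' @export
center_enrichment <- function(values_a, values_b, welch = FALSE) {
  compare_groups(values_a, values_b, welch = welch)
}
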