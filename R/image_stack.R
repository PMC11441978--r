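#' Multi-channel, multi-z image stack
#'
#' The universal image container of the package: a 4-dimensional numeric
#' array indexed \code{(z, channel, y, x)} together with its physical
#' calibration. y increases downward, x rightward; pixel indices are 1-based
#' and address pixel centers. Intensities are stored as floating point
#' regardless of the on-disk integer type (background subtraction produces
#' non-integers).
#'
#' @param pixels numeric array with dimensions \code{(z, channel, y, x)}.
#'   A 2D matrix or a 3D \code{(channel, y, x)} array is promoted to 4D.
#' @param pixel_size_um physical pixel size in micrometres (y and x).
#' @param z_step_um spacing between z planes in micrometres; required
#'   (positive) when there is more than one z plane.
#' @param channel_names character vector of channel labels, one per channel
#'   (e.g. \code{c("gfp", "mcherry")}).
#' @return an object of class \code{image_stack}.
#' @examples
#' img <- array(0, dim = c(1, 1, 8, 8))
#' s <- image_stack(img, pixel_size_um = 0.1, channel_names = "gfp")
#' dim(s$pixels)
#' @export
image_stack <- function(pixels, pixel_size_um, z_step_um = NA_real_,
                        channel_names = NULL) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(1L, 1L, nrow(pixels), ncol(pixels)))
  } else if (length(dim(pixels)) == 3L) {
    pixels <- array(pixels, dim = c(1L, dim(pixels)))
  }
  if (length(dim(pixels)) != 4L)
    stop("'pixels' must have dimensions (z, channel, y, x)")
  storage.mode(pixels) <- "double"
  nc <- dim(pixels)[2L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  obj <- structure(
    list(pixels = pixels,
         pixel_size_um = as.numeric(pixel_size_um),
         z_step_um = as.numeric(z_step_um),
         channel_names = as.character(channel_names)),
    class = "image_stack")
  validate_image_stack(obj)
  obj
}

#' @rdname image_stack
#' @param x an \code{image_stack}.
#' @export
validate_image_stack <- function(x) {
  d <- dim(x$pixels)
  if (any(!is.finite(x$pixels))) stop("intensities must be finite")
  if (any(x$pixels < 0)) stop("intensities must be non-negative")
  if (length(x$channel_names) != d[2L])
    stop("number of channel_names must equal the channel-axis length")
  if (!is.finite(x$pixel_size_um) || x$pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  if (d[1L] > 1L && (!is.finite(x$z_step_um) || x$z_step_um <= 0))
    stop("z_step_um must be > 0 for stacks with more than one z plane")
  invisible(x)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d z x %d channel(s) [%s] x %d x %d px, %.3g um/px",
              d[1L], d[2L], paste(x$channel_names, collapse = ","),
              d[3L], d[4L], x$pixel_size_um))
  if (d[1L] > 1L) cat(sprintf(", z step %.3g um", x$z_step_um))
  cat("\n")
  invisible(x)
}

#' Dimensions and plane access for image stacks
#'
#' @param stack an \code{image_stack}.
#' @param channel channel name or index.
#' @param z 1-based z index.
#' @return \code{n_z}/\code{n_channels}: integers. \code{channel_index}: the
#'   integer channel index. \code{get_plane}: the \code{(y, x)} matrix of one
#'   plane.
#' @export
n_z <- function(stack) dim(stack$pixels)[1L]

#' @rdname n_z
#' @export
n_channels <- function(stack) dim(stack$pixels)[2L]

#' @rdname n_z
#' @export
channel_index <- function(stack, channel) {
  if (is.numeric(channel)) {
    ci <- as.integer(channel)
    if (ci < 1L || ci > n_channels(stack)) stop("channel index out of range")
    return(ci)
  }
  ci <- match(channel, stack$channel_names)
  if (is.na(ci)) stop(sprintf("channel '%s' not found (have: %s)", channel,
                              paste(stack$channel_names, collapse = ", ")))
  ci
}

#' @rdname n_z
#' @export
get_plane <- function(stack, channel, z = 1L) {
  if (z < 1L || z > n_z(stack)) stop("z index out of range")
  ci <- channel_index(stack, channel)
  matrix(stack$pixels[z, ci, , ], nrow = dim(stack$pixels)[3L])
}

#' Read a TIFF / OME-TIFF file into an image stack
#'
#' Pages of a multi-page TIFF are arranged into the canonical
#' \code{(z, channel, y, x)} array according to \code{page_order}. A
#' single-page file with a sample (RGB-like) axis is interpreted as one z
#' plane with that axis as the channel axis.
#'
#' @param path path to a single- or multi-page TIFF file.
#' @param n_channels number of channels interleaved in the page sequence.
#' @param page_order \code{"cz"}: channel varies fastest across pages
#'   (default, and the order \code{\link{write_stack}} uses); \code{"zc"}:
#'   z varies fastest.
#' @param pixel_size_um,z_step_um physical calibration (not stored in plain
#'   TIFF, so supplied here).
#' @param channel_names optional channel labels.
#' @return an \code{image_stack}.
#' @export
read_stack <- function(path, n_channels = 1L, page_order = c("cz", "zc"),
                       pixel_size_um = 0.1, z_step_um = NA_real_,
                       channel_names = NULL) {
  page_order <- match.arg(page_order)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("unreadable file: %s (%s)", path,
                                   conditionMessage(e)), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop(sprintf("unreadable file: %s (no pages)", path))
  if (length(pages) == 1L && length(dim(pages[[1L]])) == 3L) {
    # one page carrying a sample axis (y, x, channel)
    a <- pages[[1L]]
    nc <- dim(a)[3L]
    px <- array(aperm(a, c(3L, 1L, 2L)), dim = c(1L, nc, dim(a)[1L], dim(a)[2L]))
    return(image_stack(px, pixel_size_um, z_step_um,
                       channel_names %||% paste0("ch", seq_len(nc))))
  }
  dims <- vapply(pages, function(p) {
    if (!is.matrix(p)) stop("unreadable file: page is not a 2D image")
    dim(p)
  }, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("unreadable file: pages differ in size")
  np <- length(pages)
  nc <- as.integer(n_channels)
  if (np %% nc != 0L)
    stop(sprintf("page count (%d) is not a multiple of n_channels (%d)", np, nc))
  nz <- np %/% nc
  ny <- dims[1L, 1L]; nx <- dims[2L, 1L]
  px <- array(0, dim = c(nz, nc, ny, nx))
  for (p in seq_len(np)) {
    if (page_order == "cz") {
      zi <- (p - 1L) %/% nc + 1L; ci <- (p - 1L) %% nc + 1L
    } else {
      zi <- (p - 1L) %% nz + 1L; ci <- (p - 1L) %/% nz + 1L
    }
    px[zi, ci, , ] <- pages[[p]]
  }
  if (any(px < 0)) stop("negative intensities after offset handling")
  image_stack(px, pixel_size_um, z_step_um, channel_names)
}

#' Write an image stack to a multi-page TIFF
#'
#' Pages are written with the channel axis varying fastest (the \code{"cz"}
#' order of \code{\link{read_stack}}). 16-bit output is bit-exact for
#' integer-valued images in [0, 65535] (simulated photon-count stacks
#' round-trip losslessly). 32-bit float output stores \code{pixels / scale};
#' libtiff float pages only reliably hold values in [0, 1], so \code{scale}
#' defaults to the stack maximum and is returned invisibly.
#'
#' @param stack an \code{image_stack}.
#' @param path output path.
#' @param bits 16 (integer) or 32 (float).
#' @param scale divisor applied before writing 32-bit float pages.
#' @return invisibly, the scale factor used (1 for 16-bit).
#' @export
write_stack <- function(stack, path, bits = 16L, scale = NULL) {
  validate_image_stack(stack)
  d <- dim(stack$pixels)
  pages <- vector("list", d[1L] * d[2L])
  p <- 1L
  for (zi in seq_len(d[1L])) for (ci in seq_len(d[2L])) {
    pages[[p]] <- matrix(stack$pixels[zi, ci, , ], nrow = d[3L])
    p <- p + 1L
  }
  if (bits == 16L) {
    mx <- max(vapply(pages, max, 0))
    if (mx > 65535) stop("16-bit output requires intensities <= 65535")
    pages <- lapply(pages, function(m) round(m) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    return(invisible(1))
  }
  if (bits == 32L) {
    scale <- scale %||% max(1, vapply(pages, max, 0))
    pages <- lapply(pages, function(m) m / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    return(invisible(scale))
  }
  stop("bits must be 16 or 32")
}

#' Write a results table to CSV or TSV
#'
#' @param rows a data.frame, or a list of named lists/vectors sharing one
#'   schema (an empty list yields a header-only file when \code{schema}
#'   names are supplied via a zero-row data.frame).
#' @param path output path; extension selects the format (\code{.tsv} /
#'   \code{.txt} write tab-separated, anything else comma-separated).
#' @return invisibly, the data.frame written.
#' @export
write_results <- function(rows, path) {
  if (!is.data.frame(rows)) {
    if (!is.list(rows)) stop("'rows' must be a data.frame or list of rows")
    if (length(rows) == 0L) stop("empty row list without schema; pass a zero-row data.frame")
    nms <- lapply(rows, names)
    if (any(vapply(nms, is.null, TRUE)) ||
        !all(vapply(nms, identical, TRUE, nms[[1L]])))
      stop("ragged rows: all rows must share one set of column names")
    rows <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(rows)
}

#' Read a results table written by \code{\link{write_results}}
#'
#' @param path path to a CSV/TSV file.
#' @return a data.frame.
#' @export
read_results <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
    read.delim(path, check.names = FALSE)
  else read.csv(path, check.names = FALSE)
}
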