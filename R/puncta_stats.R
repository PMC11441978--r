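#' Per-region pixel-intensity statistics (CV and Fano number)
#'
#' The condensate-detection metric: for the pixel values of one nucleus,
#' computes the background-subtracted mean, the sample (n-1) variance of
#' the raw values, the coefficient of variation CV = sd / sub_mean and the
#' Fano number = variance / sub_mean. Background is modeled as a constant
#' offset measured on unlabeled cells, so it shifts the mean but not the
#' variance; CV and Fano therefore use the subtracted mean in the
#' denominator and the raw-pixel variance in the numerator. A free,
#' well-mixed fluorophore imaged in photon units gives Fano ~ 1 (Poisson
#' statistics); concentration of intensity into puncta inflates it.
#'
#' When the subtracted mean is non-positive, CV and Fano are undefined and
#' returned as NA with \code{undefined = TRUE} — such cells are excluded
#' from condition aggregates rather than silently included.
#'
#' @param pixels numeric vector of raw pixel values (length >= 2).
#' @param background_mean mean background intensity (>= 0).
#' @return an object of class \code{pixel_stats}: \code{n_pixels},
#'   \code{raw_mean}, \code{background_mean}, \code{sub_mean},
#'   \code{variance}, \code{sd}, \code{cv}, \code{fano}, \code{undefined}.
#'   The identity fano = cv^2 * sub_mean holds to machine precision.
#' @examples
#' compute_pixel_stats(c(2, 4, 6))           # sub_mean 4, var 4, cv 0.5, fano 1
#' compute_pixel_stats(c(12, 14, 16), 10)    # identical: shift invariance
#' @export
compute_pixel_stats <- function(pixels, background_mean = 0) {
  if (length(pixels) < 2L)
    stop("at least 2 pixels are required for a variance")
  if (background_mean < 0) stop("background_mean must be >= 0")
  m <- mean(pixels)
  v <- var(pixels)
  sub <- m - background_mean
  undef <- sub <= 0
  structure(list(n_pixels = length(pixels), raw_mean = m,
                 background_mean = background_mean, sub_mean = sub,
                 variance = v, sd = sqrt(v),
                 cv = if (undef) NA_real_ else sqrt(v) / sub,
                 fano = if (undef) NA_real_ else v / sub,
                 undefined = undef),
            class = "pixel_stats")
}

#' @export
print.pixel_stats <- function(x, ...) {
  cat(sprintf("<pixel_stats> n=%d mean=%.4g (bg %.4g) var=%.4g cv=%.4g fano=%.4g%s\n",
              x$n_pixels, x$raw_mean, x$background_mean, x$variance,
              x$cv, x$fano, if (x$undefined) " [undefined]" else ""))
  invisible(x)
}

#' Per-nucleus pixel statistics for a segmented stack
#'
#' Convenience pipeline: applies \code{\link{compute_pixel_stats}} to every
#' region of a stack. Dispersion statistics use the interior pixel set by
#' default (see \code{\link{segment_nuclei}}).
#'
#' @param stack an \code{\link{image_stack}}.
#' @param regions list of \code{nucleus_region}s (from
#'   \code{\link{segment_nuclei}}); segmented on the fly when NULL.
#' @param channel channel name or index.
#' @param background_mean mean background intensity.
#' @param use pixel set for the statistics (\code{"interior"} default).
#' @param params a \code{\link{run_config}}.
#' @return data.frame, one row per region: \code{cell_id}, \code{n_pixels},
#'   \code{raw_mean}, \code{sub_mean}, \code{variance}, \code{cv},
#'   \code{fano}, \code{undefined}.
#' @export
nucleus_pixel_stats <- function(stack, regions = NULL, channel = 1L,
                                background_mean = 0,
                                use = c("interior", "all"),
                                params = run_config()) {
  use <- match.arg(use)
  if (is.null(regions)) regions <- segment_nuclei(stack, channel, params)
  rows <- lapply(regions, function(r) {
    v <- extract_pixels(r, stack, channel, use = use)
    if (length(v) < 2L) return(NULL)
    s <- compute_pixel_stats(v, background_mean)
    data.frame(cell_id = r$region_id, n_pixels = s$n_pixels,
               raw_mean = s$raw_mean, sub_mean = s$sub_mean,
               variance = s$variance, cv = s$cv, fano = s$fano,
               undefined = s$undefined)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(cell_id = integer(), n_pixels = integer(),
                      raw_mean = numeric(), sub_mean = numeric(),
                      variance = numeric(), cv = numeric(),
                      fano = numeric(), undefined = logical()))
  do.call(rbind, rows)
}

#' Normalize per-cell Fano numbers to a reference condition
#'
#' Scales every Fano number by the mean Fano of a reference
#' (free-fluorophore) condition, so the reference condition's mean
#' normalized Fano is exactly 1.
#'
#' @param condition_fanos per-cell Fano numbers of the condition (NAs from
#'   undefined cells are dropped).
#' @param reference_fanos per-cell Fano numbers of the reference condition;
#'   must be non-empty with positive mean.
#' @return an object of class \code{normalized_fano}: \code{values}
#'   (per-cell normalized Fanos), \code{reference_mean}, \code{n},
#'   \code{mean}, \code{sem} (SD / sqrt(n)).
#' @export
normalize_fano <- function(condition_fanos, reference_fanos) {
  reference_fanos <- reference_fanos[!is.na(reference_fanos)]
  condition_fanos <- condition_fanos[!is.na(condition_fanos)]
  if (length(reference_fanos) == 0L)
    stop("reference condition is empty")
  ref_mean <- mean(reference_fanos)
  if (ref_mean <= 0) stop("reference mean Fano must be positive")
  vals <- condition_fanos / ref_mean
  # the summary mean divides once, so normalizing a condition against
  # itself gives exactly 1 in floating point
  structure(list(values = vals, reference_mean = ref_mean,
                 n = length(vals), mean = mean(condition_fanos) / ref_mean,
                 sem = sd(vals) / sqrt(length(vals))),
            class = "normalized_fano")
}

#' @export
print.normalized_fano <- function(x, ...) {
  cat(sprintf("<normalized_fano> n=%d mean=%.4g +/- %.4g (SEM); reference mean Fano %.4g\n",
              x$n, x$mean, x$sem, x$reference_mean))
  invisible(x)
}

#' Per-cell two-channel pixel co-localization (Pearson r)
#'
#' Pearson correlation between the two channels' pixel values inside one
#' nucleus — the per-cell co-localization readout. Undefined (NA, flagged)
#' when either channel has zero variance within the region.
#'
#' @param pixels_ch1,pixels_ch2 equal-length pixel-value vectors
#'   (length >= 3).
#' @param cell_id optional identifier carried through.
#' @return an object of class \code{coloc_result}: \code{cell_id},
#'   \code{n_pixels}, \code{pearson_r} in [-1, 1], \code{undefined}.
#' @export
pixel_colocalization <- function(pixels_ch1, pixels_ch2, cell_id = NA) {
  if (length(pixels_ch1) != length(pixels_ch2))
    stop("channel pixel vectors must have equal length")
  if (length(pixels_ch1) < 3L) stop("at least 3 pixels are required")
  undef <- var(pixels_ch1) == 0 || var(pixels_ch2) == 0
  r <- if (undef) NA_real_ else cor(pixels_ch1, pixels_ch2)
  structure(list(cell_id = cell_id, n_pixels = length(pixels_ch1),
                 pearson_r = r, undefined = undef),
            class = "coloc_result")
}

#' Per-nucleus co-localization for a two-channel stack
#'
#' Applies \code{\link{pixel_colocalization}} to each segmented region using
#' the interior pixel set of both channels.
#'
#' @param stack a two-channel \code{\link{image_stack}}.
#' @param ch1,ch2 channel names or indices.
#' @param regions optional pre-computed regions (segmented on \code{ch1}
#'   when NULL).
#' @param params a \code{\link{run_config}}.
#' @return data.frame with \code{cell_id}, \code{n_pixels},
#'   \code{pearson_r}, \code{undefined}.
#' @export
nucleus_colocalization <- function(stack, ch1 = 1L, ch2 = 2L, regions = NULL,
                                   params = run_config()) {
  if (is.null(regions)) regions <- segment_nuclei(stack, ch1, params)
  rows <- lapply(regions, function(r) {
    v1 <- extract_pixels(r, stack, ch1, use = "interior")
    v2 <- extract_pixels(r, stack, ch2, use = "interior")
    if (length(v1) < 3L) return(NULL)
    cc <- pixel_colocalization(v1, v2, cell_id = r$region_id)
    data.frame(cell_id = cc$cell_id, n_pixels = cc$n_pixels,
               pearson_r = cc$pearson_r, undefined = cc$undefined)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(cell_id = integer(), n_pixels = integer(),
                      pearson_r = numeric(), undefined = logical()))
  do.call(rbind, rows)
}

star_label <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Two-sample comparison of per-cell values
#'
#' Two-sided Student's t-test between two groups of per-cell values, with
#' the figure-caption star convention (* p < 0.05, ** p < 0.01,
#' *** p < 0.001). The pooled (equal-variance) test is the default;
#' Welch's test is available via \code{welch} or the config switch.
#'
#' @param a,b numeric vectors of per-cell values (each n >= 2; NAs
#'   dropped).
#' @param welch use Welch's unequal-variance t-test.
#' @return an object of class \code{group_comparison}: group \code{means},
#'   \code{sems}, \code{n}, \code{t}, \code{df}, \code{p}, \code{stars}.
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  tt <- t.test(a, b, var.equal = !welch)
  structure(list(means = c(a = mean(a), b = mean(b)),
                 sems = c(a = sd(a) / sqrt(length(a)),
                          b = sd(b) / sqrt(length(b))),
                 n = c(a = length(a), b = length(b)),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stars = star_label(tt$p.value),
                 welch = welch),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> mean a=%.4g (n=%d), b=%.4g (n=%d); %s t=%.3g, df=%.4g, p=%.3g %s\n",
              x$means[["a"]], x$n[["a"]], x$means[["b"]], x$n[["b"]],
              if (x$welch) "Welch" else "Student", x$t, x$df, x$p, x$stars))
  invisible(x)
}
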