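#' Analysis run configuration
#'
#' Central container for the tunable parameters of the analysis stages, with
#' the package defaults. All sizes are in pixels; sigmas are Gaussian
#' standard deviations in pixels.
#'
#' @param seg_sigma smoothing sigma before thresholding (nucleus/cell
#'   segmentation).
#' @param threshold thresholding mode for nucleus/cell segmentation.
#'   \code{"nucleus"} (default): two-pass robust threshold — Otsu on the
#'   log-compressed smoothed image seeds a foreground, and the final
#'   threshold is half the foreground median; this keeps whole nuclei
#'   intact when bright puncta dominate the dynamic range. \code{"otsu"}:
#'   plain Otsu, suited to bimodal images. Both operate on the normalized
#'   image and are therefore invariant to global intensity scaling.
#' @param min_area minimum region area in pixels; smaller components are
#'   discarded.
#' @param erode_px interior-erosion margin applied to region masks before
#'   pixel extraction for dispersion statistics (CV/Fano). The PSF-blurred
#'   rim of a region has an intensity gradient that would otherwise inflate
#'   pixel variance; the region's reported boundary, area and centroid are
#'   not affected. Set 0 to disable.
#' @param projection which image the 2D segmentation runs on for z-stacks:
#'   \code{"mean"} projection (default) or a fixed plane via \code{z_plane}.
#' @param z_plane 1-based z plane used when \code{projection = "plane"}.
#' @param dot_sigma smoothing sigma for chromatin-dot detection.
#' @param dot_min_prominence minimum (smoothed peak)/(smoothed median) ratio
#'   for a dot detection to pass.
#' @param window_radius half-width w of the dot-centered averaging window;
#'   the averaged image is (2w+1) x (2w+1).
#' @param center_halfwidth half-width of the center window (offsets with
#'   |d| <= center_halfwidth) used for enrichment tests.
#' @param welch use Welch's t-test instead of the pooled (equal-variance)
#'   Student's t-test in group comparisons.
#' @param frap_restarts number of jittered restarts for the FRAP fit.
#' @param droplet_min_area minimum droplet area in pixels.
#' @param droplet_guard_px guard band (pixels) around droplets excluded from
#'   the dilute-phase mask.
#' @param seed integer seed recorded for reproducibility (optional).
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(seg_sigma = 1, threshold = c("nucleus", "otsu"),
                       min_area = 30,
                       erode_px = 2, projection = c("mean", "plane"),
                       z_plane = 1L,
                       dot_sigma = 1, dot_min_prominence = 3,
                       window_radius = 10, center_halfwidth = 2,
                       welch = FALSE,
                       frap_restarts = 3,
                       droplet_min_area = 10, droplet_guard_px = 2,
                       seed = NULL) {
  cfg <- structure(list(
    seg_sigma = seg_sigma,
    threshold = match.arg(threshold, c("nucleus", "otsu")),
    min_area = min_area, erode_px = erode_px,
    projection = match.arg(projection), z_plane = as.integer(z_plane),
    dot_sigma = dot_sigma, dot_min_prominence = dot_min_prominence,
    window_radius = as.integer(window_radius),
    center_halfwidth = as.integer(center_halfwidth),
    welch = isTRUE(welch),
    frap_restarts = as.integer(frap_restarts),
    droplet_min_area = droplet_min_area,
    droplet_guard_px = as.integer(droplet_guard_px),
    seed = seed), class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' @rdname run_config
#' @param cfg a \code{run_config}.
#' @export
validate_run_config <- function(cfg) {
  pos <- c("seg_sigma", "min_area", "dot_sigma", "dot_min_prominence",
           "window_radius", "droplet_min_area")
  for (p in pos)
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0)
      stop(sprintf("'%s' must be > 0", p))
  for (p in c("erode_px", "center_halfwidth", "droplet_guard_px",
              "frap_restarts"))
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0)
      stop(sprintf("'%s' must be >= 0", p))
  if (!is.null(cfg$seed) && (!is.numeric(cfg$seed) ||
                             cfg$seed != round(cfg$seed)))
    stop("'seed' must be an integer when supplied")
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Values in the file override the package defaults of
#' \code{\link{run_config}}; unknown keys are rejected.
#'
#' @param path path to a YAML file.
#' @return a \code{run_config}.
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L)
    stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  do.call(run_config, vals)
}
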