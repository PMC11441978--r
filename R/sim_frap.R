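#' Ground truth for a synthetic FRAP experiment
#'
#' Parameters of a single-exponential fluorescence recovery:
#' I(t) = D + (P - D) (1 - exp(-k t)) with k = ln 2 / half_time, t measured
#' from the bleach. Defaults follow a typical in vitro condensate FRAP
#' acquisition: bleach after three frames, one frame every 3 s for 270 s,
#' and recovery kinetics on the minute scale.
#'
#' @param half_time_s half recovery time (s); k = ln2 / half_time_s.
#' @param plateau_pct recovery plateau, percent of pre-bleach intensity.
#' @param bleach_depth_pct intensity immediately after the bleach, percent
#'   of pre-bleach.
#' @param frame_interval_s frame interval (s).
#' @param duration_s post-bleach monitoring span (s); the series has
#'   duration_s / frame_interval_s post-bleach frames at t = 0,
#'   frame_interval_s, ..., duration_s - frame_interval_s.
#' @param n_pre number of pre-bleach frames (>= 1).
#' @param noise_sd_pct per-frame Gaussian noise SD, percent of the plateau.
#' @param seed optional integer seed used by \code{\link{simulate_frap}}.
#' @return an object of class \code{frap_truth}.
#' @export
frap_truth <- function(half_time_s = 64, plateau_pct = 85,
                       bleach_depth_pct = 25, frame_interval_s = 3,
                       duration_s = 270, n_pre = 3L, noise_sd_pct = 0,
                       seed = NULL) {
  obj <- structure(list(half_time_s = half_time_s, plateau_pct = plateau_pct,
                        bleach_depth_pct = bleach_depth_pct,
                        frame_interval_s = frame_interval_s,
                        duration_s = duration_s, n_pre = as.integer(n_pre),
                        noise_sd_pct = noise_sd_pct, seed = seed),
                   class = "frap_truth")
  validate_frap_truth(obj)
  obj
}

#' @rdname frap_truth
#' @param x a \code{frap_truth}.
#' @export
validate_frap_truth <- function(x) {
  if (x$half_time_s <= 0) stop("half_time_s must be > 0")
  if (x$frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  if (x$n_pre < 1L) stop("at least one pre-bleach frame is required")
  if (x$bleach_depth_pct < 0 || x$bleach_depth_pct > x$plateau_pct ||
      x$plateau_pct > 105)
    stop("need 0 <= bleach_depth_pct <= plateau_pct <= ~100")
  if (x$noise_sd_pct < 0) stop("noise_sd_pct must be >= 0")
  invisible(x)
}

#' Simulate a FRAP time series
#'
#' Pre-bleach frames sit at 100 percent-scale intensity; at the bleach frame
#' the intensity drops to the bleach depth and then recovers along the
#' single exponential of the truth object, with per-frame Gaussian noise.
#' The raw series is emitted in arbitrary camera units (\code{scale} a.u. =
#' 100 percent) so that \code{\link{normalize_frap}} performs real work.
#'
#' @param truth a \code{\link{frap_truth}}.
#' @param scale raw intensity corresponding to 100 percent pre-bleach.
#' @param seed integer seed; defaults to the seed stored in \code{truth}
#'   (no seeding when both are NULL and noise is 0).
#' @return a \code{frap_series} (see \code{\link{normalize_frap}}) with the
#'   truth attached as attribute \code{"truth"}.
#' @export
simulate_frap <- function(truth = frap_truth(), scale = 1000,
                          seed = truth$seed) {
  validate_frap_truth(truth)
  if (!is.null(seed)) set.seed(seed)
  k <- log(2) / truth$half_time_s
  n_post <- round(truth$duration_s / truth$frame_interval_s)
  t_post <- (seq_len(n_post) - 1L) * truth$frame_interval_s
  pct <- c(rep(100, truth$n_pre),
           truth$bleach_depth_pct +
             (truth$plateau_pct - truth$bleach_depth_pct) *
             (1 - exp(-k * t_post)))
  if (truth$noise_sd_pct > 0)
    pct <- pct + rnorm(length(pct), 0,
                       truth$noise_sd_pct / 100 * truth$plateau_pct)
  raw <- pct / 100 * scale
  ser <- normalize_frap(raw, bleach_index = truth$n_pre + 1L,
                        frame_interval_s = truth$frame_interval_s)
  attr(ser, "truth") <- truth
  ser
}
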