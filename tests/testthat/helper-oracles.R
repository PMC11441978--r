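# Independent brute-force oracles. These deliberately avoid the package's
# code paths: explicit loops and textbook formulas only.

o_mean <- function(x) sum(x) / length(x)

o_var <- function(x) {
  m <- o_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / (length(x) - 1)
}

o_pixel_stats <- function(px, bg = 0) {
  m <- o_mean(px)
  v <- o_var(px)
  sub <- m - bg
  list(sub_mean = sub, variance = v, cv = sqrt(v) / sub, fano = v / sub)
}

o_pearson <- function(x, y) {
  mx <- o_mean(x); my <- o_mean(y)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(x)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

# pooled-variance two-sample two-sided t-test, textbook form
o_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * o_var(a) + (nb - 1) * o_var(b)) / (na + nb - 2)
  t <- (o_mean(a) - o_mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# per-pixel maximum over z by explicit loops
o_mip <- function(pixels, ci) {
  d <- dim(pixels)
  out <- matrix(-Inf, d[3L], d[4L])
  for (z in seq_len(d[1L]))
    for (y in seq_len(d[3L]))
      for (x in seq_len(d[4L]))
        out[y, x] <- max(out[y, x], pixels[z, ci, y, x])
  out
}

# pad-and-mask alignment oracle: average and counts over (2w+1)^2 windows
o_align <- function(images, centers, w) {
  size <- 2L * w + 1L
  s <- matrix(0, size, size)
  n <- matrix(0L, size, size)
  for (i in seq_along(images)) {
    img <- images[[i]]
    cy <- round(centers[i, 1L]); cx <- round(centers[i, 2L])
    for (dy in -w:w) for (dx in -w:w) {
      yy <- cy + dy; xx <- cx + dx
      if (yy >= 1 && yy <= nrow(img) && xx >= 1 && xx <= ncol(img)) {
        s[dy + w + 1L, dx + w + 1L] <- s[dy + w + 1L, dx + w + 1L] + img[yy, xx]
        n[dy + w + 1L, dx + w + 1L] <- n[dy + w + 1L, dx + w + 1L] + 1L
      }
    }
  }
  avg <- ifelse(n > 0, s / n, NA_real_)
  list(average = avg, count = n)
}

# small noise-free single-nucleus scene used across tests
quiet_scene <- function(seed = 1, ...) {
  simulate_nucleus_scene(
    scene_config(noise = "none", cell_intensity_sdlog = 0, ...), seed = seed)
}
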