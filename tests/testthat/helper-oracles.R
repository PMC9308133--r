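# Independent oracles and small fixture builders used across the suite.

# Kapur maximum-entropy criterion by explicit summation over every candidate
# bin: the brute-force reference the fast implementation must match exactly.
kapur_bruteforce <- function(image, n_bins = 256L) {
  rng <- range(image)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(image, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  p <- tabulate(bin, nbins = n_bins) / length(image)
  best_H <- -Inf; best_t <- NA_integer_
  for (t in seq_len(n_bins - 1L)) {
    P0 <- sum(p[1:t]); P1 <- 1 - P0
    if (P0 <= 0 || P1 <= 0) next
    H0 <- 0
    for (i in 1:t) if (p[i] > 0) H0 <- H0 - (p[i] / P0) * log(p[i] / P0)
    H1 <- 0
    for (i in (t + 1L):n_bins) if (p[i] > 0) {
      H1 <- H1 - (p[i] / P1) * log(p[i] / P1)
    }
    if (H0 + H1 > best_H) { best_H <- H0 + H1; best_t <- t }
  }
  breaks[best_t + 1L]
}

# Welch statistic, Welch-Satterthwaite df and one-tailed p from the closed
# forms, independent of stats::t.test.
welch_closed_form <- function(a, b, alternative = "greater") {
  va <- stats::var(a) / length(a); vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- if (alternative == "greater") stats::pt(t, df, lower.tail = FALSE)
  else stats::pt(t, df)
  list(t = t, df = df, p = p)
}

# analytic binary shapes on a pixel grid
disk_mask <- function(radius, pad = 10) {
  n <- 2 * (radius + pad)
  ctr <- (n + 1) / 2
  m <- matrix(FALSE, n, n)
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= radius^2] <- TRUE
  m
}

square_mask <- function(side, pad = 10) {
  n <- side + 2 * pad
  m <- matrix(FALSE, n, n)
  m[(pad + 1):(pad + side), (pad + 1):(pad + side)] <- TRUE
  m
}

# stadium (capsule) mask of total length `len` and width `wid`, rotated by
# `angle_deg` about the image center
stadium_mask <- function(len, wid, angle_deg = 0, pad = 15) {
  n <- len + 2 * pad
  ctr <- (n + 1) / 2
  th <- angle_deg * pi / 180
  half_seg <- (len - wid) / 2
  ax <- cos(th) * half_seg; ay <- sin(th) * half_seg
  rr <- row(matrix(0, n, n)) - ctr
  cc <- col(matrix(0, n, n)) - ctr
  # distance to the centerline segment between (-ay,-ax) and (ay,ax) in
  # (row, col) coordinates
  t_raw <- (rr * ay + cc * ax) / (half_seg^2)
  t_cl <- pmin(pmax(t_raw, -1), 1)
  d <- sqrt((rr - t_cl * ay)^2 + (cc - t_cl * ax)^2)
  d <= wid / 2
}

gri3d_cfg <- function(fill_overshoot = 1.0) {
  well_config("gri3d-24", set_volume = 1330, dead_volume = 150,
              fill_overshoot_fraction = fill_overshoot,
              empty_s = 90, fill_s = 270, level_s = 60)
}

nunc_cfg <- function() {
  well_config("standard-24", set_volume = 750, dead_volume = 0,
              empty_s = 45, fill_s = 75, level_s = 30)
}

two_input_cfg <- function(stock = 7.5) {
  pwm_config(list(stock = c(FITC = stock), buffer = numeric()))
}
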