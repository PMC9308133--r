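# ---- gastruloid segmentation and morphometry --------------------------------

#' Maximum-entropy (Kapur) threshold and mask
#'
#' Binarizes a grayscale image at the threshold maximizing the sum of the
#' Shannon entropies of the background and foreground histogram partitions
#' (Kapur's criterion), the 'MaxEntropy' method of common image-analysis
#' toolkits. The histogram has `n_bins` equal-width bins over the image
#' range; foreground is `> threshold` (or `< threshold` with
#' `invert = TRUE`), and only the largest connected component is retained.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @param invert Flip polarity for dark objects on bright background.
#' @return List with `threshold` (gray value) and `mask` (a
#'   `gastruloid_mask`).
#' @export
max_entropy_threshold <- function(image, n_bins = 256L, invert = FALSE) {
  rng <- range(image, na.rm = TRUE)
  if (diff(rng) == 0) stop("degenerate input: image is constant")
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(image, breaks,
                                            rightmost.closed = TRUE), 1L),
                          n_bins), nbins = n_bins)
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P0 <- cumsum(p); S0 <- cumsum(plogp)
  P1 <- 1 - P0;   S1 <- sum(plogp) - S0
  t_idx <- seq_len(n_bins - 1L)
  ok <- P0[t_idx] > 0 & P1[t_idx] > 0
  H <- rep(-Inf, n_bins - 1L)
  H[ok] <- (log(P0[t_idx][ok]) - S0[t_idx][ok] / P0[t_idx][ok]) +
    (log(P1[t_idx][ok]) - S1[t_idx][ok] / P1[t_idx][ok])
  t_best <- which.max(H)
  threshold <- breaks[t_best + 1L]           # upper edge of the best bin
  fg <- if (invert) image < threshold else image > threshold
  mask <- largest_component(fg)
  list(threshold = threshold,
       mask = structure(list(mask = mask, threshold = threshold),
                        class = "gastruloid_mask"))
}

# retain the largest 8-connected foreground component
largest_component <- function(fg) {
  fg[is.na(fg)] <- FALSE
  if (!any(fg)) stop("empty foreground after thresholding")
  labels <- EBImage::bwlabel(EBImage::Image(fg * 1))
  labels <- EBImage::imageData(labels)
  tab <- tabulate(labels[labels > 0])
  labels == which.max(tab)
}

#' Create a gastruloid mask from a binary matrix
#'
#' @param mask Logical or 0/1 matrix; the largest connected component is
#'   retained.
#' @param threshold Optional provenance threshold.
#' @return A `gastruloid_mask`.
#' @export
gastruloid_mask <- function(mask, threshold = NA_real_) {
  structure(list(mask = largest_component(mask > 0), threshold = threshold),
            class = "gastruloid_mask")
}

#' @export
print.gastruloid_mask <- function(x, ...) {
  cat(sprintf("<gastruloid_mask> %d x %d, %d foreground px, threshold %.6g\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$threshold))
  invisible(x)
}

#' Elongation index of a gastruloid mask
#'
#' Length over width: the maximum Feret diameter of the component (largest
#' distance between any two foreground pixels, taken over the convex hull)
#' divided by the diameter of the largest circle that fits inside the mask
#' (twice the maximum of the Euclidean distance transform). A disk scores 1,
#' a square scores sqrt(2) (diagonal over side), an elongated body > 1.
#'
#' @param mask A `gastruloid_mask` or binary matrix.
#' @return The elongation ratio (>= 1 up to discretization).
#' @export
elongation_index <- function(mask) {
  m <- if (inherits(mask, "gastruloid_mask")) mask$mask else mask > 0
  if (!any(m)) stop("empty mask")
  idx <- which(m, arr.ind = TRUE)
  hull <- idx[grDevices::chull(idx[, 1L], idx[, 2L]), , drop = FALSE]
  d2 <- outer(hull[, 1L], hull[, 1L], `-`)^2 +
    outer(hull[, 2L], hull[, 2L], `-`)^2
  feret <- sqrt(max(d2))
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(m * 1)))
  inscribed <- 2 * max(dm)
  if (inscribed <= 0) stop("degenerate mask: no interior")
  feret / inscribed
}

#' Define a gastruloid central-axis polyline
#'
#' @param vertices Two-column matrix of (row, col) vertices, ordered from
#'   the posterior pole to the anterior pole (>= 2 vertices).
#' @return An `axis_polyline` with the cumulative arc length attached.
#' @export
axis_polyline <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2L, nrow(vertices) >= 2L)
  seg <- sqrt(rowSums((vertices[-1L, , drop = FALSE] -
                         vertices[-nrow(vertices), , drop = FALSE])^2))
  if (sum(seg) <= 0) stop("degenerate axis: zero arc length")
  structure(list(vertices = vertices, arc_length_px = sum(seg)),
            class = "axis_polyline")
}

# exact nearest point on a polyline for a set of pixels: returns, per pixel,
# the perpendicular distance, the arc-length position of the nearest point,
# and whether the pixel projects beyond the first/last vertex
project_to_polyline <- function(px_row, px_col, vertices) {
  nseg <- nrow(vertices) - 1L
  seg_len <- sqrt(rowSums((vertices[-1L, , drop = FALSE] -
                             vertices[-nrow(vertices), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg_len))
  n <- length(px_row)
  best_d2 <- rep(Inf, n); best_arc <- numeric(n)
  beyond_start <- rep(FALSE, n); beyond_end <- rep(FALSE, n)
  for (i in seq_len(nseg)) {
    a <- vertices[i, ]; b <- vertices[i + 1L, ]
    ab <- b - a; len2 <- sum(ab^2)
    if (len2 == 0) next
    t_raw <- ((px_row - a[1L]) * ab[1L] + (px_col - a[2L]) * ab[2L]) / len2
    t <- pmin(pmax(t_raw, 0), 1)
    d2 <- (px_row - (a[1L] + t * ab[1L]))^2 +
      (px_col - (a[2L] + t * ab[2L]))^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cum[i] + t[upd] * seg_len[i]
    beyond_start[upd] <- i == 1L & t_raw[upd] < 0
    beyond_end[upd] <- i == nseg & t_raw[upd] > 1
  }
  list(dist = sqrt(best_d2), arc = best_arc, total = cum[nseg + 1L],
       beyond = beyond_start | beyond_end)
}

#' Axial expression profile along a gastruloid's central axis
#'
#' Partitions the axis into `n_segments` equal-arc-length segments and sums
#' the image intensity of every pixel lying within half the band width
#' (perpendicular distance) of the axis, assigning each pixel to the segment
#' of its nearest axis point; pixels beyond the axis poles are excluded and
#' no pixel is counted twice. The sums are then normalized to the
#' gastruloid's own maximum and the positions to its axis length (see
#' [normalize_profile()]).
#'
#' @param image Numeric intensity matrix.
#' @param axis An [axis_polyline()] (posterior pole first).
#' @param n_segments Number of segments (default 10).
#' @param band_width_px Total band width across the axis (default 80, i.e.
#'   40 px to each side).
#' @param id Optional gastruloid identifier carried into the profile.
#' @return An `axial_profile` (see [normalize_profile()]).
#' @export
axial_profile <- function(image, axis, n_segments = 10L, band_width_px = 80,
                          id = NA_character_) {
  stopifnot(inherits(axis, "axis_polyline"), n_segments >= 1L)
  v <- axis$vertices
  half <- band_width_px / 2
  r0 <- max(1L, floor(min(v[, 1L]) - half))
  r1 <- min(nrow(image), ceiling(max(v[, 1L]) + half))
  c0 <- max(1L, floor(min(v[, 2L]) - half))
  c1 <- min(ncol(image), ceiling(max(v[, 2L]) + half))
  if (r0 > r1 || c0 > c1) stop("axis lies outside the image")
  grid <- expand.grid(row = r0:r1, col = c0:c1)
  vals <- image[cbind(grid$row, grid$col)]
  pj <- project_to_polyline(grid$row, grid$col, v)
  keep <- pj$dist <= half & !pj$beyond
  seg_idx <- pmin(n_segments, 1L + floor(pj$arc / pj$total * n_segments))
  sums <- vapply(seq_len(n_segments), function(k) {
    sum(vals[keep & seg_idx == k])
  }, 0)
  normalize_profile(sums, pj$total, id = id)
}

#' Normalize raw axial segment sums into a profile
#'
#' Intensities are divided by the gastruloid's own maximum segment sum (so
#' the peak is 1) and positions are expressed as fractions of the axis
#' length: segment centers 0.05, 0.15, ..., 0.95 for ten segments, running
#' posterior to anterior.
#'
#' @param raw_sums Numeric vector of per-segment intensity sums.
#' @param axis_length_px Axis arc length in pixels.
#' @param id Optional gastruloid id.
#' @return An `axial_profile`: `positions`, `intensities` (max 1),
#'   `raw_sums`, `axis_length_px`, `id`.
#' @export
normalize_profile <- function(raw_sums, axis_length_px, id = NA_character_) {
  n <- length(raw_sums)
  if (max(raw_sums) <= 0) stop("all-zero profile cannot be normalized")
  structure(list(positions = (seq_len(n) - 0.5) / n,
                 intensities = raw_sums / max(raw_sums),
                 raw_sums = raw_sums, axis_length_px = axis_length_px,
                 id = id),
            class = "axial_profile")
}

#' @export
print.axial_profile <- function(x, ...) {
  cat(sprintf("<axial_profile> %s%d segments, axis %.4g px, peak at %.2f\n",
              if (!is.na(x$id)) paste0(x$id, ": ") else "",
              length(x$positions), x$axis_length_px,
              as.numeric(peak_position(x))))
  invisible(x)
}

#' Axial position of the expression peak
#'
#' The normalized position of the segment holding the maximal (raw, not
#' fitted) normalized intensity. Ties resolve to the smallest position, with
#' attribute `tie = TRUE`.
#'
#' @param profile An `axial_profile`.
#' @return Peak position in (0, 1) with logical attribute `tie`.
#' @export
peak_position <- function(profile) {
  stopifnot(inherits(profile, "axial_profile"))
  mx <- max(profile$intensities)
  hits <- which(abs(profile$intensities - mx) <= 1e-12)
  pos <- profile$positions[hits[1L]]
  attr(pos, "tie") <- length(hits) > 1L
  pos
}

#' Fit a condition-level polynomial to pooled axial profiles
#'
#' Pools the (position, intensity) points of all profiles of one condition
#' and fits a least-squares polynomial of the given degree; per-point
#' residuals (observed minus fitted at the same position) are returned.
#'
#' @param profiles List of `axial_profile`s (>= 1).
#' @param degree Polynomial degree (default 4); must be below the number of
#'   distinct positions.
#' @return A `condition_fit`: `coefficients` (ascending powers),
#'   `residuals`, `points` (pooled data frame), `degree`, `n_gastruloids`.
#' @export
fit_condition <- function(profiles, degree = 4L) {
  if (inherits(profiles, "axial_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L)
  pts <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(position = p$positions, intensity = p$intensities,
               id = p$id, stringsAsFactors = FALSE)
  }))
  if (degree >= length(unique(pts$position))) {
    stop("degree must be below the number of distinct positions")
  }
  fit <- if (degree == 0L) stats::lm(intensity ~ 1, data = pts) else
    stats::lm(intensity ~ poly(position, degree, raw = TRUE), data = pts)
  co <- unname(stats::coef(fit))
  structure(list(coefficients = co, residuals = unname(stats::resid(fit)),
                 points = pts, degree = degree,
                 n_gastruloids = length(profiles), fit = fit),
            class = "condition_fit")
}

#' Evaluate a condition fit at positions
#'
#' @param object A `condition_fit`.
#' @param positions Positions in `[0, 1]` (default the pooled positions).
#' @param ... Unused.
#' @return Fitted intensities.
#' @export
predict.condition_fit <- function(object, positions = NULL, ...) {
  if (is.null(positions)) positions <- object$points$position
  drop(outer(positions, 0:object$degree, `^`) %*% object$coefficients)
}

#' @export
print.condition_fit <- function(x, ...) {
  cat(sprintf(
    "<condition_fit> degree %d over %d gastruloid(s), RMS residual %.4g\n",
    x$degree, x$n_gastruloids, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Condition-level summary of peak positions
#'
#' The per-gastruloid peak positions are averaged; the mean is the summary
#' statistic of the condition, with the standard error of the mean.
#'
#' @param profiles List of `axial_profile`s (or precomputed numeric peak
#'   positions).
#' @return List with `mean`, `se` (0 with `se_defined = FALSE` when n = 1),
#'   `n`, and the per-gastruloid `peaks`.
#' @export
condition_peak_summary <- function(profiles) {
  peaks <- if (is.numeric(profiles)) profiles else
    vapply(profiles, function(p) as.numeric(peak_position(p)), 0)
  n <- length(peaks)
  stopifnot(n >= 1L)
  se <- if (n > 1L) stats::sd(peaks) / sqrt(n) else 0
  list(mean = mean(peaks), se = se, n = n, se_defined = n > 1L, peaks = peaks)
}

#' Welch's unpaired one-tailed t-test
#'
#' Heteroscedastic (unequal-variance) two-sample t-test with the
#' Welch-Satterthwaite degrees of freedom and a one-tailed p-value, the test
#' used for all condition comparisons.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @param alternative `"greater"` tests mean(a) > mean(b); `"less"` tests
#'   mean(a) < mean(b).
#' @return List with `t`, `df`, `p`.
#' @examples
#' welch_one_tailed(c(4, 5, 6), c(1, 2, 3), "greater")
#' @export
welch_one_tailed <- function(group_a, group_b,
                             alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    stop("zero variance in both groups")
  }
  ht <- stats::t.test(group_a, group_b, alternative = alternative,
                      var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

# ---- montage I/O ------------------------------------------------------------

#' Read gastruloid central axes from CSV
#'
#' @param path CSV with columns `id`, `row`, `col`; vertices ordered
#'   posterior pole first within each id.
#' @return Named list of [axis_polyline()]s.
#' @export
read_axes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "row", "col") %in% names(df)))
  lapply(split(df, factor(df$id, levels = unique(df$id))), function(d) {
    axis_polyline(cbind(d$row, d$col))
  })
}

#' Per-gastruloid morphometry table
#'
#' @param results Named list where each element has `elongation` (numeric)
#'   and `profile` (an `axial_profile`), e.g. from [analyze_gastruloid()].
#' @return Data frame with `id`, `elongation_index`, `peak_position`, and
#'   one column per profile segment.
#' @export
morphometry_table <- function(results) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    seg <- stats::setNames(as.list(r$profile$intensities),
                           sprintf("seg%02d", seq_along(r$profile$intensities)))
    cbind(data.frame(id = nm, elongation_index = r$elongation,
                     peak_position = as.numeric(peak_position(r$profile)),
                     stringsAsFactors = FALSE),
          as.data.frame(seg))
  })
  do.call(rbind, rows)
}

#' Analyze one gastruloid image
#'
#' Convenience wrapper: maximum-entropy segmentation, elongation index, and
#' the axial expression profile along a supplied central axis.
#'
#' @param image Numeric intensity matrix (corrected reporter channel).
#' @param axis An [axis_polyline()].
#' @param n_segments,band_width_px Passed to [axial_profile()].
#' @param id Gastruloid identifier.
#' @return List with `mask`, `elongation`, `profile`.
#' @export
analyze_gastruloid <- function(image, axis, n_segments = 10L,
                               band_width_px = 80, id = NA_character_) {
  th <- max_entropy_threshold(image)
  list(mask = th$mask,
       elongation = elongation_index(th$mask),
       profile = axial_profile(image, axis, n_segments, band_width_px, id))
}
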