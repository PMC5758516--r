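#' Resample a volume to a target grid spacing
#'
#' Resamples a 3D volume onto a uniform target spacing (default 0.5 x 0.5 mm
#' in plane, 3 mm through plane). Intensities are interpolated linearly;
#' label maps should use `method = "nearest"`. Output voxel centres are
#' aligned so that resampling to the input spacing is the identity.
#'
#' @param volume 3D numeric (or integer) array.
#' @param spacing input voxel spacing, mm triple.
#' @param target_spacing output spacing, mm triple.
#' @param method `"linear"` (intensities) or `"nearest"` (labels).
#' @return Array with attribute `spacing` set to `target_spacing`.
#' @export
resample_volume <- function(volume, spacing,
                            target_spacing = c(0.5, 0.5, 3.0),
                            method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (any(spacing <= 0) || any(target_spacing <= 0))
    abort("spacings must be positive")
  dims <- dim(volume)
  if (any(dims < 2)) abort("degenerate (single-voxel) axis cannot be resampled")
  out <- volume
  for (axis in 1:3) {
    n_in <- dim(out)[axis]
    n_out <- max(1L, as.integer(round(dims[axis] * spacing[axis] /
                                        target_spacing[axis])))
    # input (fractional) index of each output voxel centre
    x <- ((seq_len(n_out) - 0.5) * target_spacing[axis]) / spacing[axis] + 0.5
    x <- pmin(pmax(x, 1), n_in)
    out <- interp_axis(out, x, axis, method)
  }
  attr(out, "spacing") <- target_spacing
  out
}

# 1D interpolation of a 3D array along one axis at fractional indices x
interp_axis <- function(arr, x, axis, method) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  if (method == "nearest") {
    res <- m[pmin(pmax(round(x), 1), d[1]), , drop = FALSE]
  } else {
    i0 <- pmin(floor(x), d[1] - 1)
    w <- x - i0
    res <- m[i0, , drop = FALSE] * (1 - w) + m[i0 + 1, , drop = FALSE] * w
  }
  res <- array(res, dim = c(length(x), d[2], d[3]))
  aperm(res, order(perm))
}

#' Otsu threshold of a numeric vector
#'
#' Histogram-based two-class variance maximization; used to define the
#' foreground when no tissue mask is available.
#'
#' @param values numeric vector.
#' @param n_bins histogram resolution.
#' @return The threshold value; foreground is `values > threshold`.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  rng <- range(values)
  if (diff(rng) == 0) abort("constant input has no threshold")
  h <- tabulate(pmin(as.integer((values - rng[1]) / diff(rng) * n_bins) + 1L,
                     n_bins), n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * diff(rng) / n_bins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

default_landmark_percentiles <- function() c(1, seq(10, 90, 10), 99)

volume_foreground <- function(volume, mask = NULL) {
  v <- if (is.null(mask)) {
    thr <- otsu_threshold(as.numeric(volume))
    volume[volume > thr]
  } else {
    volume[mask]
  }
  if (length(v) == 0) abort("empty foreground")
  v
}

#' Fit a landmark intensity-standardization model
#'
#' MR intensities have no tissue-specific numeric meaning across scans; this
#' learns a common scale by the histogram-landmark method: per volume, the
#' foreground percentile landmarks are mapped affinely onto a fixed output
#' range, and the per-volume mapped landmarks are averaged into the standard
#' scale. Landmarks are order statistics (type-1 quantiles), which makes the
#' subsequent standardization exactly idempotent and exactly invariant to
#' affine intensity transforms of the input.
#'
#' @param volumes list of 3D arrays (one protocol).
#' @param masks optional list of logical foreground masks (same shapes);
#'   when absent, foreground is taken above the Otsu threshold.
#' @param percentiles landmark percentiles; default deciles plus 1st/99th.
#' @param output_range the fixed standard scale range, default `c(0, 4095)`.
#' @return A list of class `landmark_model` with `percentiles`,
#'   `standard_scale`, `output_range`.
#' @export
fit_landmark_model <- function(volumes, masks = NULL,
                               percentiles = default_landmark_percentiles(),
                               output_range = c(0, 4095)) {
  if (length(percentiles) < 3) abort("need at least 3 landmark percentiles")
  per_vol <- lapply(seq_along(volumes), function(i) {
    v <- volume_foreground(volumes[[i]], if (is.null(masks)) NULL else masks[[i]])
    q <- quantile(v, percentiles / 100, type = 1, names = FALSE)
    if (q[length(q)] == q[1]) abort("constant foreground: landmarks undefined")
    (q - q[1]) / (q[length(q)] - q[1]) * diff(output_range) + output_range[1]
  })
  scale <- colMeans(do.call(rbind, per_vol))
  if (any(diff(scale) <= 0))
    abort("standard scale landmarks are not strictly increasing")
  structure(list(percentiles = percentiles, standard_scale = scale,
                 output_range = output_range),
            class = "landmark_model")
}

#' Standardize a volume's intensities onto a landmark model
#'
#' Piecewise-linear mapping of the volume's own foreground landmarks onto the
#' model's standard scale, applied to every voxel; the end segments are
#' extended linearly beyond the tail landmarks. Monotone in the input
#' intensity.
#'
#' @param volume 3D array.
#' @param model a [fit_landmark_model()].
#' @param mask optional logical foreground mask used to compute the volume's
#'   landmarks.
#' @return Array of the same shape on the standard scale.
#' @export
standardize_intensity <- function(volume, model, mask = NULL) {
  v <- volume_foreground(volume, mask)
  q <- quantile(v, model$percentiles / 100, type = 1, names = FALSE)
  if (q[length(q)] == q[1]) abort("constant foreground: landmarks undefined")
  piecewise_linear(as.numeric(volume), q, model$standard_scale) |>
    array(dim = dim(volume))
}

# monotone piecewise-linear map with linear extrapolation of the end segments
piecewise_linear <- function(x, knots_in, knots_out) {
  keep <- c(TRUE, diff(knots_in) > 0)
  knots_in <- knots_in[keep]
  knots_out <- knots_out[keep]
  y <- stats::approx(knots_in, knots_out, xout = x, rule = 2, ties = "ordered")$y
  k <- length(knots_in)
  s_lo <- (knots_out[2] - knots_out[1]) / (knots_in[2] - knots_in[1])
  s_hi <- (knots_out[k] - knots_out[k - 1]) / (knots_in[k] - knots_in[k - 1])
  lo <- x < knots_in[1]
  hi <- x > knots_in[k]
  y[lo] <- knots_out[1] + (x[lo] - knots_in[1]) * s_lo
  y[hi] <- knots_out[k] + (x[hi] - knots_in[k]) * s_hi
  y
}
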