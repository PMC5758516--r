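#' Laws texture kernels
#'
#' The five 1D Laws vectors — level `L5`, edge `E5`, spot `S5`, wave `W5`,
#' ripple `R5` — and their symmetric 5x5 self-product kernels `L5L5` ...
#' `R5R5` used as the package's Laws energy bank.
#'
#' @return Named list with `vectors` (1D) and `kernels` (5x5 outer products).
#' @export
laws_kernels <- function() {
  v <- list(L5 = c(1, 4, 6, 4, 1),
            E5 = c(-1, -2, 0, 2, 1),
            S5 = c(-1, 0, 2, 0, -1),
            W5 = c(-1, 2, 0, -2, 1),
            R5 = c(1, -4, 6, -4, 1))
  k <- lapply(v, function(x) outer(x, x))
  names(k) <- paste0(names(v), names(v))
  list(vectors = v, kernels = k)
}

#' Per-pixel Laws energy maps
#'
#' Convolves the image with the five symmetric self-product Laws kernels
#' (L5L5, E5E5, S5S5, W5W5, R5R5; reflect padding) and returns the absolute
#' response (energy) per pixel.
#'
#' @param image2d numeric matrix.
#' @param mask2d optional logical matrix; out-of-mask pixels are set `NA` in
#'   the returned maps. An empty mask yields all-`NA` maps with a warning.
#' @return Named list of 5 matrices.
#' @export
laws_maps <- function(image2d, mask2d = NULL) {
  lk <- laws_kernels()
  maps <- lapply(lk$vectors, function(v) {
    abs(conv1d_reflect(conv1d_reflect(image2d, v, 1L), v, 2L))
  })
  names(maps) <- names(lk$kernels)
  apply_map_mask(maps, mask2d)
}

apply_map_mask <- function(maps, mask2d) {
  if (!is.null(mask2d)) {
    if (!any(mask2d)) warn("mask covers no pixel: all-missing maps")
    maps <- lapply(maps, function(m) { m[!mask2d] <- NA_real_; m })
  }
  maps
}

#' The 12-filter Gabor parameter bank
#'
#' Three frequencies (0, 4, 16 cycles per filter window) crossed with four
#' orientations (45, 90, 135, 180 degrees). Frequency 0 degenerates to the
#' pure Gaussian envelope — orientation-independent, but still emitted once
#' per orientation so the descriptor bank always has 12 stable names.
#'
#' @param frequencies cycles per filter window.
#' @param orientations degrees; direction of the carrier wave vector,
#'   measured from the image x-axis (columns) towards the y-axis (rows).
#' @param window odd filter window size in pixels.
#' @param sigma Gaussian envelope SD in pixels (default `window / 6`).
#' @return Tibble with columns `name`, `frequency`, `orientation`, `window`,
#'   `sigma`.
#' @export
gabor_bank <- function(frequencies = c(0, 4, 16),
                       orientations = c(45, 90, 135, 180),
                       window = 15, sigma = window / 6) {
  grid <- expand.grid(orientation = orientations, frequency = frequencies)
  tibble(name = sprintf("f%g_th%g", grid$frequency, grid$orientation),
         frequency = grid$frequency, orientation = grid$orientation,
         window = window, sigma = sigma)
}

#' Per-pixel Gabor energy maps
#'
#' Magnitude of the complex Gabor response — a complex sinusoid carrier
#' modulated by an isotropic Gaussian envelope — for each filter of the bank.
#' The separable complex kernel is applied with reflect padding.
#'
#' @inheritParams laws_maps
#' @param bank a [gabor_bank()].
#' @return Named list of `nrow(bank)` matrices.
#' @export
gabor_maps <- function(image2d, mask2d = NULL, bank = gabor_bank()) {
  maps <- vector("list", nrow(bank))
  names(maps) <- bank$name
  dc_at <- NA_integer_  # f = 0 is orientation-free: compute once, reuse
  for (i in seq_len(nrow(bank))) {
    if (bank$frequency[i] == 0 && !is.na(dc_at) &&
        bank$window[i] == bank$window[dc_at] &&
        bank$sigma[i] == bank$sigma[dc_at]) {
      maps[[i]] <- maps[[dc_at]]
      next
    }
    if (bank$frequency[i] == 0) dc_at <- i
    r <- (bank$window[i] - 1) / 2
    t <- seq(-r, r)
    env <- stats::dnorm(t, sd = bank$sigma[i])
    env <- env / sum(env)
    th <- bank$orientation[i] * pi / 180
    kx <- 2 * pi * bank$frequency[i] * cos(th) / bank$window[i]
    ky <- 2 * pi * bank$frequency[i] * sin(th) / bank$window[i]
    if (bank$frequency[i] == 0) {
      # Gaussian-envelope limit: real smoothing filter
      maps[[i]] <- abs(conv1d_reflect(conv1d_reflect(image2d, env, 2L),
                                      env, 1L))
    } else {
      # separable complex kernel: g(x, y) = [env(x) e^{i kx x}] [env(y) e^{i ky y}]
      a <- conv1d_reflect(image2d, env * cos(kx * t), 2L)
      b <- conv1d_reflect(image2d, env * sin(kx * t), 2L)
      re <- conv1d_reflect(a, env * cos(ky * t), 1L) -
        conv1d_reflect(b, env * sin(ky * t), 1L)
      im <- conv1d_reflect(a, env * sin(ky * t), 1L) +
        conv1d_reflect(b, env * cos(ky * t), 1L)
      maps[[i]] <- sqrt(re^2 + im^2)
    }
  }
  apply_map_mask(maps, mask2d)
}

#' Default GLCM parameters
#'
#' 64 gray levels by min-max quantization within the region of interest,
#' 11x11 window (radius 5), the four distance-1 offsets (0, 45, 90, 135
#' degrees) accumulated, symmetric counting.
#'
#' @param n_gray_levels number of quantization levels (>= 2).
#' @param window_radius half-width of the local window in pixels.
#' @param offsets integer matrix with columns `(drow, dcol)`.
#' @param symmetric count each pair in both directions.
#' @return List of class `glcm_params`.
#' @export
glcm_params <- function(n_gray_levels = 64L, window_radius = 5L,
                        offsets = rbind(c(0L, 1L), c(-1L, 1L),
                                        c(-1L, 0L), c(-1L, -1L)),
                        symmetric = TRUE) {
  if (n_gray_levels < 2) abort("need at least 2 gray levels")
  if (window_radius < 1) abort("window must cover at least 2x2 pixels")
  structure(list(n_gray_levels = as.integer(n_gray_levels),
                 window_radius = as.integer(window_radius),
                 offsets = offsets, symmetric = symmetric),
            class = "glcm_params")
}

#' Gray-level co-occurrence matrix of one quantized window
#'
#' Counts gray-level pairs at each displacement, accumulated over the
#' offsets, optionally symmetrized, normalized to sum 1. Pure pair
#' enumeration; levels are `0 .. n_levels - 1`.
#'
#' @param window integer matrix of quantized gray levels (`NA` = invalid).
#' @param offsets integer matrix with columns `(drow, dcol)`.
#' @param symmetric also count each reversed pair.
#' @param n_levels matrix size; defaults to `max(window) + 1`.
#' @return `n_levels` x `n_levels` matrix summing to 1.
#' @export
#' @examples
#' glcm(rbind(c(0, 0), c(1, 1)), offsets = cbind(0, 1))  # P(0,0)=P(1,1)=1/2
glcm <- function(window, offsets = rbind(c(0L, 1L)), symmetric = TRUE,
                 n_levels = NULL) {
  if (is.null(n_levels)) n_levels <- max(window, na.rm = TRUE) + 1L
  P <- matrix(0, n_levels, n_levels)
  nr <- nrow(window); nc <- ncol(window)
  for (o in seq_len(nrow(offsets))) {
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      i2 <- i + offsets[o, 1]; j2 <- j + offsets[o, 2]
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
      g1 <- window[i, j]; g2 <- window[i2, j2]
      if (is.na(g1) || is.na(g2)) next
      P[g1 + 1, g2 + 1] <- P[g1 + 1, g2 + 1] + 1
      if (symmetric) P[g2 + 1, g1 + 1] <- P[g2 + 1, g1 + 1] + 1
    }
  }
  tot <- sum(P)
  if (tot == 0) abort("no valid pixel pair for the given offsets")
  P / tot
}

haralick_descriptors <- function() {
  c("energy", "contrast", "correlation", "variance", "idm", "sum_average",
    "sum_variance", "sum_entropy", "entropy", "difference_variance",
    "difference_entropy", "imc1", "imc2")
}

#' Min-max quantization within a region of interest
#'
#' @param x numeric array/matrix.
#' @param roi logical mask defining the intensity range used.
#' @param n_levels number of output levels.
#' @return Integer array of levels `0 .. n_levels - 1` (constant ROI maps to
#'   level 0 everywhere).
#' @export
quantize_minmax <- function(x, roi, n_levels = 64L) {
  rng <- range(x[roi])
  q <- if (diff(rng) == 0) array(0L, dim = dim(x)) else {
    array(pmin(as.integer((x - rng[1]) / diff(rng) * n_levels), n_levels - 1L),
          dim = dim(x))
  }
  q[q < 0L] <- 0L
  q
}

#' Per-pixel Haralick texture maps
#'
#' For every in-mask pixel, accumulates the symmetrized GLCM of its local
#' window (only pairs with both endpoints inside the window and the mask) and
#' computes the 13 classical Haralick statistics: energy (angular second
#' moment), contrast, correlation, sum-of-squares variance, inverse
#' difference moment, sum average, sum variance, sum entropy, entropy,
#' difference variance, difference entropy, and the two information measures
#' of correlation. Pixels whose window yields no valid pair are `NA`.
#'
#' @param image2d numeric matrix (ignored if `quantized`).
#' @param mask2d logical matrix: region of interest.
#' @param params a [glcm_params()].
#' @param quantized if `TRUE`, `image2d` is already an integer matrix of
#'   levels `0 .. n_gray_levels - 1` (e.g. quantized over a 3D ROI).
#' @return Named list of 13 matrices.
#' @export
haralick_features <- function(image2d, mask2d, params = glcm_params(),
                              quantized = FALSE) {
  q <- if (quantized) image2d else
    quantize_minmax(image2d, mask2d, params$n_gray_levels)
  storage.mode(q) <- "integer"
  res <- haralick_maps_cpp(q, mask2d, params$n_gray_levels,
                           params$window_radius,
                           as.integer(params$offsets[, 1]),
                           as.integer(params$offsets[, 2]),
                           params$symmetric)
  maps <- lapply(seq_len(13), function(k) res[, , k])
  names(maps) <- haralick_descriptors()
  maps
}

#' Deterministic names of the 270-feature radiomic vector
#'
#' Protocol-major order (Gd-T1w, T2w, FLAIR), then compartment (necrosis,
#' enhancing, edema), then family (laws, gabor, haralick), then descriptor:
#' `<protocol>__<compartment>__<family>__<descriptor>`.
#'
#' @return Character vector of length 270.
#' @export
feature_names <- function() {
  descr <- c(paste0("laws__", names(laws_kernels()$kernels)),
             paste0("gabor__", gabor_bank()$name),
             paste0("haralick__", haralick_descriptors()))
  unlist(lapply(.protocols, function(p)
    lapply(names(.compartments), function(cc)
      paste(p, cc, descr, sep = "__"))), use.names = FALSE)
}

#' Extract the 270-feature radiomic vector of one study
#'
#' For each protocol and tumor compartment, computes the 30 per-pixel texture
#' maps (5 Laws energy, 12 Gabor, 13 Haralick) on every axial slice where the
#' compartment appears, pools the in-mask per-pixel responses across slices,
#' and takes the median — 30 scalars per (protocol, compartment), 270 per
#' study. Haralick quantization is min-max over the compartment's full 3D
#' region so all slices share gray levels. A compartment absent everywhere
#' yields `NA` for its 90 features.
#'
#' @param study a [generate_phantom_study()]-shaped study (fields `volumes`,
#'   `labelmap`).
#' @param volumes optional named list of preprocessed/standardized volumes to
#'   use instead of `study$volumes`.
#' @param params a [glcm_params()].
#' @param bank a [gabor_bank()].
#' @return Named numeric vector of length 270 (order of [feature_names()]).
#' @export
extract_study_features <- function(study, volumes = NULL,
                                   params = glcm_params(),
                                   bank = gabor_bank()) {
  if (is.null(volumes)) volumes <- study$volumes
  lab <- study$labelmap
  pad <- max((max(bank$window) - 1) / 2, params$window_radius)
  out <- setNames(rep(NA_real_, 270), feature_names())
  descr_laws <- paste0("laws__", names(laws_kernels()$kernels))
  descr_gab <- paste0("gabor__", bank$name)
  descr_har <- paste0("haralick__", haralick_descriptors())

  for (p in .protocols) {
    vol <- volumes[[p]]
    qvols <- lapply(names(.compartments), function(cc) {
      roi <- lab == .compartments[[cc]]
      if (any(roi)) quantize_minmax(vol, roi, params$n_gray_levels) else NULL
    })
    names(qvols) <- names(.compartments)
    pool <- list()  # per feature-name list of pooled pixel values
    for (z in seq_len(dim(lab)[3])) {
      labz <- lab[, , z]
      if (!any(labz > 0)) next
      rr <- range(which(rowSums(labz > 0) > 0))
      cr <- range(which(colSums(labz > 0) > 0))
      rows <- max(1, rr[1] - pad):min(nrow(labz), rr[2] + pad)
      cols <- max(1, cr[1] - pad):min(ncol(labz), cr[2] + pad)
      img <- vol[rows, cols, z]
      labc <- labz[rows, cols]
      lmaps <- laws_maps(img)
      gmaps <- gabor_maps(img, bank = bank)
      for (cc in names(.compartments)) {
        m <- labc == .compartments[[cc]]
        if (!any(m)) next
        for (k in seq_along(lmaps)) {
          nm <- paste(p, cc, descr_laws[k], sep = "__")
          pool[[nm]] <- c(pool[[nm]], lmaps[[k]][m])
        }
        for (k in seq_along(gmaps)) {
          nm <- paste(p, cc, descr_gab[k], sep = "__")
          pool[[nm]] <- c(pool[[nm]], gmaps[[k]][m])
        }
        hmaps <- haralick_features(qvols[[cc]][rows, cols, z], m, params,
                                   quantized = TRUE)
        for (k in seq_along(hmaps)) {
          nm <- paste(p, cc, descr_har[k], sep = "__")
          v <- hmaps[[k]][m]
          pool[[nm]] <- c(pool[[nm]], v[!is.nan(v)])
        }
      }
    }
    for (nm in names(pool)) out[nm] <- median(pool[[nm]], na.rm = TRUE)
  }
  out
}

#' Extract the cohort feature table
#'
#' Applies [extract_study_features()] to every study and assembles the
#' studies x 270 feature table, with identifier and split columns.
#'
#' @param cohort a [generate_cohort()] result with images, or a list of
#'   studies.
#' @param standardize if `TRUE`, landmark-standardize each protocol across
#'   the cohort first (model fitted on the training split, foreground = union
#'   of the three compartments).
#' @param params,bank texture parameters, see [extract_study_features()].
#' @return Tibble: `patient_id`, `split`, then the 270 feature columns.
#' @export
extract_cohort_features <- function(cohort, standardize = TRUE,
                                    params = glcm_params(),
                                    bank = gabor_bank()) {
  studies <- if (inherits(cohort, "synthetic_cohort")) cohort$studies else cohort
  splits <- if (inherits(cohort, "synthetic_cohort"))
    cohort$clinical$split else rep("train", length(studies))
  models <- NULL
  if (standardize) {
    train_idx <- which(splits == "train")
    if (length(train_idx) == 0) train_idx <- seq_along(studies)
    models <- lapply(.protocols, function(p) {
      fit_landmark_model(
        lapply(studies[train_idx], function(s) s$volumes[[p]]),
        lapply(studies[train_idx], function(s) s$labelmap > 0))
    })
    names(models) <- .protocols
  }
  rows <- lapply(seq_along(studies), function(i) {
    st <- studies[[i]]
    vols <- if (standardize) {
      lapply(setNames(.protocols, .protocols), function(p)
        standardize_intensity(st$volumes[[p]], models[[p]],
                              mask = st$labelmap > 0))
    } else NULL
    fv <- extract_study_features(st, volumes = vols, params = params,
                                 bank = bank)
    bind_cols_feature_row(st$patient_id, splits[i], fv)
  })
  bind_rows(rows)
}

bind_cols_feature_row <- function(id, split, fv) {
  as_tibble(c(list(patient_id = id, split = split), as.list(fv)))
}

#' Impute missing features with training-split medians
#'
#' Features can be missing when a compartment is absent from a study. They
#' are imputed with the per-feature median over the training split; the
#' number of imputed cells is reported in a message.
#'
#' @param feature_table an [extract_cohort_features()] tibble.
#' @return The table with `NA` feature cells filled.
#' @export
impute_features <- function(feature_table) {
  cols <- intersect(feature_names(), names(feature_table))
  train <- feature_table$split == "train"
  n_imp <- 0L
  for (cc in cols) {
    miss <- is.na(feature_table[[cc]])
    if (any(miss)) {
      feature_table[[cc]][miss] <- median(feature_table[[cc]][train], na.rm = TRUE)
      n_imp <- n_imp + sum(miss)
    }
  }
  if (n_imp > 0) message(sprintf("imputed %d missing feature value(s)", n_imp))
  feature_table
}
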