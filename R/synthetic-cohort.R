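#' Configuration for a synthetic radiogenomic cohort
#'
#' Collects every tunable of the synthetic cohort generator: cohort size and
#' train/validation split, the latent hypoxia range, expression and survival
#' generative parameters, and the phantom image geometry. Defaults emulate the
#' shape of a 115-study GBM cohort split 85/30 with overall-survival groups cut
#' at 7 and 16 months.
#'
#' The survival generator is Weibull with shape `weibull_shape` and scale
#' `weibull_scale * exp(-weibull_decay * h)` months, so the hazard increases
#' with the latent hypoxia level `h`; `age_effect` adds an independent clinical
#' signal through the scale (per standard deviation of age).
#'
#' @param n_studies total number of studies (default 115).
#' @param n_train number of training studies; the remainder is the held-out
#'   validation split (default 85).
#' @param hypoxia_latent_range interval on \[0,1\] from which the latent
#'   hypoxia level is drawn uniformly.
#' @param n_background_genes number of null background genes in the expression
#'   matrix (default 200).
#' @param expression_effect_size mean shift (in units of the per-gene SD) of
#'   the hypoxia genes at `h = 1` relative to `h = 0` (default 3).
#' @param survival_cutoffs_months OS cuts for the STS/MTS/LTS grouping
#'   (default `c(7, 16)`).
#' @param censoring_rate fraction of subjects independently censored.
#' @param weibull_shape,weibull_scale,weibull_decay survival generative law
#'   parameters (months).
#' @param age_effect log-scale survival effect per SD of age (0 disables).
#' @param voxel_spacing_mm voxel spacing of generated volumes, mm.
#' @param volume_shape integer triple of voxel dimensions.
#' @param seed integer master seed; every study derives its own stream from it.
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_studies = 6, n_train = 4, volume_shape = c(32, 32, 8))
cohort_config <- function(n_studies = 115L,
                          n_train = 85L,
                          hypoxia_latent_range = c(0, 1),
                          n_background_genes = 200L,
                          expression_effect_size = 3,
                          survival_cutoffs_months = c(7, 16),
                          censoring_rate = 0.1,
                          weibull_shape = 1.8,
                          weibull_scale = 40,
                          weibull_decay = 1.8,
                          age_effect = 0.15,
                          voxel_spacing_mm = c(0.5, 0.5, 3.0),
                          volume_shape = c(96L, 96L, 24L),
                          seed = 1L) {
  if (n_studies <= 0 || n_train <= 0 || n_background_genes <= 0)
    abort("all counts must be positive")
  if (n_train >= n_studies)
    abort("n_train must be smaller than n_studies")
  if (length(survival_cutoffs_months) != 2 ||
      diff(survival_cutoffs_months) <= 0)
    abort("survival cutoffs must be two strictly increasing values")
  if (censoring_rate < 0 || censoring_rate >= 1)
    abort("censoring_rate must lie in [0, 1)")
  if (hypoxia_latent_range[1] < 0 || hypoxia_latent_range[2] > 1 ||
      diff(hypoxia_latent_range) < 0)
    abort("hypoxia_latent_range must be an interval within [0, 1]")
  structure(list(
    n_studies = as.integer(n_studies),
    n_train = as.integer(n_train),
    hypoxia_latent_range = hypoxia_latent_range,
    n_background_genes = as.integer(n_background_genes),
    expression_effect_size = expression_effect_size,
    survival_cutoffs_months = survival_cutoffs_months,
    censoring_rate = censoring_rate,
    weibull_shape = weibull_shape,
    weibull_scale = weibull_scale,
    weibull_decay = weibull_decay,
    age_effect = age_effect,
    voxel_spacing_mm = voxel_spacing_mm,
    volume_shape = as.integer(volume_shape),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# per-study reproducible stream derived from (master seed, study index)
study_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + 7919 * as.double(i)) %% 2147483647)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# 2D Gaussian smoothing of every axial slice of a 3D array
smooth_slices <- function(vol, sigma) {
  k <- gaussian_kernel_1d(sigma)
  for (z in seq_len(dim(vol)[3])) {
    s <- conv1d_reflect(vol[, , z], k, 1L)
    vol[, , z] <- conv1d_reflect(s, k, 2L)
  }
  vol
}

# normalized ellipsoid "radius" field for a volume shape
ellipsoid_field <- function(shape, center, semi) {
  x <- (seq_len(shape[1]) - center[1]) / semi[1]
  y <- (seq_len(shape[2]) - center[2]) / semi[2]
  z <- (seq_len(shape[3]) - center[3]) / semi[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

# protocol x tissue mean intensities (rows: bg, necrosis, enhancing, edema);
# necrosis hypointense on GdT1w, edema hyperintense on FLAIR
.phantom_means <- rbind(
  GdT1w = c(bg = 40, necrosis = 80, enhancing = 200, edema = 120),
  T2w   = c(bg = 60, necrosis = 180, enhancing = 140, edema = 160),
  FLAIR = c(bg = 70, necrosis = 90, enhancing = 160, edema = 220)
)

# texture-planting law: correlation length shrinks and amplitude grows with h,
# in the enhancing and edema compartments only (necrosis stays fixed)
texture_params <- function(h, compartment) {
  if (compartment %in% c("enhancing", "edema")) {
    list(sigma = 3.2 - 2.6 * h, sd = 6 * (1 + 2 * h))
  } else {
    list(sigma = 1.4, sd = 6)
  }
}

#' Generate one multi-contrast tumor phantom study
#'
#' Builds three co-registered volumes (Gd-T1w, T2w, FLAIR) containing a tumor
#' of three nested ellipsoidal compartments — necrotic core (label 1),
#' enhancing rim (2), edema/nonenhancing halo (3) — on a background of 0.
#' Intra-compartment texture is Gaussian-filtered white noise whose amplitude
#' increases, and correlation length decreases, with the latent hypoxia level
#' `h` in the enhancing and edema compartments; i.i.d. scanner noise is added
#' everywhere.
#'
#' @param h latent hypoxia level in \[0,1\].
#' @param config a [cohort_config()].
#' @param seed integer seed for this study's private stream.
#' @param patient_id identifier stored with the study.
#' @return A list of class `phantom_study` with elements `patient_id`,
#'   `volumes` (named list of 3D arrays), `labelmap`, `spacing`, `latent_h`.
#' @export
generate_phantom_study <- function(h, config = cohort_config(), seed = config$seed,
                                   patient_id = "SYN-001") {
  if (h < 0 || h > 1) abort("h must lie in [0, 1]")
  set.seed(seed)
  shape <- config$volume_shape
  frac <- list(necrosis = c(0.105, 0.085, 0.125),
               enhancing = c(0.21, 0.17, 0.23),
               edema = c(0.34, 0.28, 0.34))
  jit <- runif(3, 0.85, 1.15)
  center <- shape / 2 + runif(3, -0.02, 0.02) * shape
  semi <- lapply(frac, function(f) f * shape * jit)
  if (any(semi$necrosis < 1))
    abort("volume too small to contain the three nested compartments")

  lab <- array(0L, dim = shape)
  for (nm in c("edema", "enhancing", "necrosis")) {  # inner overwrites outer
    inside <- ellipsoid_field(shape, center, semi[[nm]]) <= 1
    lab[inside] <- .compartments[[nm]]
  }
  if (!all(1:3 %in% lab))
    abort("volume too small to contain the three nested compartments")

  vols <- list()
  for (p in .protocols) {
    base <- .phantom_means[p, "bg"] + array(0, dim = shape)
    for (nm in names(.compartments)) {
      base[lab == .compartments[[nm]]] <- .phantom_means[p, nm]
    }
    for (nm in names(.compartments)) {
      tp <- texture_params(h, nm)
      idx <- lab == .compartments[[nm]]
      white <- array(rnorm(prod(shape)), dim = shape)
      field <- smooth_slices(white, tp$sigma)
      s_hat <- sd(field[idx])
      base[idx] <- base[idx] + field[idx] / s_hat * tp$sd
    }
    base <- base + array(rnorm(prod(shape), sd = 1.5), dim = shape)
    vols[[p]] <- base
  }
  structure(list(patient_id = patient_id, volumes = vols, labelmap = lab,
                 spacing = config$voxel_spacing_mm, latent_h = h),
            class = "phantom_study")
}

#' Generate one synthetic expression profile
#'
#' Hypoxia-signature genes are drawn `Normal(mu0 + effect_size * h, sigma)`,
#' background genes `Normal(mu0, sigma)`, mimicking a z-scored microarray
#' profile in which the hypoxia pathway shifts coordinately with the latent
#' hypoxia level.
#'
#' @param h latent hypoxia level in \[0,1\].
#' @param hypoxia_genes character vector of signature gene symbols (default:
#'   the packaged 21-gene set, see [hypoxia_geneset()]).
#' @param n_background number of null background genes.
#' @param effect_size shift at `h = 1` in units of `sigma`.
#' @param mu0,sigma baseline mean and SD of every gene.
#' @return Named numeric vector of length `length(hypoxia_genes) + n_background`.
#' @export
generate_expression <- function(h, hypoxia_genes = hypoxia_geneset(),
                                n_background = 200L, effect_size = 3,
                                mu0 = 8, sigma = 1) {
  if (n_background <= 0) abort("n_background must be positive")
  hyp <- rnorm(length(hypoxia_genes), mu0 + effect_size * h, sigma)
  bg <- rnorm(n_background, mu0, sigma)
  setNames(c(hyp, bg),
           c(hypoxia_genes, sprintf("BG%04d", seq_len(n_background))))
}

#' Generate one synthetic survival outcome
#'
#' Overall survival is Weibull with scale decreasing exponentially in the
#' latent hypoxia level, planting the hypoxia-to-poor-survival direction;
#' subjects are independently censored at the configured rate (a censored
#' subject's observed time is uniform on (0, OS\]).
#'
#' @param h latent hypoxia level in \[0,1\].
#' @param config a [cohort_config()].
#' @param lp_extra additional log-scale linear predictor (e.g. a clinical
#'   covariate effect); positive values shorten survival.
#' @return List with `os_months` (> 0) and `event` (1 = death observed).
#' @export
generate_survival <- function(h, config = cohort_config(), lp_extra = 0) {
  if (h < 0 || h > 1) abort("h must lie in [0, 1]")
  scale <- config$weibull_scale * exp(-config$weibull_decay * h - lp_extra)
  os <- rweibull(1, shape = config$weibull_shape, scale = scale)
  event <- 1L
  if (runif(1) < config$censoring_rate) {
    os <- os * runif(1)
    event <- 0L
  }
  list(os_months = max(os, 1e-3), event = event)
}

#' Assign the short/mid/long-term survival group
#'
#' @param os_months positive overall survival in months (vectorized).
#' @param cutoffs the two group cuts in months; OS at or below the first cut is
#'   `STS`, above the second is `LTS`, otherwise `MTS`.
#' @return Factor with ordered levels `STS`, `MTS`, `LTS`.
#' @export
#' @examples
#' assign_survival_group(c(3.9, 7, 16, 29.8))
assign_survival_group <- function(os_months, cutoffs = c(7, 16)) {
  if (any(os_months <= 0)) abort("os_months must be positive")
  factor(ifelse(os_months <= cutoffs[1], "STS",
                ifelse(os_months > cutoffs[2], "LTS", "MTS")),
         levels = c("STS", "MTS", "LTS"))
}

#' Generate a synthetic radiogenomic cohort
#'
#' Draws a latent hypoxia level for every study and generates, per study, the
#' three phantom MR volumes with a compartment label map, an expression
#' profile, a survival outcome and clinical covariates, all through a chain in
#' which hypoxia drives texture, expression and hazard. The first
#' `config$n_train` studies form the training split.
#'
#' @param config a [cohort_config()].
#' @param images if `FALSE`, skip phantom image generation (clinical and
#'   expression only); the `studies` element is then `NULL`.
#' @return A list of class `synthetic_cohort`:
#'   * `studies`: list of [generate_phantom_study()] results (or `NULL`),
#'   * `clinical`: tibble (patient_id, split, os_months, event, group, age,
#'     sex, kps, latent_h),
#'   * `expression`: genes x samples matrix,
#'   * `truth`: list with the planted hypoxia gene symbols and generator
#'     parameters,
#'   * `config`: the configuration used.
#' @export
generate_cohort <- function(config = cohort_config(), images = TRUE) {
  set.seed(config$seed)
  n <- config$n_studies
  h <- runif(n, config$hypoxia_latent_range[1], config$hypoxia_latent_range[2])
  ids <- sprintf("SYN-%03d", seq_len(n))
  hyp_genes <- hypoxia_geneset()

  studies <- vector("list", n)
  expr <- matrix(NA_real_, nrow = length(hyp_genes) + config$n_background_genes,
                 ncol = n)
  clin <- vector("list", n)
  for (i in seq_len(n)) {
    si <- study_seed(config$seed, i)
    if (images) {
      studies[[i]] <- generate_phantom_study(h[i], config, seed = si,
                                             patient_id = ids[i])
    } else {
      set.seed(si)
    }
    # clinical covariates and outcome share the study stream
    age <- min(max(rnorm(1, 58.4, 12.56), 25), 85)
    sex <- if (runif(1) < 69 / 115) "M" else "F"
    kps <- round(min(max(90 - 18 * h[i] + rnorm(1, 0, 8), 40), 100) / 10) * 10
    ex <- generate_expression(h[i], hyp_genes, config$n_background_genes,
                              config$expression_effect_size)
    sv <- generate_survival(h[i], config,
                            lp_extra = config$age_effect * (age - 58.4) / 12.56)
    expr[, i] <- ex
    if (i == 1) rownames(expr) <- names(ex)
    clin[[i]] <- tibble(
      patient_id = ids[i],
      split = if (i <= config$n_train) "train" else "validation",
      os_months = sv$os_months, event = sv$event,
      age = age, sex = sex, kps = kps, latent_h = h[i]
    )
  }
  colnames(expr) <- ids
  clinical <- bind_rows(clin)
  clinical$group <- assign_survival_group(clinical$os_months,
                                          config$survival_cutoffs_months)
  structure(list(
    studies = if (images) studies else NULL,
    clinical = clinical,
    expression = expr,
    truth = list(hypoxia_genes = hyp_genes,
                 planted_compartments = c("enhancing", "edema"),
                 latent_h = setNames(h, ids)),
    config = config
  ), class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes per-study NIfTI volumes (`<id>_GdT1w.nii.gz` etc.) and the
#' compartment label map (`<id>_seg.nii.gz`), plus cohort-level
#' `clinical.tsv`, `expression.tsv`, `hypoxia_genes.gmt` and a JSON ground
#' truth record.
#'
#' @param cohort a [generate_cohort()] result (with images).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cohort$studies)) {
    hdr <- list(pixdim = c(-1, cohort$config$voxel_spacing_mm, 0, 0, 0, 0))
    for (st in cohort$studies) {
      for (p in names(st$volumes)) {
        img <- RNifti::asNifti(st$volumes[[p]], reference = hdr)
        RNifti::writeNifti(img, file.path(dir, paste0(st$patient_id, "_", p, ".nii.gz")))
      }
      seg <- RNifti::asNifti(st$labelmap, reference = hdr, datatype = "int16")
      RNifti::writeNifti(seg, file.path(dir, paste0(st$patient_id, "_seg.nii.gz")))
    }
  }
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expr <- data.frame(gene = rownames(cohort$expression), cohort$expression,
                     check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(list(hypoxia = cohort$truth$hypoxia_genes),
            file.path(dir, "hypoxia_genes.gmt"))
  jsonlite::write_json(
    list(hypoxia_genes = cohort$truth$hypoxia_genes,
         planted_compartments = cohort$truth$planted_compartments,
         latent_h = as.list(cohort$truth$latent_h)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
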