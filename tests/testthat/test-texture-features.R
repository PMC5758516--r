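test_that("Laws kernels respond as their structure dictates", {
  lk <- laws_kernels()
  expect_equal(sum(lk$kernels$L5L5), 256)
  for (nm in c("E5E5", "S5S5", "W5W5", "R5R5"))
    expect_equal(sum(lk$kernels[[nm]]), 0)
  # constant image: zero-sum kernels respond 0, L5L5 responds 256 x intensity
  m <- matrix(7, 11, 11)
  maps <- laws_maps(m)
  expect_equal(maps$L5L5[6, 6], 256 * 7)
  for (nm in c("E5E5", "S5S5", "W5W5", "R5R5"))
    expect_lt(max(maps[[nm]]), 1e-9)
  # unit impulse reproduces the (mirrored) kernel
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  got <- laws_maps(imp)$E5E5[6:10, 6:10]
  expect_equal(got, abs(lk$kernels$E5E5[5:1, 5:1]), tolerance = 1e-12)
  # vertical step edge: E5E5 energy maximal at the edge, zero far away
  step <- cbind(matrix(0, 15, 8), matrix(10, 15, 7))
  e <- laws_maps(step)$E5E5
  expect_equal(which.max(e[8, ]), 8, tolerance = 1)
  expect_lt(max(e[, c(1:5, 12:15)]), 1e-9)
})

test_that("Gabor bank has 12 orientation/frequency-stable descriptors", {
  bank <- gabor_bank()
  expect_equal(nrow(bank), 12)
  img <- matrix(rnorm(900), 30, 30)
  maps <- gabor_maps(img, bank = bank)
  expect_named(maps, bank$name)
  # f = 0 collapses to the Gaussian envelope, identical across orientations
  expect_lt(max(abs(maps$f0_th45 - maps$f0_th180)), 1e-9)
  expect_lt(max(abs(maps$f0_th90 - maps$f0_th135)), 1e-9)
  # a grating matching (f = 4, theta = 90) excites that filter selectively
  t <- 1:30
  grating <- outer(t, t, function(y, x) sin(2 * pi * 4 / 15 * y))
  gm <- gabor_maps(grating, bank = bank)
  expect_gt(mean(gm$f4_th90), 10 * mean(gm$f4_th180))
})

test_that("GLCM accumulation matches hand enumeration", {
  P <- glcm(rbind(c(0, 0), c(1, 1)), offsets = cbind(0L, 1L), symmetric = TRUE)
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  # normalization and the constant-window degenerate case
  set.seed(1)
  w <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
  expect_equal(sum(glcm(w, offsets = rbind(c(0L, 1L), c(-1L, 0L)))), 1)
  Pc <- glcm(matrix(2L, 3, 3), offsets = cbind(0L, 1L))
  expect_equal(Pc[3, 3], 1)
  expect_equal(sum(Pc), 1)
  expect_error(glcm(matrix(0L, 1, 1), offsets = cbind(0L, 1L)), "pair")
})

test_that("Haralick maps match closed forms on degenerate patterns", {
  # constant image: single-entry GLCM
  h <- haralick_features(matrix(3, 9, 9), matrix(TRUE, 9, 9),
                         glcm_params(n_gray_levels = 8, window_radius = 2))
  expect_equal(h$entropy[5, 5], 0)
  expect_equal(h$energy[5, 5], 1)
  expect_equal(h$idm[5, 5], 1)
  expect_equal(h$contrast[5, 5], 0)
  # checkerboard, offset (0,1) symmetric: all mass on the two off-diagonals
  cb <- outer(1:9, 1:9, function(i, j) (i + j) %% 2)
  p <- glcm_params(n_gray_levels = 2, window_radius = 2,
                   offsets = cbind(0L, 1L))
  hcb <- haralick_features(cb, matrix(TRUE, 9, 9), p)
  expect_equal(hcb$contrast[5, 5], 1)
  expect_equal(hcb$energy[5, 5], 0.5)
  # entropy >= 0 and energy in (0, 1] wherever defined
  set.seed(2)
  img <- matrix(runif(144), 12, 12)
  hr <- haralick_features(img, matrix(TRUE, 12, 12),
                          glcm_params(n_gray_levels = 8, window_radius = 2))
  expect_true(all(hr$entropy >= 0))
  expect_true(all(hr$energy > 0 & hr$energy <= 1))
})

test_that("per-pixel GLCM features match brute-force pair enumeration", {
  set.seed(42)
  p <- glcm_params(n_gray_levels = 8, window_radius = 2)
  for (rep in seq_len(20)) {
    img <- matrix(runif(256), 16, 16)
    mask <- matrix(runif(256) > 0.15, 16, 16)
    got <- simplify2array(haralick_features(img, mask, p))
    dimnames(got) <- NULL
    q <- quantize_minmax(img, mask, 8)
    want <- oracle_haralick(q, mask, 8, 2, p$offsets, TRUE)
    expect_identical(is.na(got), is.na(want))
    expect_lt(max(abs(got - want), na.rm = TRUE), 1e-10)
  }
})

test_that("texture maps respect their symmetries", {
  set.seed(3)
  img <- matrix(runif(400, 10, 40), 20, 20)
  mask <- matrix(runif(400) > 0.2, 20, 20)
  rot <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  # 180-degree rotation leaves Laws energies unchanged
  l1 <- laws_maps(img)
  l2 <- laws_maps(rot(img))
  for (nm in names(l1)) expect_lt(max(abs(rot(l2[[nm]]) - l1[[nm]])), 1e-9)
  # ... and Haralick maps (symmetrized GLCM, point-symmetric offset set)
  p <- glcm_params(n_gray_levels = 8, window_radius = 2)
  h1 <- simplify2array(haralick_features(img, mask, p))
  h2 <- simplify2array(haralick_features(rot(img), rot(mask), p))
  h2r <- aperm(apply(h2, 3, rot, simplify = FALSE) |> simplify2array(), c(1, 2, 3))
  expect_lt(max(abs(h1 - h2r), na.rm = TRUE), 1e-9)
  # adding a constant changes neither Haralick (min-max quantization) nor
  # the zero-sum Laws responses
  h3 <- simplify2array(haralick_features(img + 57.3, mask, p))
  expect_lt(max(abs(h1 - h3), na.rm = TRUE), 1e-9)
  l3 <- laws_maps(img + 57.3)
  for (nm in c("E5E5", "S5S5", "W5W5", "R5R5"))
    expect_lt(max(abs(l1[[nm]] - l3[[nm]])), 1e-6)
})

test_that("study extraction yields the full deterministic feature census", {
  nm <- feature_names()
  expect_length(nm, 270)
  parts <- strsplit(nm, "__")
  expect_true(all(lengths(parts) == 4))
  tab <- table(vapply(parts, `[`, character(1), 1),
               vapply(parts, `[`, character(1), 2))
  expect_true(all(tab == 30))
  fam <- table(vapply(parts, `[`, character(1), 3))
  expect_equal(as.numeric(fam[c("laws", "gabor", "haralick")]) / 9, c(5, 12, 13))

  st <- generate_phantom_study(0.6, small_config(), seed = 9)
  fv <- extract_study_features(st)
  expect_identical(names(fv), nm)
  expect_true(all(is.finite(fv)))
})

test_that("absent compartments flag their features missing and impute", {
  st <- generate_phantom_study(0.4, small_config(), seed = 10)
  st$labelmap[st$labelmap == 1L] <- 2L  # remove necrosis entirely
  fv <- extract_study_features(st)
  miss <- is.na(fv)
  expect_equal(sum(miss), 90)
  expect_true(all(grepl("__necrosis__", names(fv)[miss])))
  # imputation fills from training medians
  ok <- extract_study_features(generate_phantom_study(0.4, small_config(),
                                                      seed = 11))
  tab <- dplyr::bind_rows(
    tibble::as_tibble(c(list(patient_id = "a", split = "train"), as.list(ok))),
    tibble::as_tibble(c(list(patient_id = "b", split = "validation"),
                        as.list(fv))))
  expect_message(out <- impute_features(tab), "90")
  expect_false(anyNA(out[, feature_names()]))
})

test_that("enhancing-compartment entropy tracks the latent hypoxia level", {
  cfg <- small_config(shape = c(48L, 48L, 12L))
  h <- seq(0.02, 0.98, length.out = 30)
  ent <- vapply(seq_along(h), function(i) {
    st <- generate_phantom_study(h[i], cfg, seed = 400 + i)
    fv <- extract_study_features(st)
    fv[["GdT1w__enhancing__haralick__entropy"]]
  }, numeric(1))
  expect_gt(cor(h, ent, method = "spearman"), 0.7)
})
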