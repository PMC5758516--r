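test_that("cohort scaffold has the configured size, split and invariants", {
  cfg <- cohort_config(seed = 4)
  co <- generate_cohort(cfg, images = FALSE)
  expect_equal(nrow(co$clinical), 115)
  expect_equal(sum(co$clinical$split == "train"), 85)
  expect_equal(sum(co$clinical$split == "validation"), 30)
  expect_equal(co$clinical$split[1:85], rep("train", 85))
  expect_true(all(co$clinical$os_months > 0))
  expect_equal(ncol(co$expression), 115)
  expect_equal(nrow(co$expression), 21 + 200)
  expect_identical(co$truth$hypoxia_genes, hypoxia_geneset())
  # configuration invariants are enforced
  expect_error(cohort_config(n_studies = 10, n_train = 10), "n_train")
  expect_error(cohort_config(survival_cutoffs_months = c(16, 7)), "increasing")
  expect_error(cohort_config(censoring_rate = 1), "censoring")
})

test_that("cohort generation is deterministic and compartments are present", {
  cfg <- small_config(seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$expression, b$expression)
  expect_identical(a$studies[[3]]$volumes, b$studies[[3]]$volumes)
  expect_equal(length(a$studies), 6)
  for (st in a$studies) {
    expect_setequal(unique(as.vector(st$labelmap)), 0:3)
    for (v in st$volumes) expect_identical(dim(v), dim(st$labelmap))
  }
})

test_that("too-small volumes raise a sizing error", {
  cfg <- cohort_config(volume_shape = c(10L, 10L, 4L))
  expect_error(generate_phantom_study(0.5, cfg, seed = 1), "too small")
})

test_that("phantom texture carries the planted hypoxia signal", {
  cfg <- small_config(shape = c(48L, 48L, 12L))
  # same stream, h extremes: enhancing-rim variance strictly larger at h = 1
  v0 <- generate_phantom_study(0, cfg, seed = 5)
  v1 <- generate_phantom_study(1, cfg, seed = 5)
  expect_lt(var(v0$volumes$GdT1w[v0$labelmap == 2]),
            var(v1$volumes$GdT1w[v1$labelmap == 2]))
  # monotonicity across 50 phantoms
  h <- seq(0.01, 0.99, length.out = 50)
  vv <- vapply(seq_along(h), function(i) {
    st <- generate_phantom_study(h[i], cfg, seed = 100 + i)
    var(st$volumes$GdT1w[st$labelmap == 2])
  }, numeric(1))
  expect_gt(cor(h, vv, method = "spearman"), 0.8)
})

test_that("expression generator matches its generative law", {
  genes <- hypoxia_geneset()
  set.seed(1)
  x <- generate_expression(0.5, genes, n_background = 50)
  expect_length(x, 21 + 50)
  # null case: effect 0 makes hypoxia and background indistinguishable
  set.seed(2)
  null_mat <- replicate(200, generate_expression(runif(1), genes,
                                                 n_background = 200,
                                                 effect_size = 0))
  z <- (null_mat - rowMeans(null_mat)) / apply(null_mat, 1, sd)
  ks <- stats::ks.test(as.vector(z[seq_len(21), ]), "pnorm")
  expect_gt(ks$p.value, 0.01)
  hyp <- rowMeans(null_mat[seq_len(21), ])
  bg <- rowMeans(null_mat[-seq_len(21), ])
  expect_gt(stats::t.test(hyp, bg)$p.value, 0.01)
  # Monte-Carlo recovery of a 3-sigma shift between h = 1 and h = 0
  set.seed(3)
  d <- replicate(500, {
    mean(generate_expression(1, genes, 10, effect_size = 3)[seq_len(21)]) -
      mean(generate_expression(0, genes, 10, effect_size = 3)[seq_len(21)])
  })
  expect_lt(abs(mean(d) - 3), 0.2)
})

test_that("survival generator plants the hypoxia-hazard link", {
  cfg <- cohort_config(censoring_rate = 0)
  set.seed(1)
  s <- replicate(200, generate_survival(0.5, cfg))
  expect_true(all(unlist(s["event", ]) == 1))
  expect_true(all(unlist(s["os_months", ]) > 0))
  set.seed(2)
  os0 <- replicate(2000, generate_survival(0, cfg)$os_months)
  os1 <- replicate(2000, generate_survival(1, cfg)$os_months)
  expect_lt(median(os1), median(os0))
  # censoring produces event = 0 at roughly the configured rate
  cfg2 <- cohort_config(censoring_rate = 0.3)
  set.seed(3)
  ev <- replicate(2000, generate_survival(0.5, cfg2)$event)
  expect_lt(abs(mean(ev == 0) - 0.3), 0.05)
})

test_that("survival groups follow the 7 / 16 month cuts", {
  expect_equal(as.character(assign_survival_group(3.9)), "STS")
  expect_equal(as.character(assign_survival_group(29.8)), "LTS")
  expect_equal(as.character(assign_survival_group(7)), "STS")
  expect_equal(as.character(assign_survival_group(16)), "MTS")
  expect_equal(as.character(assign_survival_group(c(11.4, 16.01))),
               c("MTS", "LTS"))
  expect_error(assign_survival_group(0), "positive")
})

test_that("high- and low-hypoxia subgroups separate in survival", {
  cfg <- cohort_config(censoring_rate = 0.1)
  sig <- vapply(seq_len(20), function(r) {
    set.seed(1000 + r)
    h <- c(runif(60, 0, 0.3), runif(60, 0.7, 1))
    sv <- lapply(h, generate_survival, config = cfg)
    p <- logrank_test(vapply(sv, `[[`, numeric(1), "os_months"),
                      vapply(sv, `[[`, numeric(1), "event"),
                      rep(c("low", "high"), each = 60))$p
    p < 0.01
  }, logical(1))
  expect_gte(mean(sig), 0.9)
})

test_that("cohorts round-trip to disk in standard formats", {
  cfg <- small_config(seed = 3, n_studies = 2L, n_train = 1L)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "SYN-001_GdT1w.nii.gz")))
  expect_true(file.exists(file.path(dir, "SYN-002_seg.nii.gz")))
  img <- RNifti::readNifti(file.path(dir, "SYN-001_T2w.nii.gz"))
  expect_equal(dim(img), cfg$volume_shape)
  expect_equal(RNifti::pixdim(img), cfg$voxel_spacing_mm)
  seg <- RNifti::readNifti(file.path(dir, "SYN-001_seg.nii.gz"))
  expect_setequal(unique(as.vector(seg)), 0:3)
  clin <- utils::read.delim(file.path(dir, "clinical.tsv"))
  expect_equal(nrow(clin), 2)
  expect_identical(read_gmt(file.path(dir, "hypoxia_genes.gmt"))[[1]],
                   hypoxia_geneset())
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(truth$latent_h, 2)
})
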