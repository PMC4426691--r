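test_that("inner-filter correction matches the ABA closed form and inverts the forward model", {
  g <- small_grid()
  eem <- matrix(1, length(g$em), length(g$ex))
  wl <- 200:800

  # zero absorbance: identity
  out <- ife_correct(eem, g, rep(0, length(wl)), wl)
  expect_equal(unclass(out), eem, ignore_attr = TRUE)
  expect_equal(attr(out, "ife_flagged"), 0L)

  # constant absorbance 0.3 at both wavelengths: factor 10^0.3
  out <- ife_correct(eem, g, rep(0.3, length(wl)), wl)
  expect_equal(out[5, 5], 10^0.3, tolerance = 1e-12)
  expect_equal(out[5, 5], 1.9953, tolerance = 1e-4)

  # heavy absorbance flagged as unreliable
  out <- ife_correct(eem, g, rep(2, length(wl)), wl)
  expect_equal(attr(out, "ife_flagged"), length(eem))

  # round trip with the generator's forward attenuation
  sim <- trio_dataset(n = 4)
  a <- simulate_absorbance(rowSums(sim$truth$scores))[2, ]
  raw <- sim$dataset$intensities[2, , ]
  att <- apply_ife(raw, g, a, wl)
  back <- ife_correct(att, g, a, wl)
  expect_lt(max(abs(back - raw)) / max(raw), 1e-10)

  expect_error(ife_correct(eem, g, rep(0.1, 11), 300:310), "cover")
})

test_that("Raman area follows the trapezoid rule on the 381-426 band", {
  g <- eem_grid(seq(220, 450, 5), seq(250, 550, 1))
  flat <- matrix(1, length(g$em), length(g$ex))
  expect_equal(raman_area(flat, g), 45)
  expect_equal(raman_area(2 * flat, g), 90)

  # triangular scan rising 0 -> 1 linearly across the band
  tri <- matrix(0, length(g$em), length(g$ex))
  k <- which(g$ex == 350)
  jb <- g$em >= 381 & g$em <= 426
  tri[jb, k] <- (g$em[jb] - 381) / 45
  expect_equal(raman_area(tri, g), 22.5)

  g2 <- eem_grid(seq(220, 340, 5), seq(250, 550, 1))
  expect_error(raman_area(flat[, 1:25], g2), "absent")
  g3 <- eem_grid(seq(220, 450, 5), seq(250, 400, 1))
  expect_error(raman_area(flat[1:151, ], g3), "partially")
})

test_that("Raman normalization divides by the blank area", {
  sim <- trio_dataset(n = 3)
  expect_equal(raman_normalize(sim$dataset, 1)$intensities,
               sim$dataset$intensities)
  expect_equal(raman_normalize(110.6, 55.3), 2, tolerance = 1e-12)

  # blank normalized by its own area integrates to 1 over the band
  bl <- blank_eem()
  area <- raman_area(bl$eem, bl$grid)
  expect_gt(area, 0)
  expect_equal(raman_area(raman_normalize(bl$eem, area), bl$grid), 1,
               tolerance = 1e-12)

  expect_error(raman_normalize(sim$dataset, 0), "positive")
})

test_that("scatter excision masks the stated bands and nothing else", {
  g <- default_grid()
  sim <- simulate_dataset(dom_library(), "G2", concentration_design(2, seed = 1),
                          grid = g)
  ds <- sim$dataset

  # all widths zero: only the em < ex triangle
  out0 <- excise_scatter(ds, scatter_spec(0, 0, 0))
  tri <- aperm(array(outer(g$em, g$ex, "<"),
                     c(length(g$em), length(g$ex), 2)), c(3, 1, 2))
  expect_identical(out0$mask, tri)

  # Rayleigh-1 half-width 15: (em 350, ex 350) masked, (em 400, ex 350) not
  out1 <- excise_scatter(ds, scatter_spec(15, 0, 0))
  j350 <- which(g$em == 350); j400 <- which(g$em == 400)
  k350 <- which(g$ex == 350)
  expect_true(out1$mask[1, j350, k350])
  expect_false(out1$mask[1, j400, k350])

  # monotone masked fraction in every half-width
  fr <- function(spec) mean(excise_scatter(ds, spec)$mask)
  expect_lte(fr(scatter_spec(10, 0, 0)), fr(scatter_spec(20, 0, 0)))
  expect_lte(fr(scatter_spec(10, 5, 0)), fr(scatter_spec(10, 15, 0)))
  expect_lte(fr(scatter_spec(10, 5, 2)), fr(scatter_spec(10, 5, 8)))
  expect_lte(fr(scatter_spec(0, 0, 0)), fr(scatter_spec(15, 15, 5)))

  # intensities untouched
  expect_identical(out1$intensities, ds$intensities)
})

test_that("total-signal normalization stores exact reversal factors", {
  g <- small_grid()
  sim <- trio_dataset(n = 6)
  ds <- sim$dataset

  nrm <- normalize_total_signal(ds)
  norms <- apply(nrm$intensities, 1, function(m) sqrt(sum(m^2)))
  expect_equal(norms, rep(1, 6), tolerance = 1e-12)

  # homogeneity: scaling a sample by 10 scales its factor, not its shape
  ds10 <- ds
  ds10$intensities[3, , ] <- 10 * ds10$intensities[3, , ]
  nrm10 <- normalize_total_signal(ds10)
  expect_equal(nrm10$intensities[3, , ], nrm$intensities[3, , ],
               tolerance = 1e-12)
  expect_equal(nrm10$sample_meta$norm_factor[3],
               10 * nrm$sample_meta$norm_factor[3], tolerance = 1e-12)

  # scalar-multiple samples normalize to identical EEMs
  ds2 <- ds
  ds2$intensities[2, , ] <- 3.7 * ds2$intensities[1, , ]
  nrm2 <- normalize_total_signal(ds2)
  expect_equal(nrm2$intensities[2, , ], nrm2$intensities[1, , ],
               tolerance = 1e-12)

  # reversal
  sc <- matrix(1, 6, 2)
  expect_equal(reverse_normalization(sc, rep(1, 6)), sc)
  f <- nrm$sample_meta$norm_factor
  expect_equal(reverse_normalization(sc, nrm)[, 1], f, tolerance = 1e-12)
  expect_error(reverse_normalization(sc, rep(1, 5)), "one normalization factor")

  dsz <- ds
  dsz$intensities[1, , ] <- 0
  expect_error(normalize_total_signal(dsz), "no positive unmasked signal")
})

test_that("normalize -> fit -> reverse reproduces raw-scale scores", {
  sim <- trio_dataset(n = 12)
  raw_fit <- parafac_fit(sim$dataset, 3, nstarts = 2, seed = 3)
  nrm <- normalize_total_signal(sim$dataset)
  nrm_fit <- parafac_fit(nrm, 3, nstarts = 2, seed = 3)
  restored <- reverse_normalization(fmax(nrm_fit), nrm)

  mm <- match_components(nrm_fit, raw_fit)
  for (r in seq_len(nrow(mm))) {
    a <- restored[, mm$comp_a[r]]
    b <- fmax(raw_fit)[, mm$comp_b[r]]
    expect_lt(max(abs(a - b)) / max(b), 1e-6)
  }
})

test_that("outlier flags pick out a foreign-component sample", {
  g <- small_grid()
  lib <- trio_library()
  sim <- simulate_dataset(lib, c("P1", "P2"), concentration_design(12, seed = 5),
                          grid = g, noise = noise_model(relative = 0.01, seed = 6))
  ds <- sim$dataset
  # replace one sample with a pure foreign component EEM
  ld <- component_loadings(lib$P3, g)
  ds$intensities[4, , ] <- 8 * outer(ld$em, ld$ex)

  model <- parafac_fit(ds, 2, nstarts = 2, seed = 2)
  rep_ <- flag_outliers(ds, model)
  expect_true(all(rep_$leverage >= 0 & rep_$leverage <= 1))
  expect_equal(which.max(rep_$leverage), 4L)
  expect_true(rep_$flagged[4])

  # exchangeable samples: no flags at default thresholds
  sim2 <- trio_dataset(n = 10, noise_rel = 0.01, seed = 21)
  m2 <- parafac_fit(sim2$dataset, 3, nstarts = 2, seed = 2)
  expect_false(any(flag_outliers(sim2$dataset, m2)$flagged))
})

test_that("preprocess_dataset applies the canonical stage order", {
  g <- default_grid(em_step = 4)
  sim <- simulate_dataset(dom_library(), c("G2", "G6"),
                          concentration_design(5, seed = 9), grid = g,
                          with_absorbance = TRUE)
  pp <- preprocess_dataset(sim$dataset, blank_area = 55.3)
  expect_equal(attr(pp, "preprocess_steps"),
               c("ife", "raman", "excise", "total_signal"))
  norms <- vapply(seq_len(5), function(i) {
    x <- pp$intensities[i, , ]; sqrt(sum(x[!pp$mask[i, , ]]^2))
  }, numeric(1))
  expect_equal(norms, rep(1, 5), tolerance = 1e-12)
  expect_true(any(pp$mask))
})
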