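test_that("component loadings are unit-maximum with peaks at band centers", {
  g <- default_grid()
  lib <- dom_library()

  ld <- component_loadings(lib$G7, g)
  expect_true(all(ld$em >= 0) && all(ld$ex >= 0))
  expect_equal(max(ld$em), 1)
  expect_equal(max(ld$ex), 1)
  expect_equal(g$em[which.max(ld$em)], 314)
  expect_equal(g$ex[which.max(ld$ex)], 265)

  # determinism: same component, same grid, identical vectors
  expect_identical(ld, component_loadings(lib$G7, g))

  # dual-excitation component: global argmax at the taller band, local
  # maximum at the shorter one (both within one grid step of the centers)
  dual <- fluorophore("dual", rbind(c(265, 12, 0.8), c(365, 14, 1.0)),
                      c(450, 40, 1))
  ex <- component_loadings(dual, g)$ex
  expect_lte(abs(g$ex[which.max(ex)] - 365), 5)
  k265 <- which(g$ex == 265)
  expect_gt(ex[k265], ex[k265 - 1L] - 1e-12)
  expect_gt(ex[k265], ex[k265 + 1L] - 1e-12)

  expect_error(fluorophore("bad", matrix(numeric(0), 0, 3), c(300, 10, 1)),
               "bands")
  expect_error(fluorophore("bad", c(300, -5, 1), c(300, 10, 1)), "positive")
})

test_that("simulate_dataset is exactly trilinear and seed-deterministic", {
  g <- small_grid()
  lib <- trio_library()

  # one component, fixed concentrations 1:2:4, no noise: every EEM is a
  # scalar multiple of the component surface
  sim <- simulate_dataset(lib, "P2", concentration_design(3, seed = 1),
                          grid = g, concentrations = cbind(c(1, 2, 4)))
  px <- sim$dataset$intensities[, 8, 5]
  expect_equal(px / px[1], c(1, 2, 4), tolerance = 1e-12)
  surf <- outer(sim$truth$em_loadings[, 1], sim$truth$ex_loadings[, 1])
  expect_equal(sim$dataset$intensities[2, , ], 2 * surf, tolerance = 1e-12)

  # seed contract: identical tensors bitwise
  s1 <- simulate_dataset(lib, c("P1", "P2", "P3"),
                         concentration_design(20, seed = 7), grid = g,
                         noise = noise_model(relative = 0.02, seed = 9))
  s2 <- simulate_dataset(lib, c("P1", "P2", "P3"),
                         concentration_design(20, seed = 7), grid = g,
                         noise = noise_model(relative = 0.02, seed = 9))
  expect_identical(s1$dataset$intensities, s2$dataset$intensities)

  # reconstructing from returned truth reproduces the noiseless tensor
  s0 <- trio_dataset(n = 10)
  recon <- reconstruct(truth_model(s0$truth, g))
  expect_equal(s0$dataset$intensities, recon, tolerance = 1e-12)

  expect_error(concentration_design(0), "at least one")
  expect_error(noise_model(additive = -1), ">= 0")
  expect_error(simulate_dataset(lib, character(0),
                                concentration_design(3)), "nonempty")
  expect_error(simulate_dataset(lib, "nope", concentration_design(3)),
               "not in library")
})

test_that("noiseless three-component tensor has multilinear rank 3 by both solvers", {
  sim <- trio_dataset(n = 10)
  X <- sim$dataset$intensities
  nrm <- sum(X^2)

  fit <- parafac_fit(sim$dataset, 3, nstarts = 2, seed = 5)
  expect_lt(fit$sse / nrm, 1e-9)

  orc <- oracle_parafac(X, 3, seed = 5)
  expect_lt(orc$sse / nrm, 1e-9)
})

test_that("shift_component translates centers and degrades congruence monotonically", {
  g <- default_grid()
  lib <- dom_library()

  expect_equal(shift_component(lib$G1, 0, 0), lib$G1)

  sh <- shift_component(lib$G1, 0, 20)
  expect_equal(unname(sh$em_bands[1, "center"]), 434)
  expect_equal(sh$em_bands[, c("width", "height")],
               lib$G1$em_bands[, c("width", "height")])

  base_em <- component_loadings(lib$G1, g)$em
  rc <- vapply(c(0, 5, 10, 20, 30), function(d)
    tucker_congruence(base_em,
                      component_loadings(shift_component(lib$G1, 0, d), g)$em),
    numeric(1))
  expect_equal(rc[1], 1)
  expect_lt(rc[4], rc[2])                  # 20 nm shift worse than 5 nm
  expect_true(all(diff(rc) <= 1e-12))      # non-increasing in |delta|

  expect_error(shift_component(lib$G1, 0, 200, grid = g), "off the grid")
})

test_that("scatter is local and the Raman line sits at the water shift", {
  expect_equal(raman_em_center(350), 397, tolerance = 0.005)

  g <- small_grid()
  lib <- trio_library()
  des <- concentration_design(4, seed = 2)
  clean <- simulate_dataset(lib, "P1", des, grid = g)
  spec <- scatter_spec(rayleigh1_width = 10, rayleigh2_width = 10,
                       raman_width = 5, rayleigh1_amp = 4,
                       rayleigh2_amp = 1, raman_amp = 0.5)
  dirty <- simulate_dataset(lib, "P1", des, grid = g, scatter = spec)

  # off-band pixels (> 3 half-widths from every line) keep scatter-free values
  for (k in seq_along(g$ex)) {
    ex <- g$ex[k]
    off <- abs(g$em - ex) > 30 & abs(g$em - 2 * ex) > 30 &
      abs(g$em - raman_em_center(ex)) > 15
    expect_lt(max(abs(dirty$dataset$intensities[1, off, k] -
                        clean$dataset$intensities[1, off, k])), 1e-6)
  }
  # on the first-order Rayleigh line the amplitude shows up
  k <- which(g$ex == 340)
  j <- which.min(abs(g$em - 340))
  expect_gt(dirty$dataset$intensities[1, j, k] -
              clean$dataset$intensities[1, j, k], 1)
})

test_that("cocktail datasets append labelled contaminated samples", {
  g <- small_grid()
  lib <- trio_library()
  base <- simulate_dataset(lib, c("P1", "P2"),
                           concentration_design(76, seed = 3), grid = g)
  intr <- spectral_library(list(X1 = shift_component(lib$P3, 0, 10)))

  cock <- make_cocktail(base, lib, c("P1", "P2"), intr, "X1", 10,
                        concentration_design(10, seed = 4), grid = g)
  expect_equal(n_samples(cock$dataset), 86)
  expect_equal(sum(cock$dataset$sample_meta$source == "cocktail"), 10)
  expect_equal(cock$dataset$sample_meta$source[77:86], rep("cocktail", 10))
  # base samples untouched
  expect_identical(cock$dataset$intensities[1:76, , ],
                   base$dataset$intensities)

  expect_error(make_cocktail(base, lib, c("P1", "P2"), intr, "X1", 0,
                             concentration_design(1)), "n_contaminated")
  g2 <- eem_grid(seq(240, 440, 10), seq(300, 496, 8))
  expect_error(make_cocktail(base, lib, c("P1", "P2"), intr, "X1", 5,
                             concentration_design(5), grid = g2),
               "grid mismatch")
})

test_that("simulated absorbance is linear in concentration and decays", {
  a1 <- simulate_absorbance(1)
  a0 <- simulate_absorbance(0)
  a2 <- simulate_absorbance(2)
  expect_true(all(a0 == 0))
  expect_equal(2 * a1, a2, tolerance = 1e-12)
  wl <- 200:800
  expect_gt(a1[1, wl == 254], a1[1, wl == 500])
  expect_true(all(a1 >= 0))
})
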