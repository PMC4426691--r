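test_that("noiseless recovery reaches machine precision and matches truth", {
  sim <- trio_dataset(n = 12)
  fit <- parafac_fit(sim$dataset, 3, nstarts = 3, seed = 1)
  expect_lt(fit$sse / sum(sim$dataset$intensities^2), 1e-9)
  expect_gt(fit$expl_var, 1 - 1e-9)
  expect_true(all(fit$scores >= 0))
  expect_true(all(fit$em_loadings >= 0) && all(fit$ex_loadings >= 0))
  expect_equal(apply(fit$em_loadings, 2, max), rep(1, 3),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(apply(fit$ex_loadings, 2, max), rep(1, 3),
               ignore_attr = TRUE, tolerance = 1e-12)

  mm <- match_components(fit, truth_model(sim$truth, sim$dataset$grid))
  expect_true(all(mm$rc_ex > 0.999) && all(mm$rc_em > 0.999))

  # seed contract: refit identical
  fit2 <- parafac_fit(sim$dataset, 3, nstarts = 3, seed = 1)
  expect_identical(fit$scores, fit2$scores)
})

test_that("rank-1 data yields scores proportional to true concentrations", {
  g <- small_grid()
  sim <- simulate_dataset(trio_library(), "P2",
                          concentration_design(10, seed = 4), grid = g)
  fit <- parafac_fit(sim$dataset, 1, nstarts = 2, seed = 1)
  expect_gt(cor(fit$scores[, 1], sim$truth$scores[, 1]), 1 - 1e-9)
})

test_that("longer optimization never increases the best SSE (monotone ALS)", {
  sim <- trio_dataset(n = 10, noise_rel = 0.02, seed = 13)
  s50 <- parafac_fit(sim$dataset, 3, nstarts = 1, maxit = 30, tol = 0,
                     seed = 8)$sse
  s200 <- parafac_fit(sim$dataset, 3, nstarts = 1, maxit = 120, tol = 0,
                      seed = 8)$sse
  expect_lte(s200, s50 + 1e-12)

  # warm-starting from a fitted model never worsens the solution
  m <- parafac_fit(sim$dataset, 3, nstarts = 2, seed = 8)
  warm <- parafac_fit(sim$dataset, 4, nstarts = 1, maxit = 200, seed = 8,
                      init = list(A = m$scores, B = m$em_loadings,
                                  C = m$ex_loadings))
  expect_lte(warm$sse, m$sse * (1 + 1e-9))
})

test_that("core consistency is ~100 at the true F and collapses when over-factored", {
  sim <- trio_dataset(n = 14, noise_rel = 0.01, seed = 17)
  f3 <- parafac_fit(sim$dataset, 3, nstarts = 3, seed = 2)
  cc3 <- core_consistency(f3, sim$dataset)
  expect_gt(cc3, 90)
  expect_lte(cc3, 100)

  f5 <- parafac_fit(sim$dataset, 5, nstarts = 3, seed = 2)
  cc5 <- core_consistency(f5, sim$dataset)
  expect_lt(cc5, cc3)

  f1 <- parafac_fit(sim$dataset, 1, nstarts = 1, seed = 2)
  expect_equal(core_consistency(f1, sim$dataset), 100)
})

test_that("fmax equals scores under unit-maximum loadings and is scale-stable", {
  sim <- trio_dataset(n = 10)
  fit <- parafac_fit(sim$dataset, 3, nstarts = 2, seed = 6)
  expect_equal(fmax(fit), fit$scores, tolerance = 1e-12)

  # manual rescaling then re-normalization leaves fmax invariant
  alt <- fit
  alt$em_loadings[, 1] <- 2 * alt$em_loadings[, 1]
  alt$scores[, 1] <- alt$scores[, 1] / 2
  expect_equal(fmax(alt), fmax(fit), tolerance = 1e-12)

  # noiseless: fmax ~ true concentrations with R^2 = 1 per component
  mm <- match_components(fit, truth_model(sim$truth, sim$dataset$grid))
  fm <- fmax(fit)
  for (r in seq_len(3)) {
    reg <- cross_model_fmax_regression(fm[, mm$comp_a[r]],
                                       sim$truth$scores[, mm$comp_b[r]])
    expect_gt(reg$r_squared, 1 - 1e-9)
  }
})

test_that("leverage satisfies hat-matrix identities", {
  sim <- trio_dataset(n = 11, noise_rel = 0.01, seed = 19)
  fit <- parafac_fit(sim$dataset, 3, nstarts = 2, seed = 3)
  for (mode in c("sample", "emission", "excitation")) {
    lev <- leverage(fit, mode)
    expect_true(all(lev >= -1e-12 & lev <= 1 + 1e-12))
    expect_equal(sum(lev), 3, tolerance = 1e-8)
  }
})

test_that("fitted loadings agree with an independent trilinear solver", {
  g <- eem_grid(seq(250, 440, 10), seq(300, 500, 5))
  sim <- simulate_dataset(trio_library(), c("P1", "P2", "P3"),
                          concentration_design(10, seed = 23), grid = g)
  fit <- parafac_fit(sim$dataset, 3, nstarts = 3, seed = 4)
  orc <- oracle_parafac(sim$dataset$intensities, 3, seed = 4)
  idx <- oracle_match(orc$B, fit$em_loadings)
  for (f in seq_len(3)) {
    expect_gt(abs(oracle_cosine(orc$B[, idx[f]], fit$em_loadings[, f])),
              0.9999)
    expect_gt(abs(oracle_cosine(orc$C[, idx[f]], fit$ex_loadings[, f])),
              0.9999)
  }
})

test_that("masking 20% of cells still recovers the truth", {
  sim <- trio_dataset(n = 12, seed = 29)
  ds <- sim$dataset
  set.seed(31)
  ds$mask <- array(runif(length(ds$intensities)) < 0.2, dim(ds$intensities))
  fit <- parafac_fit(ds, 3, nstarts = 2, seed = 5)
  mm <- match_components(fit, truth_model(sim$truth, ds$grid))
  expect_true(all(mm$rc_ex > 0.999) && all(mm$rc_em > 0.999))
})

test_that("split-half validation passes on identical halves and on clean data", {
  # duplicated samples: halves are exchangeable, congruence essentially 1
  sim <- trio_dataset(n = 8, seed = 37)
  dup <- sim$dataset
  both <- eem_dataset(dup$intensities[rep(1:8, 2), , ], dup$grid)
  sh <- split_half(both, 3, nstarts = 2, seed = 1)
  expect_true(sh$pass)
  expect_gt(sh$min_rc, 0.9999)

  expect_error(split_half(subset_samples(sim$dataset, 1:4), 3), "too few")
})

test_that("fit rejects degenerate requests", {
  sim <- trio_dataset(n = 5)
  expect_error(parafac_fit(sim$dataset, 0), ">= 1")
  expect_error(parafac_fit(sim$dataset, 6), "exceeds|at least")
  ds <- sim$dataset
  ds$mask[1, , ] <- TRUE
  expect_error(parafac_fit(ds, 3, nstarts = 1), "too few unmasked")
})

test_that("a shared 20 nm-shifted component distorts the merged-model loadings", {
  # two sources share a humic-like component, shifted in both modes in the
  # second source; merged fits recover a compromise spectrum less congruent
  # with either source's truth than each individual fit is with its own
  g <- coarse_grid()
  shared <- fluorophore("sharedH", c(320, 15, 1), c(414, 40, 1))
  lib1 <- spectral_library(list(H = shared,
                                U1 = fluorophore("u1", c(265, 13, 1),
                                                 c(314, 18, 1))))
  lib2 <- spectral_library(list(H = shift_component(shared, 20, 20),
                                U2 = fluorophore("u2", c(365, 22, 1),
                                                 c(472, 50, 1))))
  s1 <- simulate_dataset(lib1, c("H", "U1"), concentration_design(20, seed = 41),
                         grid = g, noise = noise_model(relative = 0.01, seed = 42))
  s2 <- simulate_dataset(lib2, c("H", "U2"), concentration_design(20, seed = 43),
                         grid = g, noise = noise_model(relative = 0.01, seed = 44))
  Xm <- array(0, c(40, length(g$em), length(g$ex)))
  Xm[1:20, , ] <- s1$dataset$intensities
  Xm[21:40, , ] <- s2$dataset$intensities
  merged <- eem_dataset(Xm, g)

  ind1 <- parafac_fit(s1$dataset, 2, nstarts = 3, seed = 6)
  glob <- parafac_fit(merged, 3, nstarts = 4, seed = 6)

  t1 <- truth_model(s1$truth, g)
  m_ind <- match_components(ind1, t1)
  m_glob <- match_components(glob, t1)
  shared_ind <- m_ind[m_ind$comp_b == 1, ]
  shared_glob <- m_glob[m_glob$comp_b == 1 & !is.na(m_glob$comp_b), ]
  expect_lt(min(shared_glob$rc_ex, shared_glob$rc_em),
            min(shared_ind$rc_ex, shared_ind$rc_em))
})
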