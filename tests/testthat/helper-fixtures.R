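# Shared fixture builders. All grids are deliberately smaller than the
# instrument grid so the default test run stays fast; the full-resolution
# checks live in test-acceptance.R.

small_grid <- function() eem_grid(seq(240, 440, 10), seq(300, 500, 8))

coarse_grid <- function() default_grid(em_step = 4)

# three well-separated components on any grid covering 240-500 nm
trio_library <- function() {
  spectral_library(list(
    P1 = fluorophore("protein-like", c(280, 15, 1), c(332, 25, 1)),
    P2 = fluorophore("humic-like", rbind(c(250, 18, 0.9), c(320, 20, 1)),
                     c(420, 40, 1)),
    P3 = fluorophore("tyrosine-like", c(265, 13, 1), c(470, 30, 1))
  ))
}

trio_dataset <- function(n = 15, noise_rel = 0, seed = 7,
                         grid = small_grid()) {
  simulate_dataset(trio_library(), c("P1", "P2", "P3"),
                   concentration_design(n, seed = seed), grid = grid,
                   noise = noise_model(relative = noise_rel,
                                       seed = seed + 100L))
}

# a parafac_model-shaped object wrapping generator truth, for matching tests
truth_model <- function(truth, grid) {
  structure(list(scores = truth$scores, em_loadings = truth$em_loadings,
                 ex_loadings = truth$ex_loadings,
                 ncomp = ncol(truth$scores), sse = 0, expl_var = 1,
                 iterations = 0L, converged = TRUE, grid = grid,
                 config = list()),
            class = "parafac_model")
}

# model built directly from library loadings (no fitting)
library_model <- function(lib, components, grid, n = 5, seed = 1) {
  F <- length(components)
  B <- matrix(0, length(grid$em), F)
  C <- matrix(0, length(grid$ex), F)
  for (f in seq_len(F)) {
    ld <- component_loadings(lib[[components[f]]], grid)
    B[, f] <- ld$em; C[, f] <- ld$ex
  }
  set.seed(seed)
  A <- matrix(rlnorm(n * F), n, F)
  structure(list(scores = A, em_loadings = B, ex_loadings = C, ncomp = F,
                 sse = 0, expl_var = 1, iterations = 0L, converged = TRUE,
                 grid = grid, config = list()),
            class = "parafac_model")
}

# flat blank EEM with a realistic Raman band profile at ex 350
blank_eem <- function(grid = eem_grid(seq(220, 450, 5), seq(250, 550, 1)),
                      level = 0) {
  m <- matrix(level, length(grid$em), length(grid$ex))
  k <- which(grid$ex == 350)
  m[, k] <- m[, k] + 1.2 * exp(-0.5 * ((grid$em - 397) / 8)^2)
  list(eem = m, grid = grid)
}
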