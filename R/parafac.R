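# ---- fast non-negative least squares on the normal equations ---------------
# Bro & de Jong's FNNLS: minimize ||Zx - b|| s.t. x >= 0 given G = Z'Z and
# h = Z'b. F is tiny (number of components), so the active-set loop is cheap.
fnnls <- function(G, h, eps = 1e-12) {
  F <- length(h)
  x <- numeric(F)
  passive <- logical(F)
  w <- h
  outer_it <- 0L
  solve_p <- function(Gp, hp) {
    out <- tryCatch(solve(Gp, hp), error = function(e) NULL)
    if (is.null(out))
      out <- solve(Gp + diag(1e-12 * max(diag(Gp)), nrow(Gp)), hp)
    out
  }
  while (any(!passive & w > eps * max(abs(h), 1)) && outer_it < 30L * F) {
    outer_it <- outer_it + 1L
    cand <- w
    cand[passive] <- -Inf
    passive[which.max(cand)] <- TRUE
    repeat {
      s <- numeric(F)
      s[passive] <- solve_p(G[passive, passive, drop = FALSE], h[passive])
      if (all(s[passive] > eps)) break
      viol <- passive & s <= eps
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * (s - x)
      passive <- passive & x > eps
      x[!passive] <- 0
      if (!any(passive)) break
    }
    x <- s
    x[!passive] <- 0
    w <- h - drop(G %*% x)
  }
  pmax(x, 0)
}

# Solve min ||X_unfold - M Z'||_F for M (rows independent), optionally with
# non-negativity. H = X_unfold %*% Z, G = Z'Z (Hadamard of Gram matrices).
# Unconstrained solve first; only rows with negative entries get FNNLS.
solve_mode <- function(H, G, nonneg) {
  M <- t(solve_sym(G, t(H)))
  if (nonneg) {
    bad <- which(matrixStats_any_neg(M))
    for (i in bad) M[i, ] <- fnnls(G, H[i, ])
    M[M < 0] <- 0
  }
  M
}

matrixStats_any_neg <- function(M) .rowSums(M < -1e-10, nrow(M), ncol(M)) > 0

solve_sym <- function(G, B) {
  out <- tryCatch(solve(G, B), error = function(e) NULL)
  if (is.null(out))
    out <- solve(G + diag(1e-10 * max(diag(G)), nrow(G)), B)
  out
}

# ---- unfoldings -------------------------------------------------------------
unfold1 <- function(X) matrix(X, dim(X)[1])                    # n  x JK (j fast)
unfold2 <- function(X) matrix(aperm(X, c(2, 1, 3)), dim(X)[2]) # J  x nK (i fast)
unfold3 <- function(X) matrix(aperm(X, c(3, 1, 2)), dim(X)[3]) # K  x nJ (i fast)

#' Reconstruct the model tensor
#'
#' @param model a [parafac_model].
#' @return numeric array (sample x emission x excitation).
#' @export
reconstruct <- function(model) {
  A <- model$scores; B <- model$em_loadings; C <- model$ex_loadings
  array(A %*% t(khatri_rao(C, B)), c(nrow(A), nrow(B), nrow(C)))
}

# nearest-neighbour/linear initial fill of masked cells, per sample and
# excitation column, interpolating along emission; falls back to the sample
# mean when a whole column is masked.
impute_initial <- function(X, mask) {
  d <- dim(X)
  for (i in seq_len(d[1])) {
    mi <- mask[i, , ]
    if (!any(mi)) next
    xi <- X[i, , ]
    fallback <- mean(xi[!mi])
    if (!is.finite(fallback)) fallback <- 0
    for (k in seq_len(d[3])) {
      bad <- mi[, k]
      if (!any(bad)) next
      good <- which(!bad)
      if (length(good) >= 2) {
        xi[bad, k] <- stats::approx(good, xi[good, k], xout = which(bad),
                                    rule = 2)$y
      } else xi[bad, k] <- fallback
    }
    X[i, , ] <- xi
  }
  X
}

#' Fit a non-negative PARAFAC model to an EEM dataset
#'
#' Decomposes the three-way array into `ncomp` trilinear components
#' `x_ijk = sum_f a_if b_jf c_kf + e_ijk` by alternating least squares with
#' column-wise non-negativity (the physical constraint for fluorescence:
#' concentrations, emission spectra and absorption coefficients are all
#' non-negative). Masked cells are handled by an EM loop: they are
#' initialized by interpolation along the emission axis and overwritten with
#' the current model reconstruction after every sweep, so the fit criterion
#' is the residual over observed cells only.
#'
#' The best of `nstarts` seeded random initializations (by final SSE) is
#' returned. Loadings are rescaled to unit maximum with all scale absorbed
#' into the scores, and components are sorted by decreasing contribution, so
#' the model is identified up to the trivial indeterminacies.
#'
#' @param dataset an [eem_dataset].
#' @param ncomp number of components F, >= 1.
#' @param nstarts random starts (default 10).
#' @param maxit maximum ALS iterations per start.
#' @param tol relative SSE-change convergence tolerance.
#' @param nonneg enforce non-negativity (default TRUE).
#' @param seed integer; together with the start index it fixes every
#'   initialization, so the fit is reproducible.
#' @param init optional warm start: a list with matrices `A`, `B`, `C`
#'   holding up to `ncomp` columns (missing columns are padded with small
#'   random values), run as an additional start. Warm-starting F from the
#'   F-1 solution makes SSE non-increasing across a nested model scan.
#' @param verbose print per-start convergence lines.
#' @return A `parafac_model`: scores (n x F), em_loadings (J x F, unit max),
#'   ex_loadings (K x F, unit max), sse, expl_var, iterations, converged,
#'   grid, config.
#' @export
parafac_fit <- function(dataset, ncomp, nstarts = 10, maxit = 2500,
                        tol = 1e-8, nonneg = TRUE, seed = 1L, init = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(dataset, "eem_dataset"))
  d <- dim(dataset$intensities)
  n <- d[1]; J <- d[2]; K <- d[3]
  F <- as.integer(ncomp)
  if (F < 1L) stop("ncomp must be >= 1")
  if (F > min(n, J, K))
    stop("ncomp exceeds a mode dimension (", paste(d, collapse = "x"), ")")
  if (n < F) stop("need at least ncomp samples")

  mask <- dataset$mask
  has_missing <- any(mask)
  if (has_missing) {
    obs_per_slab <- apply(!mask, 1, sum)
    if (any(obs_per_slab < F * (J + K)))
      stop("a sample slab has too few unmasked cells for identifiability")
  }
  X0 <- dataset$intensities
  X0[mask] <- 0            # placeholder; re-imputed below
  if (has_missing) X0 <- impute_initial(dataset$intensities, mask)
  obs <- !mask
  norm_obs2 <- sum(dataset$intensities[obs]^2)

  pad_init <- function(M, rows) {
    M <- as.matrix(M)
    if (ncol(M) > F) stop("init has more columns than ncomp")
    if (ncol(M) < F)
      M <- cbind(M, matrix(stats::runif(rows * (F - ncol(M)), 0, 1e-3),
                           rows, F - ncol(M)))
    M
  }
  starts <- seq_len(nstarts)
  if (!is.null(init)) starts <- c(0L, starts)

  best <- NULL
  for (s in starts) {
    set.seed(as.integer(seed) + 7919L * s)
    if (s == 0L) {
      A <- pad_init(init$A, n)
      B <- pad_init(init$B, J)
      C <- pad_init(init$C, K)
    } else {
      A <- matrix(stats::runif(n * F, 0.1, 1), n, F)
      B <- matrix(stats::runif(J * F, 0.1, 1), J, F)
      C <- matrix(stats::runif(K * F, 0.1, 1), K, F)
    }
    X <- X0
    X1 <- unfold1(X); X2 <- unfold2(X); X3 <- unfold3(X)
    sse_prev <- Inf
    converged <- FALSE
    it <- 0L
    while (it < maxit) {
      it <- it + 1L
      BtB <- crossprod(B); CtC <- crossprod(C)
      A <- solve_mode(X1 %*% khatri_rao(C, B), CtC * BtB, nonneg)
      AtA <- crossprod(A)
      B <- solve_mode(X2 %*% khatri_rao(C, A), CtC * AtA, nonneg)
      BtB <- crossprod(B)
      C <- solve_mode(X3 %*% khatri_rao(B, A), BtB * AtA, nonneg)

      if (has_missing || it %% 1L == 0L) {
        recon <- array(A %*% t(khatri_rao(C, B)), d)
        sse <- sum((dataset$intensities[obs] - recon[obs])^2)
        if (has_missing) {
          X[mask] <- recon[mask]
          X1 <- unfold1(X); X2 <- unfold2(X); X3 <- unfold3(X)
        }
      }
      if (sse <= norm_obs2 * 1e-16) { converged <- TRUE; break }
      rel <- (sse_prev - sse) / sse_prev
      if (is.finite(rel) && abs(rel) < tol) { converged <- TRUE; break }
      sse_prev <- sse
    }
    if (verbose)
      message(sprintf("start %d: sse %.3e (%d iter, converged=%s)",
                      s, sse, it, converged))
    if (is.null(best) || sse < best$sse)
      best <- list(A = A, B = B, C = C, sse = sse, iterations = it,
                   converged = converged, start = s)
  }

  A <- best$A; B <- best$B; C <- best$C
  # unit-maximum loadings, scale into scores
  bmax <- apply(B, 2, max); cmax <- apply(C, 2, max)
  bmax[bmax <= 0] <- 1; cmax[cmax <= 0] <- 1
  A <- A * rep(bmax * cmax, each = n)
  B <- B / rep(bmax, each = J)
  C <- C / rep(cmax, each = K)
  # order by component contribution
  strength <- colSums(A^2) * colSums(B^2) * colSums(C^2)
  ord <- order(strength, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  B <- B[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]
  colnames(A) <- colnames(B) <- colnames(C) <- paste0("C", seq_len(F))

  # two-factor degeneracy symptom: near-identical component pairs
  if (F >= 2) {
    for (f1 in seq_len(F - 1)) for (f2 in (f1 + 1):F) {
      if (sum(B[, f1]^2) == 0 || sum(B[, f2]^2) == 0 ||
          sum(C[, f1]^2) == 0 || sum(C[, f2]^2) == 0) next
      cc <- tucker_congruence(B[, f1], B[, f2]) *
        tucker_congruence(C[, f1], C[, f2])
      if (cc > 0.98)
        warning(sprintf(
          "components %d and %d have combined congruence %.3f (> 0.98): possible two-factor degeneracy",
          f1, f2, cc))
    }
  }

  structure(list(scores = A, em_loadings = B, ex_loadings = C,
                 ncomp = F, sse = best$sse,
                 expl_var = 1 - best$sse / norm_obs2,
                 iterations = best$iterations, converged = best$converged,
                 best_start = best$start, grid = dataset$grid,
                 config = list(nstarts = nstarts, maxit = maxit, tol = tol,
                               nonneg = nonneg, seed = as.integer(seed))),
            class = "parafac_model")
}

#' @export
print.parafac_model <- function(x, ...) {
  cat(sprintf(
    "parafac_model: %d components, SSE %.4g, expl. var %.4f, %d iter (%s)\n",
    x$ncomp, x$sse, x$expl_var, x$iterations,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Maximum fluorescence intensity per sample and component
#'
#' Under the unit-maximum loading convention, F_max(i, f) = a_if *
#' max_j(b_jf) * max_k(c_kf) = a_if: the modeled intensity at the component's
#' excitation/emission peak, proportional to its concentration.
#'
#' @param model a [parafac_model].
#' @return sample x component matrix.
#' @export
fmax <- function(model) {
  stopifnot(inherits(model, "parafac_model"))
  scale <- apply(model$em_loadings, 2, max) * apply(model$ex_loadings, 2, max)
  model$scores * rep(scale, each = nrow(model$scores))
}

#' Leverage of samples or wavelengths
#'
#' Diagonal of the hat matrix `M (M'M)^-1 M'` of the chosen mode's factor
#' matrix. Values lie in [0, 1] and sum to the number of components; large
#' values flag influential (potentially outlying) samples or wavelengths.
#'
#' @param model a [parafac_model].
#' @param mode one of "sample", "emission", "excitation".
#' @return numeric vector of leverages.
#' @export
leverage <- function(model, mode = c("sample", "emission", "excitation")) {
  mode <- match.arg(mode)
  M <- switch(mode, sample = model$scores, emission = model$em_loadings,
              excitation = model$ex_loadings)
  G <- crossprod(M)
  if (rcond_est(G) < 1e-12) stop("factor matrix is rank deficient")
  rowSums((M %*% solve(G)) * M)
}

rcond_est <- function(G) {
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' Core consistency diagnostic
#'
#' Computes the least-squares Tucker3 core given the fitted PARAFAC loadings
#' and compares it with the superidentity core T the trilinear model implies:
#' `100 * (1 - sum((g - t)^2) / sum(t^2))`. Values near 100 support the
#' chosen number of components; over-factored models collapse toward 0 or
#' below. A one-component model is 100 by construction (1x1x1 core).
#'
#' @param model a [parafac_model].
#' @param dataset the dataset it was fitted to; masked cells are replaced by
#'   the model reconstruction.
#' @return percentage (<= 100).
#' @export
core_consistency <- function(model, dataset) {
  stopifnot(inherits(model, "parafac_model"), inherits(dataset, "eem_dataset"))
  F <- model$ncomp
  if (F == 1L) return(100)
  X <- dataset$intensities
  if (any(dataset$mask)) {
    recon <- reconstruct(model)
    X[dataset$mask] <- recon[dataset$mask]
  }
  Ap <- pinv(model$scores); Bp <- pinv(model$em_loadings)
  Cp <- pinv(model$ex_loadings)
  d <- dim(X)
  # least-squares Tucker core: X x1 pinv(A) x2 pinv(B) x3 pinv(C)
  Y <- array(Ap %*% unfold1(X), c(F, d[2], d[3]))
  Y <- aperm(array(Bp %*% unfold2(Y), c(F, F, d[3])), c(2, 1, 3))
  Z3 <- Cp %*% unfold3(Y)                    # F x F^2, row = 3rd core index
  core <- array(t(Z3), c(F, F, F))           # core[f, g, h]
  tcore <- array(0, c(F, F, F))
  for (f in seq_len(F)) tcore[f, f, f] <- 1
  100 * (1 - sum((core - tcore)^2) / F)
}

pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
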