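#' Subset an EEM dataset by sample index
#'
#' @param dataset an [eem_dataset].
#' @param idx integer sample indices to keep.
#' @return an [eem_dataset] with the selected samples.
#' @export
subset_samples <- function(dataset, idx) {
  stopifnot(inherits(dataset, "eem_dataset"))
  eem_dataset(dataset$intensities[idx, , , drop = FALSE], dataset$grid,
              mask = dataset$mask[idx, , , drop = FALSE],
              sample_meta = dataset$sample_meta[idx, , drop = FALSE],
              absorbance = if (!is.null(dataset$absorbance))
                dataset$absorbance[idx, , drop = FALSE] else NULL,
              abs_wavelengths = dataset$abs_wavelengths)
}

#' Split-half validation
#'
#' Splits the samples into two halves (seeded shuffle, then alternating
#' assignment), fits each half independently, matches components across the
#' halves by Tucker congruence, and requires every matched component to agree
#' in both optical modes at the congruence threshold (default 0.95, the
#' "equal" boundary). A model whose components replicate across independent
#' sample halves is considered validated.
#'
#' @param dataset an [eem_dataset] with at least `2 * ncomp` samples.
#' @param ncomp number of components.
#' @param nstarts,maxit,tol,nonneg,seed passed to [parafac_fit()].
#' @param threshold minimum per-mode congruence for a pass.
#' @param split_seed seed for the half assignment (defaults to `seed`).
#' @return list of class `split_half_result`: `model_a`, `model_b`,
#'   `matches` (data.frame with rc_ex, rc_em per matched component),
#'   `min_rc`, `pass`.
#' @export
split_half <- function(dataset, ncomp, nstarts = 5, maxit = 2500, tol = 1e-8,
                       nonneg = TRUE, seed = 1L, threshold = 0.95,
                       split_seed = NULL) {
  n <- n_samples(dataset)
  if (n < 2L * ncomp) stop("too few samples to split-half validate")
  if (is.null(split_seed)) split_seed <- seed
  set.seed(as.integer(split_seed))
  perm <- sample.int(n)
  half_a <- sort(perm[seq(1, n, by = 2)])
  half_b <- sort(perm[seq(2, n, by = 2)])
  ma <- parafac_fit(subset_samples(dataset, half_a), ncomp, nstarts = nstarts,
                    maxit = maxit, tol = tol, nonneg = nonneg, seed = seed)
  mb <- parafac_fit(subset_samples(dataset, half_b), ncomp, nstarts = nstarts,
                    maxit = maxit, tol = tol, nonneg = nonneg,
                    seed = seed + 1L)
  matches <- match_components(ma, mb)
  paired <- matches[!is.na(matches$comp_a) & !is.na(matches$comp_b), ]
  min_rc <- min(c(paired$rc_ex, paired$rc_em))
  pass <- nrow(paired) == ncomp && min_rc >= threshold
  structure(list(model_a = ma, model_b = mb, matches = matches,
                 min_rc = min_rc, threshold = threshold, pass = pass,
                 halves = list(a = half_a, b = half_b)),
            class = "split_half_result")
}

#' @export
print.split_half_result <- function(x, ...) {
  cat(sprintf("split_half_result: %s (min r_c %.4f, threshold %.2f)\n",
              if (x$pass) "PASS" else "FAIL", x$min_rc, x$threshold))
  invisible(x)
}

#' Screen a range of component counts
#'
#' Fits models for every F in `f_range` (conventionally 3--7 for DOM EEMs)
#' and tabulates SSE, explained variance, core consistency and the split-half
#' outcome. The recommended F is the largest count that both passes
#' split-half validation and keeps core consistency above `cc_floor`; when
#' several counts are admissible the diagnostics table lets the analyst
#' arbitrate, but ties on the stated rule resolve toward the larger count
#' having priority only if it passes — otherwise the next smaller one.
#'
#' @param dataset an [eem_dataset].
#' @param f_range integer vector of component counts.
#' @param nstarts,maxit,tol,nonneg,seed passed to the fits.
#' @param threshold split-half congruence threshold.
#' @param cc_floor minimum acceptable core consistency (%).
#' @return list of class `component_selection`: `table` (one row per F) and
#'   `recommended` (integer or NA if nothing passes).
#' @export
select_components <- function(dataset, f_range = 3:7, nstarts = 5,
                              maxit = 2500, tol = 1e-8, nonneg = TRUE,
                              seed = 1L, threshold = 0.95, cc_floor = 60) {
  if (length(f_range) == 0L) stop("f_range must be nonempty")
  prev <- NULL
  rows <- lapply(f_range, function(F) {
    out <- data.frame(ncomp = F, sse = NA_real_, expl_var = NA_real_,
                      core_consistency = NA_real_, split_half_pass = NA,
                      min_rc = NA_real_, error = NA_character_)
    tryCatch({
      # warm-start from the previous F: keeps SSE non-increasing (and hence
      # explained variance non-decreasing) across the nested scan even when
      # the random starts land in a worse basin
      init <- if (!is.null(prev) && prev$ncomp < F)
        list(A = prev$scores, B = prev$em_loadings, C = prev$ex_loadings)
      else NULL
      m <- parafac_fit(dataset, F, nstarts = nstarts, maxit = maxit,
                       tol = tol, nonneg = nonneg, seed = seed, init = init)
      prev <<- m
      out$sse <- m$sse
      out$expl_var <- m$expl_var
      out$core_consistency <- core_consistency(m, dataset)
      sh <- split_half(dataset, F, nstarts = nstarts, maxit = maxit,
                       tol = tol, nonneg = nonneg, seed = seed,
                       threshold = threshold)
      out$split_half_pass <- sh$pass
      out$min_rc <- sh$min_rc
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$split_half_pass) & tab$split_half_pass &
                !is.na(tab$core_consistency) &
                tab$core_consistency >= cc_floor)
  recommended <- if (length(ok)) max(tab$ncomp[ok]) else NA_integer_
  structure(list(table = tab, recommended = recommended,
                 cc_floor = cc_floor, threshold = threshold),
            class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("recommended F:", x$recommended, "\n")
  invisible(x)
}
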