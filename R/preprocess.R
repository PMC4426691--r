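#' Inner-filter effect correction (absorbance-based, ABA)
#'
#' Multiplies every cell by `10^((A(ex) + A(em)) / 2)`, the standard
#' absorbance-based correction for primary plus secondary inner filtering in
#' a 1 cm cuvette. The factor is >= 1 wherever absorbance is >= 0. Cells
#' where `A(ex) + A(em) > 3` are flagged: at such optical densities the
#' correction is considered unreliable.
#'
#' @param eem emission x excitation matrix (or an [eem_dataset], corrected
#'   sample-wise using its stored absorbance spectra).
#' @param grid [eem_grid] (ignored when `eem` is a dataset).
#' @param absorbance absorbance values on `abs_wavelengths` (single spectrum
#'   for a matrix input).
#' @param abs_wavelengths wavelengths (nm) of the absorbance values.
#' @return corrected object of the same kind; attribute `ife_flagged` gives
#'   the number of cells exceeding the reliability limit.
#' @export
ife_correct <- function(eem, grid = NULL, absorbance = NULL,
                        abs_wavelengths = NULL) {
  if (inherits(eem, "eem_dataset")) {
    ds <- eem
    if (is.null(ds$absorbance))
      stop("dataset carries no absorbance spectra for IFE correction")
    flagged <- 0L
    for (i in seq_len(n_samples(ds))) {
      m <- ife_correct(ds$intensities[i, , ], ds$grid,
                       ds$absorbance[i, ], ds$abs_wavelengths)
      flagged <- flagged + attr(m, "ife_flagged")
      ds$intensities[i, , ] <- m
    }
    attr(ds, "ife_flagged") <- flagged
    return(ds)
  }
  stopifnot(inherits(grid, "eem_grid"))
  a_ex <- stats::approx(abs_wavelengths, absorbance, xout = grid$ex)$y
  a_em <- stats::approx(abs_wavelengths, absorbance, xout = grid$em)$y
  if (anyNA(a_ex) || anyNA(a_em))
    stop("absorbance spectrum does not cover the EEM wavelength range")
  tot <- outer(a_em, a_ex, "+")
  out <- eem * 10^(tot / 2)
  attr(out, "ife_flagged") <- sum(tot > 3)
  out
}

#' Area under the water Raman scatter band of a blank EEM
#'
#' Trapezoidal integral of the blank's emission scan at excitation 350 nm
#' over emission 381--426 nm (band endpoints included), in intensity * nm.
#' This area — the daily Milli-Q blank statistic — is the divisor for Raman
#' normalization.
#'
#' @param blank emission x excitation matrix of the blank-water EEM.
#' @param grid its [eem_grid]; must contain ex = 350 and cover em 381--426.
#' @param ex_line excitation wavelength of the Raman scan (nm).
#' @param em_band emission integration limits (nm).
#' @return scalar area.
#' @export
raman_area <- function(blank, grid, ex_line = 350, em_band = c(381, 426)) {
  k <- which(abs(grid$ex - ex_line) < 1e-9)
  if (length(k) != 1L)
    stop("excitation ", ex_line, " nm absent from the blank grid")
  if (min(grid$em) > em_band[1] || max(grid$em) < em_band[2])
    stop("emission grid only partially covers the Raman band ",
         em_band[1], "-", em_band[2], " nm")
  j <- which(grid$em >= em_band[1] & grid$em <= em_band[2])
  if (length(j) < 2L) stop("Raman band covered by fewer than 2 grid points")
  em <- grid$em[j]
  y <- blank[j, k]
  sum(diff(em) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Raman normalization to blank units
#'
#' Divides every intensity by the blank's Raman band area so that intensities
#' are expressed in Raman Units (R.U.).
#'
#' @param dataset an [eem_dataset] (or a bare matrix).
#' @param blank_area positive scalar from [raman_area()].
#' @return normalized dataset (or matrix).
#' @export
raman_normalize <- function(dataset, blank_area) {
  if (!is.numeric(blank_area) || length(blank_area) != 1L || blank_area <= 0)
    stop("blank area must be a positive scalar")
  if (inherits(dataset, "eem_dataset")) {
    dataset$intensities <- dataset$intensities / blank_area
    return(dataset)
  }
  dataset / blank_area
}

#' Mask scatter bands and the physically meaningless triangle
#'
#' Marks as missing every cell within the given half-width of the first-order
#' Rayleigh line (em = ex), second-order Rayleigh line (em = 2 ex) and the
#' water Raman line (em from the 3382 cm^-1 shift), plus the entire em < ex
#' region where emission would be bluer than excitation. Intensities are not
#' altered — downstream fitting treats masked cells as missing rather than
#' imputing them here.
#'
#' @param dataset an [eem_dataset].
#' @param spec a [scatter_spec]; only the half-widths are used.
#' @return dataset with an updated mask.
#' @export
excise_scatter <- function(dataset, spec = scatter_spec()) {
  stopifnot(inherits(dataset, "eem_dataset"), inherits(spec, "scatter_spec"))
  g <- dataset$grid
  em <- g$em
  bad <- matrix(FALSE, length(em), length(g$ex))
  # a zero half-width disables its band entirely (only the em < ex triangle
  # is masked unconditionally)
  for (k in seq_along(g$ex)) {
    ex <- g$ex[k]
    bad[, k] <- em < ex |
      (spec$rayleigh1_width > 0 & abs(em - ex) <= spec$rayleigh1_width) |
      (spec$rayleigh2_width > 0 & abs(em - 2 * ex) <= spec$rayleigh2_width) |
      (spec$raman_width > 0 &
         abs(em - raman_em_center(ex)) <= spec$raman_width)
  }
  n <- n_samples(dataset)
  dataset$mask <- dataset$mask | aperm(array(bad, c(dim(bad), n)), c(3, 1, 2))
  dataset
}

#' Normalize each sample to unit total signal
#'
#' Divides each sample's EEM by its Frobenius norm over unmasked cells, so
#' every sample contributes equally to the model regardless of overall
#' concentration. The norm is stored in `sample_meta$norm_factor`
#' (multiplied onto any factor already present) for exact reversal by
#' [reverse_normalization()].
#'
#' @param dataset an [eem_dataset].
#' @return normalized dataset with stored factors.
#' @export
normalize_total_signal <- function(dataset) {
  stopifnot(inherits(dataset, "eem_dataset"))
  n <- n_samples(dataset)
  for (i in seq_len(n)) {
    x <- dataset$intensities[i, , ]
    keep <- !dataset$mask[i, , ]
    nf <- sqrt(sum(x[keep]^2))
    if (!is.finite(nf) || nf <= 0)
      stop("sample ", i, " has no positive unmasked signal")
    dataset$intensities[i, , ] <- x / nf
    dataset$sample_meta$norm_factor[i] <- dataset$sample_meta$norm_factor[i] * nf
  }
  dataset
}

#' Undo total-signal normalization on model scores
#'
#' Multiplies each sample's score row by its stored normalization factor so
#' that F_max is reported on the original (pre-normalization) intensity
#' scale. Under unit-maximum loadings the round trip
#' normalize -> fit -> reverse reproduces the raw-scale scores.
#'
#' @param scores sample x component matrix.
#' @param factors per-sample factors (or an [eem_dataset] whose
#'   `sample_meta$norm_factor` is used).
#' @return rescaled score matrix.
#' @export
reverse_normalization <- function(scores, factors) {
  if (inherits(factors, "eem_dataset"))
    factors <- factors$sample_meta$norm_factor
  scores <- as.matrix(scores)
  if (length(factors) != nrow(scores))
    stop("need one normalization factor per sample")
  scores * factors
}

#' Advisory outlier flags from leverage and residuals
#'
#' Flags samples whose score-mode leverage or residual sum of squares exceeds
#' a multiple of the dataset mean — the usual screen for samples that the
#' trilinear model cannot accommodate. Flags are advisory; removal is left to
#' the caller.
#'
#' @param dataset the fitted [eem_dataset].
#' @param model a fitted [parafac_model].
#' @param leverage_mult,resid_mult flag thresholds as multiples of the mean.
#' @return data.frame (class `preprocess_report`) with per-sample leverage,
#'   residual SSE, flag and reason.
#' @export
flag_outliers <- function(dataset, model, leverage_mult = 3, resid_mult = 3) {
  stopifnot(inherits(model, "parafac_model"))
  lev <- leverage(model, "sample")
  res <- residual_sse_by_sample(model, dataset)
  flag_lev <- lev > leverage_mult * mean(lev)
  flag_res <- res > resid_mult * mean(res)
  reason <- rep("", length(lev))
  reason[flag_lev] <- "leverage"
  reason[flag_res & !flag_lev] <- "residual"
  reason[flag_res & flag_lev] <- "leverage+residual"
  out <- data.frame(sample_id = dataset$sample_meta$sample_id,
                    leverage = lev, residual_sse = res,
                    flagged = flag_lev | flag_res, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("preprocess_report", "data.frame")
  out
}

residual_sse_by_sample <- function(model, dataset) {
  recon <- reconstruct(model)
  d <- dim(dataset$intensities)
  out <- numeric(d[1])
  for (i in seq_len(d[1])) {
    keep <- !dataset$mask[i, , ]
    out[i] <- sum((dataset$intensities[i, , ][keep] - recon[i, , ][keep])^2)
  }
  out
}

#' Run the standard correction chain on a dataset
#'
#' Applies, in the canonical order: inner-filter correction (when absorbance
#' spectra are present and `ife = TRUE`), Raman normalization by the blank
#' area, scatter excision, and per-sample total-signal normalization. The
#' order is recorded in the returned attribute `preprocess_steps`.
#'
#' @param dataset an [eem_dataset].
#' @param blank_area Raman band area of the daily blank (skip Raman
#'   normalization if NULL).
#' @param spec [scatter_spec] half-widths for excision.
#' @param ife apply inner-filter correction.
#' @param total_signal apply total-signal normalization.
#' @return preprocessed dataset.
#' @export
preprocess_dataset <- function(dataset, blank_area = NULL,
                               spec = scatter_spec(), ife = TRUE,
                               total_signal = TRUE) {
  steps <- character(0)
  if (ife && !is.null(dataset$absorbance)) {
    dataset <- ife_correct(dataset)
    steps <- c(steps, "ife")
  }
  if (!is.null(blank_area)) {
    dataset <- raman_normalize(dataset, blank_area)
    steps <- c(steps, "raman")
  }
  dataset <- excise_scatter(dataset, spec)
  steps <- c(steps, "excise")
  if (total_signal) {
    dataset <- normalize_total_signal(dataset)
    steps <- c(steps, "total_signal")
  }
  attr(dataset, "preprocess_steps") <- steps
  dataset
}
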