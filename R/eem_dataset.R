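#' EEM dataset container
#'
#' Holds a three-way fluorescence array `x[i, j, k]` (sample x emission x
#' excitation) together with its wavelength grid, a logical missing-value
#' mask of the same shape (TRUE = excluded from modeling), and per-sample
#' metadata. Intensities at masked cells are retained but ignored by the
#' fitting routines.
#'
#' @param intensities numeric 3-way array, dim `(n, J, K)`.
#' @param grid an [eem_grid] with `length(grid$em) == J`, `length(grid$ex) == K`.
#' @param mask logical array of identical dim; defaults to all FALSE.
#' @param sample_meta data.frame with one row per sample; columns `sample_id`,
#'   `source` and `norm_factor` are created if absent (`norm_factor` starts
#'   at 1 and records any total-signal normalization applied later).
#' @param absorbance optional numeric matrix (n x length(abs_wavelengths)) of
#'   decadic absorbances (1 cm path).
#' @param abs_wavelengths wavelengths (nm) of the absorbance columns.
#' @return Object of class `eem_dataset`.
#' @export
eem_dataset <- function(intensities, grid, mask = NULL, sample_meta = NULL,
                        absorbance = NULL, abs_wavelengths = NULL) {
  stopifnot(inherits(grid, "eem_grid"))
  d <- dim(intensities)
  if (length(d) != 3L)
    stop("intensities must be a 3-way array (sample x emission x excitation)")
  if (d[2] != length(grid$em) || d[3] != length(grid$ex))
    stop("array dimensions do not match the wavelength grid")
  if (is.null(mask)) mask <- array(FALSE, dim = d)
  if (!identical(dim(mask), d)) stop("mask shape must match intensities")
  if (any(!is.finite(intensities[!mask])))
    stop("non-missing intensities must be finite")
  n <- d[1]
  if (is.null(sample_meta))
    sample_meta <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                              source = "unknown",
                              norm_factor = 1,
                              stringsAsFactors = FALSE)
  if (nrow(sample_meta) != n) stop("sample_meta must have one row per sample")
  if (is.null(sample_meta$norm_factor)) sample_meta$norm_factor <- 1
  if (any(sample_meta$norm_factor <= 0)) stop("norm factors must be positive")
  if (!is.null(absorbance)) {
    absorbance <- as.matrix(absorbance)
    if (nrow(absorbance) != n || is.null(abs_wavelengths) ||
        ncol(absorbance) != length(abs_wavelengths))
      stop("absorbance must be n x length(abs_wavelengths)")
  }
  structure(list(intensities = intensities, grid = grid, mask = mask,
                 sample_meta = sample_meta, absorbance = absorbance,
                 abs_wavelengths = abs_wavelengths),
            class = "eem_dataset")
}

#' @export
print.eem_dataset <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("eem_dataset: %d samples, %d em x %d ex, %.1f%% masked\n",
              d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

#' Number of samples in an EEM dataset
#' @param dataset an [eem_dataset].
#' @return integer sample count.
#' @export
n_samples <- function(dataset) dim(dataset$intensities)[1]

#' Extract one sample's EEM as an emission x excitation matrix
#' @param dataset an [eem_dataset].
#' @param i sample index.
#' @param apply_mask replace masked cells with NA.
#' @return numeric matrix (em x ex) with wavelength dimnames.
#' @export
eem_matrix <- function(dataset, i, apply_mask = FALSE) {
  m <- dataset$intensities[i, , , drop = TRUE]
  if (apply_mask) m[dataset$mask[i, , ]] <- NA_real_
  dimnames(m) <- list(em = dataset$grid$em, ex = dataset$grid$ex)
  m
}
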