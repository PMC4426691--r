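#' Concentration design for synthetic datasets
#'
#' Per-component concentrations are drawn i.i.d. log-normal: positive and
#' right-skewed, matching the concentration gradients of natural DOM sample
#' sets. The default (median 1, sdlog 0.6) spans roughly a factor of ten
#' between the 5th and 95th percentiles.
#'
#' @param n_samples number of samples.
#' @param meanlog,sdlog log-normal parameters.
#' @param seed integer seed; fully determines the drawn concentrations.
#' @return Object of class `concentration_design`.
#' @export
concentration_design <- function(n_samples, meanlog = 0, sdlog = 0.6,
                                 seed = 1L) {
  if (n_samples < 1L) stop("need at least one sample")
  if (sdlog < 0) stop("sdlog must be >= 0")
  structure(list(n_samples = as.integer(n_samples), meanlog = meanlog,
                 sdlog = sdlog, seed = as.integer(seed)),
            class = "concentration_design")
}

#' Measurement noise model
#'
#' Residual noise e_ijk added on top of the trilinear signal: zero-mean
#' Gaussian with an additive standard deviation (intensity units) plus a
#' multiplicative relative component.
#'
#' @param additive additive sigma, >= 0.
#' @param relative relative (multiplicative) sigma, >= 0.
#' @param seed integer seed.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(additive = 0, relative = 0, seed = 1L) {
  if (additive < 0 || relative < 0) stop("noise sigmas must be >= 0")
  structure(list(additive = additive, relative = relative,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Scatter band specification
#'
#' Describes first/second-order Rayleigh lines (em = ex, em = 2 ex) and the
#' water Raman line. Each band has a half-width (nm, measured along emission)
#' and, for generation, a peak amplitude. The Raman emission center is
#' computed from the excitation wavelength via the fixed 3382 cm^-1 water
#' Raman shift, which places the line at ~397-398 nm for 350 nm excitation.
#'
#' @param rayleigh1_width,rayleigh2_width,raman_width band half-widths (nm).
#' @param rayleigh1_amp,rayleigh2_amp,raman_amp peak amplitudes (intensity
#'   units) used when generating synthetic scatter.
#' @return Object of class `scatter_spec`.
#' @export
scatter_spec <- function(rayleigh1_width = 15, rayleigh2_width = 15,
                         raman_width = 5,
                         rayleigh1_amp = 5, rayleigh2_amp = 1,
                         raman_amp = 0.5) {
  w <- c(rayleigh1_width, rayleigh2_width, raman_width)
  if (any(w < 0)) stop("half-widths must be >= 0")
  structure(list(rayleigh1_width = rayleigh1_width,
                 rayleigh2_width = rayleigh2_width,
                 raman_width = raman_width,
                 rayleigh1_amp = rayleigh1_amp,
                 rayleigh2_amp = rayleigh2_amp,
                 raman_amp = raman_amp),
            class = "scatter_spec")
}

#' Water Raman line position
#'
#' Emission center of the water Raman scatter line for a given excitation
#' wavelength, using the fixed 3382 cm^-1 Raman shift of the OH stretch
#' (~397-398 nm at 350 nm excitation).
#'
#' @param ex_nm excitation wavelength(s) in nm.
#' @return emission wavelength(s) in nm.
#' @export
raman_em_center <- function(ex_nm) 1 / (1 / ex_nm - 3382e-7)

# Scatter surface (em x ex) for one sample; Gaussian profiles along emission
# with sd = half-width / 2 so the band essentially vanishes beyond one
# half-width from the line center.
scatter_surface <- function(grid, spec) {
  em <- grid$em
  J <- length(em)
  K <- length(grid$ex)
  s <- matrix(0, J, K)
  gprof <- function(center, width, amp) {
    if (amp == 0 || width <= 0) return(numeric(J))
    amp * exp(-0.5 * ((em - center) / (width / 2))^2)
  }
  for (k in seq_len(K)) {
    ex <- grid$ex[k]
    s[, k] <- gprof(ex, spec$rayleigh1_width, spec$rayleigh1_amp) +
      gprof(2 * ex, spec$rayleigh2_width, spec$rayleigh2_amp) +
      gprof(raman_em_center(ex), spec$raman_width, spec$raman_amp)
  }
  s
}

#' Simulate CDOM-like absorbance spectra
#'
#' Smooth exponentially decaying spectra, the canonical shape for
#' chromophoric DOM absorbance, scaled linearly with total concentration:
#' `A(lambda) = total * a254 * exp(-slope * (lambda - 254))`.
#'
#' @param totals per-sample total concentrations (sum over components).
#' @param wavelengths nm grid, default 200--800 at 1 nm.
#' @param a254 absorbance at 254 nm per unit total concentration.
#' @param slope exponential spectral slope (nm^-1).
#' @return numeric matrix, samples x wavelengths.
#' @export
simulate_absorbance <- function(totals, wavelengths = 200:800,
                                a254 = 0.05, slope = 0.015) {
  shape <- a254 * exp(-slope * (wavelengths - 254))
  out <- outer(as.numeric(totals), shape)
  colnames(out) <- wavelengths
  out
}

#' Attenuate an EEM by the inner-filter effect
#'
#' Applies the forward inner-filter attenuation
#' `x_att(j, k) = x(j, k) * 10^(-(A(ex_k) + A(em_j)) / 2)` so that
#' [ife_correct()] restores the original surface exactly. Used by the
#' generator to exercise correction round trips.
#'
#' @param eem emission x excitation matrix.
#' @param grid [eem_grid] of the matrix.
#' @param absorbance numeric vector of absorbances on `abs_wavelengths`.
#' @param abs_wavelengths wavelengths (nm) of `absorbance`.
#' @return attenuated matrix.
#' @export
apply_ife <- function(eem, grid, absorbance, abs_wavelengths) {
  f <- ife_factor(grid, absorbance, abs_wavelengths)
  eem / f
}

# 10^((A_ex + A_em)/2) correction surface shared by apply_ife / ife_correct
ife_factor <- function(grid, absorbance, abs_wavelengths) {
  need <- c(grid$ex, grid$em)
  if (min(need) < min(abs_wavelengths) || max(need) > max(abs_wavelengths))
    stop("absorbance spectrum does not cover the EEM wavelength range")
  a_ex <- stats::approx(abs_wavelengths, absorbance, xout = grid$ex)$y
  a_em <- stats::approx(abs_wavelengths, absorbance, xout = grid$em)$y
  10^(outer(a_em, a_ex, "+") / 2)
}

#' Simulate a multi-source EEM dataset with known trilinear truth
#'
#' Draws per-component concentrations from `design`, builds the noiseless
#' trilinear tensor `x_ijk = sum_f a_if b_jf c_kf` from the library's
#' Gaussian-band loadings (unit maximum, so scores are F_max), then adds
#' optional scatter and Gaussian noise. The exact factors used are returned
#' as ground truth. Identical seeds reproduce the dataset bitwise.
#'
#' @param library a [spectral_library].
#' @param components character vector naming library components to include.
#' @param design a [concentration_design].
#' @param grid an [eem_grid]; default [default_grid()].
#' @param noise a [noise_model]; default noiseless.
#' @param scatter a [scatter_spec] or NULL (no scatter).
#' @param source_label source tag stored per sample.
#' @param with_absorbance also simulate absorbance spectra and attenuate the
#'   EEMs by the inner-filter effect (breaking exact trilinearity until
#'   corrected); default FALSE.
#' @param concentrations optional explicit n x F score matrix overriding the
#'   log-normal draw (columns follow `components`); useful for controlled
#'   designs.
#' @return list with `dataset` (an [eem_dataset]) and `truth` (list with
#'   `scores`, `em_loadings`, `ex_loadings`, `components`).
#' @export
simulate_dataset <- function(library, components, design,
                             grid = default_grid(),
                             noise = noise_model(),
                             scatter = NULL,
                             source_label = "synthetic",
                             with_absorbance = FALSE,
                             concentrations = NULL) {
  stopifnot(inherits(design, "concentration_design"),
            inherits(noise, "noise_model"))
  if (length(components) == 0L) stop("component subset must be nonempty")
  missing_c <- setdiff(components, names(library))
  if (length(missing_c))
    stop("components not in library: ", paste(missing_c, collapse = ", "))

  n <- design$n_samples
  F <- length(components)
  J <- length(grid$em)
  K <- length(grid$ex)

  B <- matrix(0, J, F); C <- matrix(0, K, F)
  for (f in seq_len(F)) {
    ld <- component_loadings(library[[components[f]]], grid)
    B[, f] <- ld$em
    C[, f] <- ld$ex
  }
  colnames(B) <- colnames(C) <- components

  if (is.null(concentrations)) {
    set.seed(design$seed)
    A <- matrix(stats::rlnorm(n * F, design$meanlog, design$sdlog), n, F)
  } else {
    A <- as.matrix(concentrations)
    if (!identical(dim(A), c(n, F)) || any(A < 0))
      stop("concentrations must be a non-negative n x F matrix")
  }
  colnames(A) <- components

  # x[i,j,k] via mode-1 unfolding against the Khatri-Rao product C (x) B
  Z <- khatri_rao(C, B)                      # (J*K) x F, j fastest
  X <- array(A %*% t(Z), dim = c(n, J, K))

  if (!is.null(scatter)) {
    s <- scatter_surface(grid, scatter)
    X <- X + rep(s, each = n)
  }

  absorb <- NULL; abs_wl <- NULL
  if (with_absorbance) {
    abs_wl <- 200:800
    absorb <- simulate_absorbance(rowSums(A), abs_wl)
    for (i in seq_len(n))
      X[i, , ] <- apply_ife(X[i, , ], grid, absorb[i, ], abs_wl)
  }

  if (noise$additive > 0 || noise$relative > 0) {
    set.seed(noise$seed)
    if (noise$relative > 0)
      X <- X * (1 + array(stats::rnorm(length(X), 0, noise$relative), dim(X)))
    if (noise$additive > 0)
      X <- X + array(stats::rnorm(length(X), 0, noise$additive), dim(X))
  }

  meta <- data.frame(sample_id = sprintf("%s_%03d", source_label, seq_len(n)),
                     source = source_label, norm_factor = 1,
                     stringsAsFactors = FALSE)
  ds <- eem_dataset(X, grid, sample_meta = meta,
                    absorbance = absorb, abs_wavelengths = abs_wl)
  truth <- list(scores = A, em_loadings = B, ex_loadings = C,
                components = components)
  list(dataset = ds, truth = truth)
}

#' Append contaminated "cocktail" samples to a base dataset
#'
#' Emulates mixture monitoring scenarios (e.g. 76 river NOM samples plus 10
#' algal or effluent samples): generates `n_contaminated` new samples that
#' contain the base components plus intruder components, and appends them to
#' the base dataset with a distinguishing source label.
#'
#' @param base `list(dataset, truth)` as returned by [simulate_dataset()],
#'   or an [eem_dataset] (then `base_library`/`base_components` are required).
#' @param base_library,base_components library and subset generating the base
#'   signal in contaminated samples; default taken from `base$truth` is not
#'   possible, so they must be supplied.
#' @param intruder_library a [spectral_library] of foreign components.
#' @param intruder_components names within `intruder_library`.
#' @param n_contaminated number of appended samples, >= 1.
#' @param design [concentration_design] for the appended samples.
#' @param grid grid of the base dataset (checked for identity).
#' @param noise [noise_model] for appended samples.
#' @param scatter optional [scatter_spec].
#' @param intruder_amplitude multiplier on intruder concentrations.
#' @param source_label label for appended samples.
#' @return list with `dataset` (combined [eem_dataset]) and `truth` for the
#'   appended samples.
#' @export
make_cocktail <- function(base, base_library, base_components,
                          intruder_library, intruder_components,
                          n_contaminated, design,
                          grid = NULL,
                          noise = noise_model(),
                          scatter = NULL,
                          intruder_amplitude = 1,
                          source_label = "cocktail") {
  if (is.list(base) && !inherits(base, "eem_dataset") && !is.null(base$dataset))
    base <- base$dataset
  stopifnot(inherits(base, "eem_dataset"))
  if (n_contaminated < 1L) stop("n_contaminated must be >= 1")
  if (is.null(grid)) grid <- base$grid
  if (!isTRUE(all.equal(grid$ex, base$grid$ex)) ||
      !isTRUE(all.equal(grid$em, base$grid$em)))
    stop("grid mismatch between base dataset and cocktail grid")

  merged <- c(unclass(base_library)[base_components],
              unclass(intruder_library)[intruder_components])
  names(merged) <- c(base_components, paste0("intr_", intruder_components))
  lib <- spectral_library(merged)
  design$n_samples <- as.integer(n_contaminated)
  sim <- simulate_dataset(lib, names(merged), design, grid = grid,
                          noise = noise, scatter = scatter,
                          source_label = source_label)
  add <- sim$dataset
  if (intruder_amplitude != 1) {
    idx <- grepl("^intr_", names(merged))
    Aint <- sim$truth$scores
    Aint[, idx] <- Aint[, idx] * intruder_amplitude
    Z <- khatri_rao(sim$truth$ex_loadings, sim$truth$em_loadings)
    Xnew <- array(Aint %*% t(Z), dim = dim(add$intensities))
    delta <- Xnew - array(sim$truth$scores %*% t(Z), dim = dim(add$intensities))
    add$intensities <- add$intensities + delta
    sim$truth$scores <- Aint
  }

  comb <- eem_dataset(
    abind3(base$intensities, add$intensities),
    grid,
    mask = abind3(base$mask, add$mask),
    sample_meta = rbind(base$sample_meta[, c("sample_id", "source", "norm_factor")],
                        add$sample_meta[, c("sample_id", "source", "norm_factor")])
  )
  list(dataset = comb, truth = sim$truth)
}

# bind two (n, J, K) arrays along the sample mode
abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[2:3], db[2:3]))
  out <- array(NA, dim = c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  storage.mode(out) <- if (is.logical(a) && is.logical(b)) "logical" else "double"
  out
}

# Khatri-Rao (column-wise Kronecker) product: column f = kron(C[,f], B[,f])
khatri_rao <- function(C, B) {
  F <- ncol(C)
  out <- matrix(0, nrow(B) * nrow(C), F)
  for (f in seq_len(F)) out[, f] <- kronecker(C[, f], B[, f])
  out
}
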