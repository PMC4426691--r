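#' Peak location of a fitted component
#'
#' Wavelengths of the loading maxima in each mode; ties resolve toward the
#' shorter wavelength. Secondary excitation maxima — local maxima reaching at
#' least half the global maximum, a common feature of humic-like components —
#' are reported alongside the primary peak.
#'
#' @param model a [parafac_model].
#' @param f component index.
#' @param secondary_frac threshold for reporting secondary excitation maxima.
#' @return list with `ex`, `em` (nm) and `secondary_ex` (possibly empty).
#' @export
peak_location <- function(model, f, secondary_frac = 0.5) {
  stopifnot(inherits(model, "parafac_model"))
  b <- model$em_loadings[, f]
  c_ <- model$ex_loadings[, f]
  if (diff(range(b)) == 0 || diff(range(c_)) == 0)
    stop("flat loading has no peak")
  em_peak <- model$grid$em[which.max(b)]
  ex_idx <- which.max(c_)
  ex_peak <- model$grid$ex[ex_idx]
  sec <- integer(0)
  K <- length(c_)
  if (K >= 3) {
    is_local <- c(FALSE, c_[2:(K - 1)] > c_[1:(K - 2)] &
                    c_[2:(K - 1)] >= c_[3:K], FALSE)
    sec <- setdiff(which(is_local & c_ >= secondary_frac * max(c_)), ex_idx)
  }
  list(ex = ex_peak, em = em_peak, secondary_ex = model$grid$ex[sec])
}

#' Per-wavelength regression of intensity on component F_max
#'
#' For one component, regresses the raw intensity at every unmasked
#' wavelength pair (across samples) against the component's F_max, producing
#' R-squared and slope maps over the EEM plane. Where a single component
#' dominates, R^2 approaches 1 and the peak pixel can proxy for the modeled
#' intensity — the basis of peak-picking online monitoring. Spectral overlap
#' from other (possibly foreign) components degrades the map.
#'
#' @param dataset an [eem_dataset] on the physical intensity scale.
#' @param fmax_f per-sample F_max values for the component (n >= 3).
#' @return object of class `regression_map`: matrices `r_squared` and `slope`
#'   (emission x excitation, NA where any sample is masked), plus the grid.
#' @export
regression_map <- function(dataset, fmax_f) {
  stopifnot(inherits(dataset, "eem_dataset"))
  n <- n_samples(dataset)
  if (length(fmax_f) != n) stop("fmax values not aligned with dataset samples")
  if (n < 3L) stop("need at least 3 samples")
  if (stats::var(fmax_f) == 0) stop("zero variance in F_max")
  d <- dim(dataset$intensities)
  X <- matrix(dataset$intensities, n)        # n x (J*K)
  any_masked <- matrix(apply(dataset$mask, c(2, 3), any), d[2] * d[3])
  f <- fmax_f - mean(fmax_f)
  varf <- sum(f^2)
  Xc <- sweep(X, 2, colMeans(X))
  cov_xf <- drop(crossprod(Xc, f))           # per-pixel covariance * (n-1)
  var_x <- colSums(Xc^2)
  slope <- cov_xf / varf
  r2 <- ifelse(var_x > 0, cov_xf^2 / (varf * var_x), NA_real_)
  r2 <- pmin(pmax(r2, 0), 1)
  slope[any_masked] <- NA_real_
  r2[any_masked] <- NA_real_
  structure(list(r_squared = matrix(r2, d[2], d[3]),
                 slope = matrix(slope, d[2], d[3]),
                 grid = dataset$grid),
            class = "regression_map")
}

map_value_at <- function(map, em, ex) {
  j <- which.min(abs(map$grid$em - em))
  k <- which.min(abs(map$grid$ex - ex))
  c(r_squared = map$r_squared[j, k], slope = map$slope[j, k])
}

#' Peak-monitoring report for all components of a model
#'
#' One row per component: the peak location, R^2 and slope of the
#' intensity-vs-F_max regression at the peak pixel, and the fraction of
#' unmasked pixels within a +/- `window` nm box around the peak whose R^2
#' reaches `r2_threshold` (the "high-R^2 area" a monitoring wavelength could
#' be placed in).
#'
#' @param model a [parafac_model].
#' @param dataset the evaluation [eem_dataset] (physical intensity scale).
#' @param fmax_values optional sample x component F_max matrix; defaults to
#'   [fmax()] of the model (use [reverse_normalization()] first when the
#'   model was fitted on total-signal-normalized data).
#' @param window half-width (nm) of the reporting box.
#' @param r2_threshold R^2 level defining the high-R^2 area.
#' @return data.frame of class `peak_monitor_report` with columns
#'   `component`, `peak_ex`, `peak_em`, `r_squared`, `slope`,
#'   `high_r2_area`; the per-component maps are attached as attribute
#'   `maps`.
#' @export
peak_monitor_report <- function(model, dataset, fmax_values = NULL,
                                window = 25, r2_threshold = 0.9) {
  stopifnot(inherits(model, "parafac_model"))
  if (is.null(fmax_values)) fmax_values <- fmax(model)
  rows <- vector("list", model$ncomp)
  maps <- vector("list", model$ncomp)
  for (f in seq_len(model$ncomp)) {
    pk <- peak_location(model, f)
    map <- regression_map(dataset, fmax_values[, f])
    at <- map_value_at(map, pk$em, pk$ex)
    inbox <- outer(abs(map$grid$em - pk$em) <= window,
                   abs(map$grid$ex - pk$ex) <= window, "&")
    vals <- map$r_squared[inbox]
    vals <- vals[!is.na(vals)]
    rows[[f]] <- data.frame(component = f, peak_ex = pk$ex, peak_em = pk$em,
                            r_squared = at[["r_squared"]],
                            slope = at[["slope"]],
                            high_r2_area = if (length(vals))
                              mean(vals >= r2_threshold) else NA_real_)
    maps[[f]] <- map
  }
  out <- do.call(rbind, rows)
  attr(out, "maps") <- maps
  class(out) <- c("peak_monitor_report", "data.frame")
  out
}

#' Clean-versus-cocktail contamination experiment
#'
#' Quantifies how intruding foreign fluorophores degrade peak-picking
#' monitoring: simulates a clean multi-sample dataset from the base library,
#' then a cocktail dataset in which `n_contaminated` appended samples also
#' contain an intruder whose emission peak sits `delta_em` nm from a chosen
#' base component. Both datasets are fitted with the same number of
#' components and peak-monitoring reports are produced; the drop in R^2 at
#' each base component's peak measures the damage.
#'
#' @param base_library [spectral_library] of resident components.
#' @param base_components names of base components to simulate.
#' @param intruder_of name of the base component the intruder mimics.
#' @param delta_em emission offset (nm) of the intruder from that component.
#' @param delta_ex excitation offset (nm), default 0.
#' @param n_base,n_contaminated sample counts (clean base; appended cocktail).
#' @param intruder_amplitude multiplier on intruder concentrations.
#' @param grid [eem_grid].
#' @param noise [noise_model].
#' @param seed master seed; derives all stage seeds.
#' @param nstarts,maxit,tol fitting controls.
#' @return list of class `contamination_result`: `clean_report`,
#'   `cocktail_report`, `delta_r2` (clean minus cocktail R^2 at each base
#'   peak), `clean_model`, `cocktail_model`.
#' @export
contamination_experiment <- function(base_library, base_components,
                                     intruder_of = base_components[1],
                                     delta_em = 15, delta_ex = 0,
                                     n_base = 76, n_contaminated = 10,
                                     intruder_amplitude = 1,
                                     grid = default_grid(),
                                     noise = noise_model(relative = 0.01,
                                                         seed = 11L),
                                     seed = 1L, nstarts = 4, maxit = 800,
                                     tol = 1e-8) {
  if (delta_em < 0) stop("delta_em must be >= 0")
  stopifnot(intruder_of %in% base_components)
  F <- length(base_components)
  seed <- as.integer(seed)

  base <- simulate_dataset(base_library, base_components,
                           concentration_design(n_base, seed = seed),
                           grid = grid, noise = noise, source_label = "base")
  intruder <- shift_component(base_library[[intruder_of]],
                              delta_ex = delta_ex, delta_em = delta_em)
  ilib <- spectral_library(list(intruder = intruder))
  noise2 <- noise
  noise2$seed <- noise$seed + 1L
  cock <- make_cocktail(base, base_library, base_components,
                        ilib, "intruder", n_contaminated,
                        concentration_design(n_contaminated, seed = seed + 1L),
                        grid = grid, noise = noise2,
                        intruder_amplitude = intruder_amplitude)

  # the cocktail model gets one extra component for the intruder: spectral
  # overlap at the monitoring pixel, not model misspecification, is the
  # degradation mechanism under study (at delta 0 the extra component merges
  # with its base twin and the matched component count drops)
  clean_model <- parafac_fit(base$dataset, F, nstarts = nstarts,
                             maxit = maxit, tol = tol, seed = seed)
  cock_model <- suppressWarnings(
    parafac_fit(cock$dataset, F + 1L, nstarts = nstarts,
                maxit = maxit, tol = tol, seed = seed))

  clean_report <- peak_monitor_report(clean_model, base$dataset)
  cock_report <- peak_monitor_report(cock_model, cock$dataset)

  # align cocktail components to the clean model so delta R^2 is per base peak
  mm <- match_components(clean_model, cock_model)
  paired <- mm[!is.na(mm$comp_a) & !is.na(mm$comp_b), ]
  delta_r2 <- rep(NA_real_, F)
  for (r in seq_len(nrow(paired))) {
    a <- paired$comp_a[r]; b <- paired$comp_b[r]
    # evaluate both models' maps at the CLEAN peak location
    pk <- peak_location(clean_model, a)
    map_cock <- attr(cock_report, "maps")[[b]]
    at_cock <- map_value_at(map_cock, pk$em, pk$ex)
    delta_r2[a] <- clean_report$r_squared[a] - at_cock[["r_squared"]]
  }
  structure(list(clean_report = clean_report, cocktail_report = cock_report,
                 delta_r2 = delta_r2, clean_model = clean_model,
                 cocktail_model = cock_model, matches = mm),
            class = "contamination_result")
}
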