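#' Excitation/emission wavelength grid
#'
#' Defines the rectangular wavelength grid an EEM is measured on. The
#' conventional instrument grid for DOM work scans excitation 220--450 nm in
#' 5 nm steps and emission 250--550 nm in 1 nm steps; the default synthetic
#' grid halves the emission resolution (2 nm) to keep simulated tensors small.
#'
#' @param ex numeric vector of excitation wavelengths (nm), strictly increasing.
#' @param em numeric vector of emission wavelengths (nm), strictly increasing.
#' @return An object of class `eem_grid` with elements `ex` and `em`.
#' @examples
#' g <- eem_grid(seq(220, 450, 5), seq(250, 550, 2))
#' length(g$ex); length(g$em)
#' @export
eem_grid <- function(ex, em) {
  ex <- as.numeric(ex)
  em <- as.numeric(em)
  if (length(ex) < 2L || length(em) < 2L)
    stop("grid needs at least two wavelengths per mode")
  if (any(diff(ex) <= 0) || any(diff(em) <= 0))
    stop("wavelengths must be strictly increasing")
  structure(list(ex = ex, em = em), class = "eem_grid")
}

#' Default synthetic measurement grid
#'
#' Excitation 220--450 nm step 5; emission 250--550 nm at `em_step` (default
#' 2 nm). With `em_step = 1` this is the full instrument grid. The emission
#' step must resolve the water Raman integration band 381--426 nm with at
#' least two grid points.
#'
#' @param em_step emission step in nm.
#' @param ex_step excitation step in nm.
#' @return An `eem_grid`.
#' @export
default_grid <- function(em_step = 2, ex_step = 5) {
  g <- eem_grid(seq(220, 450, by = ex_step), seq(250, 550, by = em_step))
  n_band <- sum(g$em >= 381 & g$em <= 426)
  if (n_band < 2L)
    stop("emission step too coarse: Raman band 381-426 nm covered by < 2 points")
  g
}

#' @export
print.eem_grid <- function(x, ...) {
  cat(sprintf("eem_grid: ex %g-%g nm (%d pts), em %g-%g nm (%d pts)\n",
              min(x$ex), max(x$ex), length(x$ex),
              min(x$em), max(x$em), length(x$em)))
  invisible(x)
}
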