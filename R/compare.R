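#' Tucker congruence coefficient
#'
#' Cosine similarity between two loading vectors on the same wavelength grid:
#' `r_c = sum(x * y) / sqrt(sum(x^2) * sum(y^2))`. Scale-invariant up to
#' sign; for non-negative loadings it lies in [0, 1].
#'
#' @param x,y numeric vectors of equal length >= 2, not all zero.
#' @return scalar in [-1, 1].
#' @export
tucker_congruence <- function(x, y) {
  if (length(x) != length(y))
    stop("loading vectors must be on the same wavelength grid")
  if (length(x) < 2L) stop("vectors must have length >= 2")
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) stop("zero vector has no congruence")
  sum(x * y) / sqrt(sx * sy)
}

#' Classify a congruence value
#'
#' Conventional reading of the Tucker coefficient for spectral loadings:
#' below 0.85 the factors are dissimilar, 0.85 up to (but excluding) 0.95 is
#' a fair similarity, and 0.95 or above means the factors can be considered
#' equal. The 0.95 boundary is closed on the "equal" side.
#'
#' @param r_c congruence value(s) in [-1, 1].
#' @return character vector: "dissimilar", "fair" or "equal".
#' @export
classify_similarity <- function(r_c) {
  if (any(r_c < -1 - 1e-12 | r_c > 1 + 1e-12))
    stop("congruence must lie in [-1, 1]")
  out <- rep("dissimilar", length(r_c))
  out[r_c >= 0.85] <- "fair"
  out[r_c >= 0.95] <- "equal"
  out
}

# exhaustive optimal assignment maximizing total score; nr <= 8 kept small by
# the component counts in play (3-7), so brute force over permutations is
# exact and dependency-free.
best_assignment <- function(score) {
  nr <- nrow(score); nc <- ncol(score)
  stopifnot(nr <= nc)
  if (nr > 8L) stop("assignment supports at most 8 components per model")
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  cols <- utils::combn(nc, nr, simplify = FALSE)
  best <- NULL; best_val <- -Inf
  for (cs in cols) for (p in perms(cs)) {
    val <- sum(score[cbind(seq_len(nr), p)])
    if (val > best_val) { best_val <- val; best <- p }
  }
  best
}

#' Match components across two PARAFAC models
#'
#' Computes excitation and emission Tucker congruences between every pair of
#' components and finds the one-to-one assignment maximizing the summed
#' combined score (product of the two modes' congruences — both spectra must
#' agree for a pair to score well). When the models have different component
#' counts, unmatched components are reported with their best unilateral
#' combined score. The similarity class of a match is based on the weaker of
#' its two modes.
#'
#' @param model_a,model_b fitted [parafac_model]s on identical grids.
#' @return data.frame of class `component_match`: `comp_a`, `comp_b` (NA if
#'   unmatched), `rc_ex`, `rc_em`, `combined`, `class`.
#' @export
match_components <- function(model_a, model_b) {
  stopifnot(inherits(model_a, "parafac_model"),
            inherits(model_b, "parafac_model"))
  if (!isTRUE(all.equal(model_a$grid$ex, model_b$grid$ex)) ||
      !isTRUE(all.equal(model_a$grid$em, model_b$grid$em)))
    stop("models are fitted on different wavelength grids")
  Fa <- model_a$ncomp; Fb <- model_b$ncomp
  rc_ex <- matrix(0, Fa, Fb); rc_em <- matrix(0, Fa, Fb)
  safe_rc <- function(x, y)                 # degenerate zero components score 0
    if (sum(x^2) == 0 || sum(y^2) == 0) 0 else tucker_congruence(x, y)
  for (i in seq_len(Fa)) for (j in seq_len(Fb)) {
    rc_ex[i, j] <- safe_rc(model_a$ex_loadings[, i], model_b$ex_loadings[, j])
    rc_em[i, j] <- safe_rc(model_a$em_loadings[, i], model_b$em_loadings[, j])
  }
  combined <- rc_ex * rc_em

  swap <- Fa > Fb
  sc <- if (swap) t(combined) else combined
  assign_small <- best_assignment(sc)

  if (!swap) {
    comp_a <- seq_len(Fa); comp_b <- assign_small
  } else {
    comp_a <- assign_small; comp_b <- seq_len(Fb)
  }
  rows <- data.frame(comp_a = comp_a, comp_b = comp_b)
  rows$rc_ex <- rc_ex[cbind(rows$comp_a, rows$comp_b)]
  rows$rc_em <- rc_em[cbind(rows$comp_a, rows$comp_b)]
  rows$combined <- rows$rc_ex * rows$rc_em
  rows$class <- classify_similarity(pmin(rows$rc_ex, rows$rc_em))

  # unmatched components of the larger model, best unilateral score
  if (Fa != Fb) {
    if (Fa > Fb) {
      left <- setdiff(seq_len(Fa), rows$comp_a)
      extra <- data.frame(comp_a = left, comp_b = NA_integer_,
                          rc_ex = NA_real_, rc_em = NA_real_,
                          combined = apply(combined[left, , drop = FALSE], 1, max),
                          class = NA_character_)
    } else {
      left <- setdiff(seq_len(Fb), rows$comp_b)
      extra <- data.frame(comp_a = NA_integer_, comp_b = left,
                          rc_ex = NA_real_, rc_em = NA_real_,
                          combined = apply(combined[, left, drop = FALSE], 2, max),
                          class = NA_character_)
    }
    rows <- rbind(rows, extra)
  }
  rows <- rows[order(rows$comp_a, rows$comp_b, na.last = TRUE), ]
  rownames(rows) <- NULL
  class(rows) <- c("component_match", "data.frame")
  rows
}

#' Regress one model's F_max on another's for a matched component
#'
#' Ordinary least squares with intercept of `fmax_b` on `fmax_a` over the
#' same samples, returning the squared Pearson correlation and the slope.
#' Used to judge whether two alternative models (e.g. a global and an
#' individual-source model) are interchangeable for quantifying a component.
#'
#' @param fmax_a,fmax_b per-sample F_max values, same samples, same order,
#'   n >= 3.
#' @return list with `r_squared`, `slope`, `intercept`, `n`.
#' @export
cross_model_fmax_regression <- function(fmax_a, fmax_b) {
  if (length(fmax_a) != length(fmax_b)) stop("sample vectors differ in length")
  n <- length(fmax_a)
  if (n < 3L) stop("need at least 3 samples")
  if (stats::var(fmax_a) == 0) stop("zero variance in predictor F_max")
  fit <- stats::lm(fmax_b ~ fmax_a)
  list(r_squared = stats::cor(fmax_a, fmax_b)^2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = n)
}
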