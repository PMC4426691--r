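#' Write a single EEM to CSV
#'
#' Layout mirrors spectrofluorometer exports: first row holds the excitation
#' wavelengths (first cell empty), first column the emission wavelengths,
#' each cell the intensity. Missing (masked) cells are written blank. Values
#' are printed with 17 significant digits so round trips are lossless.
#'
#' @param eem emission x excitation matrix (NA = missing).
#' @param grid its [eem_grid].
#' @param path output file.
#' @export
write_eem_csv <- function(eem, grid, path) {
  header <- paste(c("", format(grid$ex, trim = TRUE)), collapse = ",")
  body <- vapply(seq_along(grid$em), function(j) {
    vals <- vapply(eem[j, ], function(v)
      if (is.na(v)) "" else sprintf("%.17g", v), character(1))
    paste(c(format(grid$em[j], trim = TRUE), vals), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Read a single EEM from CSV
#'
#' Inverse of [write_eem_csv()]. Axes must be strictly increasing; blank
#' cells become missing values.
#'
#' @param path CSV file.
#' @return list with `eem` (matrix, NA at blanks), `grid`, `mask`.
#' @export
read_eem_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("EEM file too short: ", path)
  # appending a comma before splitting preserves trailing blank fields
  split_row <- function(s) {
    v <- strsplit(paste0(s, ","), ",", fixed = TRUE)[[1]]
    length(v) <- max(length(v), lengths(regmatches(s, gregexpr(",", s))) + 1L)
    v[is.na(v)] <- ""
    v
  }
  hdr <- split_row(lines[1])
  ex <- suppressWarnings(as.numeric(hdr[-1]))
  if (anyNA(ex)) stop("non-numeric excitation header in ", path)
  ncol_exp <- length(ex) + 1L
  rows <- lapply(lines[-1], split_row)
  nfield <- vapply(rows, length, integer(1))
  if (any(nfield != ncol_exp))
    stop("ragged rows in ", path)
  em <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 1L)))
  if (anyNA(em)) stop("non-numeric emission column in ", path)
  if (any(diff(ex) <= 0) || any(diff(em) <= 0))
    stop("non-monotone wavelength axes in ", path)
  m <- matrix(NA_real_, length(em), length(ex))
  for (j in seq_along(rows)) {
    vals <- rows[[j]][-1]
    length(vals) <- length(ex)            # pad trailing blanks
    bad <- !(vals %in% c("", NA))
    num <- suppressWarnings(as.numeric(vals))
    if (any(bad & is.na(num))) stop("non-numeric cell in ", path)
    m[j, ] <- num
  }
  list(eem = m, grid = eem_grid(ex, em), mask = is.na(m))
}

#' Write an EEM dataset directory
#'
#' One CSV per sample plus `manifest.csv` (sample_id, file, source,
#' norm_factor, absorbance_file) and, when available, per-sample absorbance
#' CSVs and a `truth.json` with generator ground truth.
#'
#' @param dataset an [eem_dataset].
#' @param dir output directory (created).
#' @param truth optional generator truth list to serialize.
#' @export
write_dataset <- function(dataset, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_samples(dataset)
  meta <- dataset$sample_meta
  files <- sprintf("%s.csv", meta$sample_id)
  abs_files <- rep("", n)
  for (i in seq_len(n)) {
    m <- dataset$intensities[i, , ]
    m[dataset$mask[i, , ]] <- NA_real_
    write_eem_csv(m, dataset$grid, file.path(dir, files[i]))
    if (!is.null(dataset$absorbance)) {
      abs_files[i] <- sprintf("%s_abs.csv", meta$sample_id[i])
      utils::write.csv(data.frame(wavelength = dataset$abs_wavelengths,
                                  absorbance = dataset$absorbance[i, ]),
                       file.path(dir, abs_files[i]), row.names = FALSE)
    }
  }
  manifest <- data.frame(sample_id = meta$sample_id, file = files,
                         source = meta$source,
                         norm_factor = meta$norm_factor,
                         absorbance_file = abs_files,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read an EEM dataset directory
#'
#' Samples are stacked in manifest order; all must share one wavelength grid.
#'
#' @param dir directory written by [write_dataset()].
#' @return an [eem_dataset].
#' @export
read_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.csv")
  if (!file.exists(mf_path)) stop("manifest.csv missing in ", dir)
  manifest <- utils::read.csv(mf_path, stringsAsFactors = FALSE)
  n <- nrow(manifest)
  first <- NULL
  X <- NULL; M <- NULL
  absorb <- NULL; abs_wl <- NULL
  for (i in seq_len(n)) {
    p <- file.path(dir, manifest$file[i])
    if (!file.exists(p)) stop("manifest references missing file: ", p)
    s <- read_eem_csv(p)
    if (is.null(first)) {
      first <- s$grid
      X <- array(NA_real_, c(n, length(first$em), length(first$ex)))
      M <- array(FALSE, dim(X))
    } else if (!isTRUE(all.equal(first$ex, s$grid$ex)) ||
               !isTRUE(all.equal(first$em, s$grid$em))) {
      stop("grid mismatch in ", manifest$file[i])
    }
    mat <- s$eem
    mat[s$mask] <- 0
    X[i, , ] <- mat
    M[i, , ] <- s$mask
    af <- manifest$absorbance_file[i]
    if (!is.null(af) && !is.na(af) && nzchar(af)) {
      ab <- utils::read.csv(file.path(dir, af))
      if (is.null(absorb)) {
        abs_wl <- ab$wavelength
        absorb <- matrix(NA_real_, n, length(abs_wl))
      }
      absorb[i, ] <- ab$absorbance
    }
  }
  nf <- if (!is.null(manifest$norm_factor)) manifest$norm_factor else rep(1, n)
  eem_dataset(X, first, mask = M,
              sample_meta = data.frame(sample_id = manifest$sample_id,
                                       source = manifest$source,
                                       norm_factor = nf,
                                       stringsAsFactors = FALSE),
              absorbance = absorb, abs_wavelengths = abs_wl)
}

#' Serialize a fitted model to a directory
#'
#' Writes `model.json` (diagnostics and config), `scores.csv`,
#' `em_loadings.csv` and `ex_loadings.csv` with wavelength/sample headers.
#'
#' @param model a [parafac_model].
#' @param dir output directory (created).
#' @export
write_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(ncomp = model$ncomp, sse = model$sse, expl_var = model$expl_var,
         iterations = model$iterations, converged = model$converged,
         best_start = model$best_start, config = model$config,
         grid = list(ex = model$grid$ex, em = model$grid$em)),
    file.path(dir, "model.json"), digits = NA, auto_unbox = TRUE)
  write_csv_full(data.frame(sample = seq_len(nrow(model$scores)),
                            model$scores),
                 file.path(dir, "scores.csv"))
  write_csv_full(data.frame(em = model$grid$em, model$em_loadings),
                 file.path(dir, "em_loadings.csv"))
  write_csv_full(data.frame(ex = model$grid$ex, model$ex_loadings),
                 file.path(dir, "ex_loadings.csv"))
  invisible(dir)
}

# write.csv at full double precision (%.17g) so round trips are lossless
write_csv_full <- function(df, path) {
  for (col in names(df))
    if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a serialized model directory
#'
#' @param dir directory written by [write_model()].
#' @return a [parafac_model].
#' @export
read_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  sc <- utils::read.csv(file.path(dir, "scores.csv"))
  bm <- utils::read.csv(file.path(dir, "em_loadings.csv"))
  cm <- utils::read.csv(file.path(dir, "ex_loadings.csv"))
  structure(list(scores = as.matrix(sc[, -1, drop = FALSE]),
                 em_loadings = as.matrix(bm[, -1, drop = FALSE]),
                 ex_loadings = as.matrix(cm[, -1, drop = FALSE]),
                 ncomp = meta$ncomp, sse = meta$sse,
                 expl_var = meta$expl_var, iterations = meta$iterations,
                 converged = meta$converged, best_start = meta$best_start,
                 grid = eem_grid(meta$grid$ex, meta$grid$em),
                 config = meta$config),
            class = "parafac_model")
}
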