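#' Construct a spectral data set
#'
#' Bundles an absorbance matrix with its wavelength axis and, optionally,
#' reference analyte values and sample identifiers. This is the container
#' every fitting and transfer function in the package consumes.
#'
#' @param spectra numeric matrix, samples in rows, wavelength channels in
#'   columns (absorbance units).
#' @param wavelengths numeric vector of channel wavelengths in nm, strictly
#'   increasing, one per column of `spectra`.
#' @param reference optional numeric vector of reference concentrations /
#'   property values, one per sample.
#' @param ids optional character vector of sample labels, one per sample.
#'   Defaults to `"s1", "s2", ...`.
#'
#' @return An object of class `"spectra_set"`: a list with elements
#'   `spectra`, `wavelengths`, `reference` (possibly `NULL`) and `ids`.
#' @examples
#' s <- spectra_set(matrix(runif(6), 2, 3), c(1100, 1102, 1104),
#'                  reference = c(9.1, 10.2))
#' s
#' @export
spectra_set <- function(spectra, wavelengths, reference = NULL, ids = NULL) {
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  wavelengths <- as.numeric(wavelengths)
  n <- nrow(spectra)
  p <- ncol(spectra)
  if (length(wavelengths) != p)
    stop("wavelength axis has length ", length(wavelengths),
         " but spectra have ", p, " channels", call. = FALSE)
  if (p > 1 && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (!all(is.finite(spectra)))
    stop("spectra contain non-finite values", call. = FALSE)
  if (!is.null(reference)) {
    reference <- as.numeric(reference)
    if (length(reference) != n)
      stop("reference has length ", length(reference), " but there are ",
           n, " samples", call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("s", seq_len(max(n, 0)))
  ids <- as.character(ids)
  if (length(ids) != n)
    stop("ids has length ", length(ids), " but there are ", n, " samples",
         call. = FALSE)
  structure(list(spectra = spectra, wavelengths = wavelengths,
                 reference = reference, ids = ids),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d samples x %d channels (%.6g-%.6g nm)\n",
              nrow(x$spectra), ncol(x$spectra),
              min(x$wavelengths), max(x$wavelengths)))
  if (!is.null(x$reference))
    cat(sprintf("  reference values: range %.4g to %.4g\n",
                min(x$reference), max(x$reference)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$spectra)

#' Subset a spectral data set by sample
#'
#' @param x a [spectra_set()].
#' @param i sample (row) index vector.
#' @param ... unused.
#' @return A `spectra_set` with the selected samples.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$spectra[i, , drop = FALSE], x$wavelengths,
              reference = if (!is.null(x$reference)) x$reference[i],
              ids = x$ids[i])
}

#' Read a spectral data set from CSV
#'
#' The expected layout is one header row and one row per sample: the first
#' column holds sample ids, the remaining column names are wavelengths in nm
#' (dot decimal separator), and an optional final column named `reference`
#' holds the reference property values. This is the format written by
#' [write_spectra_csv()].
#'
#' @param path path to a CSV file.
#' @param reference_file optional path to a side CSV holding the reference
#'   values (one numeric column, header row), for datasets that ship
#'   property values separately from the spectra. Ignored when the spectra
#'   file has its own `reference` column.
#' @return A [spectra_set()].
#' @export
read_spectra_csv <- function(path, reference_file = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) < 2)
    stop("CSV must have a header row and at least one sample row: ", path,
         call. = FALSE)
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop("ragged CSV: row ", bad[1L], " has ", nf[bad[1L]],
         " fields, expected ", nf[1L], call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (ncol(raw) < 2)
    stop("CSV must have an id column and at least one wavelength column",
         call. = FALSE)
  header <- names(raw)
  has_ref <- identical(tolower(header[length(header)]), "reference")
  wl_cols <- seq(2L, ncol(raw) - if (has_ref) 1L else 0L)
  wavelengths <- suppressWarnings(as.numeric(header[wl_cols]))
  if (anyNA(wavelengths))
    stop("non-numeric wavelength in header: ",
         header[wl_cols][which(is.na(wavelengths))[1L]], call. = FALSE)
  num <- function(cells, colnames) {
    m <- suppressWarnings(vapply(cells, as.numeric, numeric(nrow(raw))))
    m <- matrix(m, nrow = nrow(raw))
    if (anyNA(m)) {
      idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop("non-numeric value at row ", idx[1L], ", column '",
           colnames[idx[2L]], "'", call. = FALSE)
    }
    m
  }
  spectra <- num(raw[wl_cols], header[wl_cols])
  reference <- if (has_ref)
    drop(num(raw[length(header)], "reference")) else NULL
  if (is.null(reference) && !is.null(reference_file)) {
    ref_raw <- utils::read.csv(reference_file, fileEncoding = "UTF-8")
    reference <- as.numeric(ref_raw[[1L]])
    if (anyNA(reference))
      stop("non-numeric reference value in ", reference_file,
           call. = FALSE)
  }
  spectra_set(spectra, wavelengths, reference = reference, ids = raw[[1L]])
}

#' Write a spectral data set to CSV
#'
#' Inverse of [read_spectra_csv()]; values survive a round trip to within
#' 1e-12 (17 significant digits are written). The `reference` column is
#' only emitted when reference values are present.
#'
#' @param s a [spectra_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  header <- c("id", fmt(s$wavelengths))
  rows <- cbind(s$ids, matrix(fmt(s$spectra), nrow = nrow(s$spectra)))
  if (!is.null(s$reference)) {
    header <- c(header, "reference")
    rows <- cbind(rows, fmt(s$reference))
  }
  lines <- c(paste(header, collapse = ","),
             apply(rows, 1L, paste, collapse = ","))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot open for writing: ",
                                           path, call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
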