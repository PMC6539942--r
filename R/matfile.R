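# Minimal MATLAB level-5 MAT-file reader (numeric arrays only).
#
# No CRAN dependency covers this format in the package's dependency set, so
# the subset needed for spectral benchmarks is implemented here: plain and
# zlib-compressed data elements holding real 2-D numeric matrices. MATLAB
# objects, cells, structs, sparse and complex arrays are rejected with a
# clear message rather than guessed at.

.mat_mi_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 2, `5` = 4, `6` = 4,
                  `7` = 4, `9` = 8, `12` = 8, `13` = 8)

.mat_read_numeric <- function(raw, type, n, endian) {
  what <- switch(as.character(type),
    "1" = "integer", "2" = "integer", "3" = "integer", "4" = "integer",
    "5" = "integer", "6" = "integer", "7" = "double", "9" = "double",
    stop("unsupported MAT numeric type mi", type, call. = FALSE))
  size <- .mat_mi_size[[as.character(type)]]
  signed <- type %in% c(1, 3, 5)
  if (type %in% c(12, 13))
    stop("64-bit integer MAT data not supported", call. = FALSE)
  if (type == 7) # single precision
    return(readBin(raw, "double", n = n, size = 4, endian = endian))
  readBin(raw, what, n = n, size = size, signed = signed || size >= 4,
          endian = endian)
}

# Parse one miMATRIX payload into list(name=, value=) or NULL if skipped.
.mat_parse_matrix <- function(payload, endian) {
  pos <- 0L
  next_el <- function() {
    tag <- readBin(payload[pos + 1:8], "integer", n = 2, size = 4,
                   endian = endian)
    type <- tag[1L]
    small <- bitwAnd(type, -65536L) != 0L # small data element format
    if (small) {
      nbytes <- bitwShiftR(bitwAnd(type, -65536L), 16)
      type <- bitwAnd(type, 65535L)
      data <- payload[pos + 4 + seq_len(nbytes)]
      pos <<- pos + 8L
    } else {
      nbytes <- tag[2L]
      data <- payload[pos + 8 + seq_len(nbytes)]
      pos <<- pos + 8L + as.integer(ceiling(nbytes / 8) * 8)
    }
    list(type = type, data = data, nbytes = nbytes)
  }
  flags <- next_el()
  af <- readBin(flags$data, "integer", n = 2, size = 4, endian = endian)
  class_id <- bitwAnd(af[1L], 255L)
  dims_el <- next_el()
  dims <- readBin(dims_el$data, "integer", n = dims_el$nbytes / 4, size = 4,
                  endian = endian)
  name_el <- next_el()
  name <- rawToChar(name_el$data[seq_len(name_el$nbytes)])
  if (!class_id %in% 6:15 || class_id == 5) # numeric classes only, not sparse
    return(list(name = name, value = NULL))
  if (length(dims) != 2)
    return(list(name = name, value = NULL))
  data_el <- next_el()
  vals <- .mat_read_numeric(data_el$data, data_el$type, prod(dims), endian)
  list(name = name, value = matrix(as.double(vals), dims[1L], dims[2L]))
}

# Read all top-level numeric matrices from a MAT v5 file.
.mat_read_all <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 128)
    stop("not a MAT v5 file (too short): ", path, call. = FALSE)
  endian_mark <- rawToChar(raw[127:128])
  endian <- if (endian_mark == "IM") "little" else if (endian_mark == "MI")
    "big" else stop("not a MAT v5 file (bad endian marker): ", path,
                    call. = FALSE)
  pos <- 128L
  out <- list()
  while (pos + 8 <= length(raw)) {
    tag <- readBin(raw[pos + 1:8], "integer", n = 2, size = 4,
                   endian = endian)
    type <- tag[1L]; nbytes <- tag[2L]
    payload <- raw[pos + 8 + seq_len(nbytes)]
    compressed <- type == 15
    if (compressed) { # miCOMPRESSED: zlib stream wrapping an miMATRIX
      payload <- memDecompress(payload, type = "gzip")
      itag <- readBin(payload[1:8], "integer", n = 2, size = 4,
                      endian = endian)
      type <- itag[1L]
      payload <- payload[8 + seq_len(itag[2L])]
    }
    if (type == 14) { # miMATRIX
      el <- .mat_parse_matrix(payload, endian)
      if (!is.null(el$value)) out[[el$name]] <- el$value
    }
    # compressed elements are stored unpadded; others align to 8 bytes
    pos <- pos + 8L + if (compressed) nbytes else
      as.integer(ceiling(nbytes / 8) * 8)
  }
  out
}

#' Read a spectral data set from a MATLAB v5 MAT-file
#'
#' Loads a numeric spectral matrix (and optionally a reference vector) from a
#' MAT-file container, the native distribution format of several public NIR
#' benchmarks. Only plain real numeric arrays are read; MATLAB objects,
#' structs and cells are skipped. Because such containers usually store only
#' the matrix, the wavelength axis is synthesized as the arithmetic sequence
#' `wl_start + wl_step * (0:(p-1))`.
#'
#' @param path path to a `.mat` file (level 5 format, plain or
#'   zlib-compressed elements).
#' @param spectra_key variable name of the n x p spectral matrix.
#' @param reference_key optional variable name of the reference vector
#'   (length n, stored as a column or row).
#' @param wl_start,wl_step first wavelength and channel spacing in nm used
#'   to synthesize the wavelength axis.
#' @return A [spectra_set()].
#' @export
read_mat_container <- function(path, spectra_key, reference_key = NULL,
                               wl_start = 1100, wl_step = 2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vars <- .mat_read_all(path)
  if (!spectra_key %in% names(vars))
    stop("variable '", spectra_key, "' not found; available: ",
         paste(names(vars), collapse = ", "), call. = FALSE)
  X <- vars[[spectra_key]]
  reference <- NULL
  if (!is.null(reference_key)) {
    if (!reference_key %in% names(vars))
      stop("variable '", reference_key, "' not found; available: ",
           paste(names(vars), collapse = ", "), call. = FALSE)
    reference <- drop(vars[[reference_key]])
  }
  p <- ncol(X)
  spectra_set(X, wl_start + wl_step * (seq_len(p) - 1), reference = reference)
}
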