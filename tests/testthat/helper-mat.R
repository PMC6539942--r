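# Independent MATLAB v5 MAT-file writer for building test fixtures, coded
# from the format description (128-byte header; tagged data elements;
# miMATRIX with array-flags, dimensions, name and real-part subelements).
# Deliberately separate from the package's reader.
write_mat_fixture <- function(path, vars, compress = FALSE) {
  pad8 <- function(r) {
    if (length(r) %% 8) c(r, raw(8 - length(r) %% 8)) else r
  }
  el <- function(type, data_raw) {
    pad8(c(writeBin(c(as.integer(type), length(data_raw)), raw(),
                    size = 4, endian = "little"),
           data_raw))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("MATLAB 5.0 MAT-file, test fixture"))
  hdr <- c(hdr, raw(116 - length(hdr)))
  writeBin(hdr, con)
  writeBin(raw(8), con)                                  # subsys offset
  writeBin(as.integer(c(256L)), con, size = 2, endian = "little") # 0x0100
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) {
    M <- as.matrix(vars[[nm]])
    flags <- writeBin(c(6L, 0L), raw(), size = 4, endian = "little")
    dims <- writeBin(as.integer(dim(M)), raw(), size = 4,
                     endian = "little")
    name <- charToRaw(nm)
    data <- writeBin(as.vector(M), raw(), size = 8, endian = "little")
    body <- c(el(6, flags), el(5, dims), el(1, name), el(9, data))
    element <- c(writeBin(c(14L, length(body)), raw(), size = 4,
                          endian = "little"), body)
    if (compress) {
      z <- memCompress(element, type = "gzip")
      element <- c(writeBin(c(15L, length(z)), raw(), size = 4,
                            endian = "little"), z)
    }
    writeBin(element, con)
  }
  invisible(path)
}
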