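# Minimal reader for NumPy .npy files (format versions 1.0/2.0), sufficient
# for the numeric arrays a phy/Kilosort output directory contains. Supports
# little-endian integer/float dtypes and C or Fortran memory order.

#' Read a NumPy `.npy` array
#'
#' @param path path to a `.npy` file.
#' @return A numeric vector, matrix, or array matching the stored shape.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6)
  if (length(magic) < 6 ||
      !identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stop_mea("CorruptInput", "%s is not an NPY file", path)
  }
  ver <- readBin(con, "integer", n = 2, size = 1, signed = FALSE)
  header_len <- if (ver[1] >= 2) {
    readBin(con, "integer", n = 1, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n = 1, size = 2, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", n = header_len))

  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  n <- if (length(shape) == 0) 1L else prod(shape)

  type <- substr(descr, 2, 2)
  size <- as.integer(substr(descr, 3, 3))
  endian <- if (substr(descr, 1, 1) == ">") "big" else "little"
  vals <- switch(type,
    "f" = readBin(con, "numeric", n = n, size = size, endian = endian),
    "i" = if (size == 8) {
      readBin(con, "numeric", n = n, size = 8, endian = endian) # see below
    } else {
      readBin(con, "integer", n = n, size = size, endian = endian)
    },
    "u" = readBin(con, "integer", n = n, size = size, signed = FALSE,
                  endian = endian),
    stop_mea("CorruptInput", "unsupported NPY dtype '%s' in %s", descr, path)
  )
  # int64 has no native R type; reinterpret the doubles read above.
  if (type == "i" && size == 8) {
    seek(con, 6 + 2 + (if (ver[1] >= 2) 4 else 2) + header_len)
    raw_data <- readBin(con, "raw", n = n * 8)
    vals <- int64_to_double(raw_data, endian)
  }
  if (length(vals) != n) {
    stop_mea("CorruptInput", "truncated NPY payload in %s", path)
  }
  if (length(shape) <= 1) return(vals)
  if (fortran) array(vals, dim = shape) else aperm(array(vals, dim = rev(shape)))
}

# Convert little/big-endian int64 raw bytes to double (exact below 2^53).
int64_to_double <- function(raw_data, endian) {
  m <- matrix(as.numeric(raw_data), nrow = 8)
  if (endian == "big") m <- m[8:1, , drop = FALSE]
  lo <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536 + m[4, ] * 16777216
  hi <- m[5, ] + m[6, ] * 256 + m[7, ] * 65536 + m[8, ] * 16777216
  neg <- m[8, ] >= 128
  v <- lo + hi * 4294967296
  v[neg] <- v[neg] - 18446744073709551616
  v
}
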