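# Minimal NPY (NumPy binary array) I/O, enough for Kilosort/Phy outputs:
# 1-D little-endian integer / float arrays, format versions 1.0 and 2.0.
# Values outside 2^53 are not representable in R doubles and are rejected.

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY"))))) {
    abort(paste0(path, ": not an NPY file"), class = "wb_schema_error")
  }
  ver <- readBin(con, "integer", n = 2L, size = 1L, signed = FALSE)
  hlen <- if (ver[1] == 1L) {
    readBin(con, "integer", n = 1L, size = 2L, signed = FALSE, endian = "little")
  } else {
    readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", n = hlen))
  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shape_str <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.numeric(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  n <- if (length(shape)) prod(shape) else 1
  if (length(shape) > 1L && fortran) {
    abort("fortran-ordered multi-dimensional NPY not supported",
          class = "wb_schema_error")
  }
  type <- substr(descr, 2, 2)
  size <- as.integer(substr(descr, 3, 3))
  out <- switch(
    type,
    "f" = readBin(con, "double", n = n, size = size, endian = "little"),
    "i" = if (size <= 4L) {
      readBin(con, "integer", n = n, size = size, endian = "little")
    } else {
      read_le_int64(con, n, signed = TRUE)
    },
    "u" = if (size <= 2L) {
      readBin(con, "integer", n = n, size = size, signed = FALSE, endian = "little")
    } else if (size == 4L) {
      lo <- readBin(con, "integer", n = n, size = 4L, endian = "little")
      ifelse(lo < 0, lo + 2^32, lo)
    } else {
      read_le_int64(con, n, signed = FALSE)
    },
    abort(paste0("unsupported NPY dtype: ", descr), class = "wb_schema_error"))
  if (length(out) != n) abort(paste0(path, ": truncated NPY data"),
                              class = "wb_schema_error")
  out
}

read_le_int64 <- function(con, n, signed) {
  words <- readBin(con, "integer", n = 2L * n, size = 4L, endian = "little")
  lo <- words[seq(1L, by = 2L, length.out = n)]
  hi <- words[seq(2L, by = 2L, length.out = n)]
  lo <- ifelse(lo < 0, lo + 2^32, lo)
  hi_u <- ifelse(hi < 0, hi + 2^32, hi)
  val <- if (signed) {
    hi_s <- ifelse(hi_u >= 2^31, hi_u - 2^32, hi_u)
    hi_s * 2^32 + lo
  } else {
    hi_u * 2^32 + lo
  }
  if (any(abs(val) > 2^53)) abort("int64 value exceeds double precision",
                                  class = "wb_schema_error")
  val
}

write_npy <- function(x, path) {
  if (is.integer(x)) {
    descr <- "<i4"
    writer <- function(con) writeBin(x, con, size = 4L, endian = "little")
  } else {
    descr <- "<f8"
    writer <- function(con) writeBin(as.numeric(x), con, size = 8L, endian = "little")
  }
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%d,), }",
                    descr, length(x))
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  writer(con)
  invisible(path)
}
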