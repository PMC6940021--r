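# Component payload codecs and quantity-type interpretation.
#
# Components travel in one of three physical forms: JSON number arrays
# (encoding "none"), base64 strings of little-endian binary (encoding
# "base64"), or raw little-endian binary in an external file. All three
# decode to the same in-memory numeral vector (double, or complex for the
# complex numeric types).

.numeric_types <- list(
  uint8      = list(bytes = 1L,  complex = FALSE, integer = TRUE,  signed = FALSE),
  uint16     = list(bytes = 2L,  complex = FALSE, integer = TRUE,  signed = FALSE),
  uint32     = list(bytes = 4L,  complex = FALSE, integer = TRUE,  signed = FALSE),
  uint64     = list(bytes = 8L,  complex = FALSE, integer = TRUE,  signed = FALSE),
  int8       = list(bytes = 1L,  complex = FALSE, integer = TRUE,  signed = TRUE),
  int16      = list(bytes = 2L,  complex = FALSE, integer = TRUE,  signed = TRUE),
  int32      = list(bytes = 4L,  complex = FALSE, integer = TRUE,  signed = TRUE),
  int64      = list(bytes = 8L,  complex = FALSE, integer = TRUE,  signed = TRUE),
  float32    = list(bytes = 4L,  complex = FALSE, integer = FALSE, signed = TRUE),
  float64    = list(bytes = 8L,  complex = FALSE, integer = FALSE, signed = TRUE),
  complex64  = list(bytes = 8L,  complex = TRUE,  integer = FALSE, signed = TRUE),
  complex128 = list(bytes = 16L, complex = TRUE,  integer = FALSE, signed = TRUE)
)

#' Describe a numeric-type literal
#'
#' @param name One of the twelve numeric-type literals (`uint8` ...
#'   `complex128`).
#' @return A list with `name`, `bytes_per_numeral` (bytes per stored data
#'   value; a complex value counts both parts), `is_complex`, `is_integer`,
#'   and `signed`.
#' @export
numeric_type_info <- function(name) {
  nt <- .numeric_types[[name]]
  if (is.null(nt))
    stop("unknown numeric_type: '", name, "'", call. = FALSE)
  list(name = name, bytes_per_numeral = nt$bytes, is_complex = nt$complex,
       is_integer = nt$integer, signed = nt$signed)
}

#' Parse a quantity-type literal
#'
#' The quantity type fixes the number of components `p` and how the p
#' values at each grid sample combine: `scalar` (p = 1), `vector_n`
#' (p = n), `matrix_m_n` (p = m*n, column-major), `symmetric_matrix_n`
#' (p = n(n+1)/2, upper triangle), or `pixel_n` (p = n).
#'
#' @param text Quantity-type string, e.g. `"symmetric_matrix_3"`.
#' @return A `csd_quantity_type` list with `family`, `m`, `n`, and `p`.
#' @examples
#' parse_quantity_type("pixel_3")$p
#' @export
parse_quantity_type <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- NULL
  if (text == "scalar") {
    out <- list(family = "scalar", m = NA_integer_, n = NA_integer_, p = 1L)
  } else if (grepl("^vector_[0-9]+$", text)) {
    n <- as.integer(sub("^vector_", "", text))
    out <- list(family = "vector", m = NA_integer_, n = n, p = n)
  } else if (grepl("^matrix_[0-9]+_[0-9]+$", text)) {
    mn <- as.integer(strsplit(sub("^matrix_", "", text), "_")[[1]])
    out <- list(family = "matrix", m = mn[1], n = mn[2],
                p = mn[1] * mn[2])
  } else if (grepl("^symmetric_matrix_[0-9]+$", text)) {
    n <- as.integer(sub("^symmetric_matrix_", "", text))
    out <- list(family = "symmetric_matrix", m = n, n = n,
                p = as.integer(n * (n + 1) / 2))
  } else if (grepl("^pixel_[0-9]+$", text)) {
    n <- as.integer(sub("^pixel_", "", text))
    out <- list(family = "pixel", m = NA_integer_, n = n, p = n)
  } else {
    stop("unknown quantity_type: '", text, "'", call. = FALSE)
  }
  if (!is.na(out$n) && out$n < 1L)
    stop("quantity_type parameter must be a positive integer: '", text, "'",
         call. = FALSE)
  out$literal <- text
  class(out) <- "csd_quantity_type"
  out
}

# ---- base64 (RFC alphabet, padded, no line breaks) -------------------------

.b64_chars <- "^[A-Za-z0-9+/]*={0,2}$"

#' Base64-encode raw bytes
#'
#' Standard alphabet, mandatory padding, no line breaks.
#' @param bytes A raw vector.
#' @return A single character string.
#' @export
base64_encode <- function(bytes) {
  stopifnot(is.raw(bytes))
  gsub("\n", "", jsonlite::base64_enc(bytes), fixed = TRUE)
}

#' Base64-decode a string to raw bytes
#'
#' @param text Base64 string. In strict mode any whitespace inside the
#'   payload is an error; in lenient mode it is stripped.
#' @param strict Reject embedded whitespace?
#' @return A raw vector.
#' @export
base64_decode <- function(text, strict = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("[ \t\r\n]", text)) {
    if (strict)
      stop("whitespace inside base64 payload", call. = FALSE)
    text <- gsub("[ \t\r\n]", "", text)
  }
  if (!grepl(.b64_chars, text) || nchar(text) %% 4L != 0L)
    stop("invalid base64 payload (alphabet or padding)", call. = FALSE)
  jsonlite::base64_dec(text)
}

# ---- little-endian binary <-> numerals -------------------------------------

.bytes_to_numerals <- function(bytes, numeric_type) {
  nt <- numeric_type_info(numeric_type)
  if (length(bytes) %% nt$bytes_per_numeral != 0L)
    stop("byte length ", length(bytes), " is not a multiple of ",
         nt$bytes_per_numeral, " (", numeric_type, ")", call. = FALSE)
  n <- length(bytes) %/% nt$bytes_per_numeral
  if (n == 0L)
    return(if (nt$is_complex) complex(0) else numeric(0))
  switch(numeric_type,
    uint8  = as.numeric(readBin(bytes, "integer", n, size = 1, signed = FALSE)),
    int8   = as.numeric(readBin(bytes, "integer", n, size = 1, signed = TRUE)),
    uint16 = as.numeric(readBin(bytes, "integer", n, size = 2, signed = FALSE,
                                endian = "little")),
    int16  = as.numeric(readBin(bytes, "integer", n, size = 2, signed = TRUE,
                                endian = "little")),
    uint32 = {
      x <- as.numeric(readBin(bytes, "integer", n, size = 4,
                              endian = "little"))
      ifelse(x < 0, x + 4294967296, x)
    },
    int32  = as.numeric(readBin(bytes, "integer", n, size = 4,
                                endian = "little")),
    uint64 = , int64 = {
      # compose two 32-bit little-endian words; exact below 2^53
      w <- readBin(bytes, "integer", 2L * n, size = 4, endian = "little")
      lo <- as.numeric(w[seq(1L, 2L * n, 2L)])
      hi <- as.numeric(w[seq(2L, 2L * n, 2L)])
      lo <- ifelse(lo < 0, lo + 4294967296, lo)
      if (numeric_type == "uint64")
        hi <- ifelse(hi < 0, hi + 4294967296, hi)
      hi * 4294967296 + lo
    },
    float32 = as.numeric(readBin(bytes, "double", n, size = 4,
                                 endian = "little")),
    float64 = readBin(bytes, "double", n, size = 8, endian = "little"),
    complex64 = {
      f <- readBin(bytes, "double", 2L * n, size = 4, endian = "little")
      complex(real = f[seq(1L, 2L * n, 2L)],
              imaginary = f[seq(2L, 2L * n, 2L)])
    },
    complex128 = {
      f <- readBin(bytes, "double", 2L * n, size = 8, endian = "little")
      complex(real = f[seq(1L, 2L * n, 2L)],
              imaginary = f[seq(2L, 2L * n, 2L)])
    })
}

.check_integer_range <- function(x, numeric_type) {
  nt <- numeric_type_info(numeric_type)
  if (!nt$is_integer) return(invisible(NULL))
  if (any(x != floor(x)))
    stop("non-integer value for numeric_type ", numeric_type, call. = FALSE)
  bits <- nt$bytes_per_numeral * 8L
  lo <- if (nt$signed) -2^(bits - 1) else 0
  hi <- if (nt$signed) 2^(bits - 1) - 1 else 2^bits - 1
  if (any(x < lo | x > hi))
    stop("value out of range for numeric_type ", numeric_type, call. = FALSE)
  invisible(NULL)
}

.numerals_to_bytes <- function(values, numeric_type) {
  nt <- numeric_type_info(numeric_type)
  if (nt$is_complex) {
    values <- as.complex(values)
    inter <- as.numeric(rbind(Re(values), Im(values)))
    sz <- nt$bytes_per_numeral %/% 2L
    return(writeBin(inter, raw(), size = sz, endian = "little"))
  }
  values <- as.numeric(values)
  if (nt$is_integer) {
    .check_integer_range(values, numeric_type)
    if (nt$bytes_per_numeral == 8L) {
      hi <- floor(values / 4294967296)
      lo <- values - hi * 4294967296
      # writeBin wants signed 32-bit words
      lo <- ifelse(lo >= 2147483648, lo - 4294967296, lo)
      hi <- ifelse(hi >= 2147483648, hi - 4294967296, hi)
      w <- as.integer(as.vector(rbind(lo, hi)))
      return(writeBin(w, raw(), size = 4, endian = "little"))
    }
    v <- values
    if (!nt$signed) {
      bits <- nt$bytes_per_numeral * 8L
      v <- ifelse(v >= 2^(bits - 1), v - 2^bits, v)  # two's complement
    }
    return(writeBin(as.integer(v), raw(), size = nt$bytes_per_numeral,
                    endian = "little"))
  }
  writeBin(values, raw(), size = nt$bytes_per_numeral, endian = "little")
}

# ---- decode / encode -------------------------------------------------------

.new_component <- function(values, numeric_type) {
  structure(list(values = values, numeric_type = numeric_type,
                 samples = length(values)),
            class = "csd_component")
}

#' Decode a serialized component payload
#'
#' @param payload Either a numeric vector (or list of JSON numbers) for
#'   encoding `"none"`, or a base64 string for encoding `"base64"`, or a raw
#'   vector of little-endian binary (external files).
#' @param numeric_type Numeric-type literal.
#' @param encoding `"none"`, `"base64"`, or `"raw"`.
#' @param strict Passed to [base64_decode()].
#' @return A `csd_component`: `values` (double or complex vector),
#'   `numeric_type`, and `samples`. For complex types the flat serialized
#'   array holds `2 * samples` numerals, interleaved real/imaginary starting
#'   with the real part.
#' @export
decode_component <- function(payload, numeric_type, encoding = "none",
                             strict = TRUE) {
  nt <- numeric_type_info(numeric_type)
  if (encoding == "base64") {
    bytes <- base64_decode(payload, strict = strict)
    return(.new_component(.bytes_to_numerals(bytes, numeric_type),
                          numeric_type))
  }
  if (encoding == "raw") {
    stopifnot(is.raw(payload))
    return(.new_component(.bytes_to_numerals(payload, numeric_type),
                          numeric_type))
  }
  if (encoding != "none")
    stop("unknown encoding: '", encoding, "'", call. = FALSE)
  if (is.list(payload)) {
    ok <- vapply(payload, function(v) is.numeric(v) && length(v) == 1L,
                 logical(1))
    if (!all(ok))
      stop("non-numeric JSON entry in component array", call. = FALSE)
    payload <- as.numeric(unlist(payload, use.names = FALSE))
    if (length(ok) == 0L) payload <- numeric(0)
  }
  if (!is.numeric(payload))
    stop("component payload must be numeric for encoding 'none'",
         call. = FALSE)
  if (nt$is_complex) {
    if (length(payload) %% 2L != 0L)
      stop("complex component array must have even length (2M interleaved ",
           "numerals)", call. = FALSE)
    np <- length(payload)
    vals <- if (np == 0L) complex(0)
    else complex(real = payload[seq(1L, np, 2L)],
                 imaginary = payload[seq(2L, np, 2L)])
    # snap to storage precision on import
    vals <- .bytes_to_numerals(.numerals_to_bytes(vals, numeric_type),
                               numeric_type)
    return(.new_component(vals, numeric_type))
  }
  .check_integer_range(payload, numeric_type)
  vals <- .bytes_to_numerals(.numerals_to_bytes(payload, numeric_type),
                             numeric_type)
  .new_component(vals, numeric_type)
}

#' Encode a component for serialization
#'
#' Inverse of [decode_component()]: `decode(encode(x))` reproduces the
#' numerals bit-exactly.
#'
#' @param component A `csd_component`, or a bare numeric/complex vector
#'   (then `numeric_type` must be given).
#' @param encoding `"none"` (JSON numbers), `"base64"`, or `"raw"` (bytes).
#' @param numeric_type Numeric-type literal when `component` is a bare
#'   vector.
#' @return For `"none"` a numeric vector of interleaved numerals; for
#'   `"base64"` a character string; for `"raw"` a raw vector.
#' @export
encode_component <- function(component, encoding = "none",
                             numeric_type = NULL) {
  if (!inherits(component, "csd_component")) {
    stopifnot(!is.null(numeric_type))
    component <- .new_component(component, numeric_type)
  }
  nt <- numeric_type_info(component$numeric_type)
  if (encoding == "base64")
    return(base64_encode(.numerals_to_bytes(component$values,
                                            component$numeric_type)))
  if (encoding == "raw")
    return(.numerals_to_bytes(component$values, component$numeric_type))
  if (encoding != "none")
    stop("unknown encoding: '", encoding, "'", call. = FALSE)
  if (nt$is_complex) {
    v <- as.complex(component$values)
    as.numeric(rbind(Re(v), Im(v)))
  } else {
    as.numeric(component$values)
  }
}

# 0-based flat index into the packed upper triangle of an n x n symmetric
# matrix for entry (r, c), 0-based, row-by-row along the upper triangle:
# (r, c) with r <= c maps to r*n - r(r-1)/2 + (c - r).
.sym_index <- function(r, c, n) {
  r0 <- pmin(r, c); c0 <- pmax(r, c)
  r0 * n - r0 * (r0 - 1) / 2 + (c0 - r0)
}

#' Assemble the typed data value at one grid sample
#'
#' Combines the i-th entry of each of the p components into the value the
#' quantity type describes: a scalar, a length-n vector or pixel, an m x n
#' matrix filled column-major (entry (r, c) comes from component `c*m + r`),
#' or an n x n symmetric matrix reconstructed from its packed upper
#' triangle.
#'
#' @param qtype A `csd_quantity_type` or quantity-type string.
#' @param components List of p numeric/complex vectors (or
#'   `csd_component`s), all the same length.
#' @param i Sample index, 1-based.
#' @return A scalar, vector, or matrix.
#' @export
assemble_value <- function(qtype, components, i) {
  if (!inherits(qtype, "csd_quantity_type"))
    qtype <- parse_quantity_type(qtype)
  vals <- lapply(components, function(u)
    if (inherits(u, "csd_component")) u$values else u)
  if (length(vals) != qtype$p)
    stop("expected ", qtype$p, " components, got ", length(vals),
         call. = FALSE)
  ns <- unique(vapply(vals, length, integer(1)))
  if (length(ns) > 1L)
    stop("components differ in sample count", call. = FALSE)
  if (i < 1L || i > ns)
    stop("sample index out of range", call. = FALSE)
  at <- vapply(vals, function(u) u[[i]],
               if (any(vapply(vals, is.complex, logical(1))))
                 complex(1) else numeric(1))
  switch(qtype$family,
    scalar = at[[1]],
    vector = , pixel = at,
    matrix = matrix(at, nrow = qtype$m, ncol = qtype$n),
    symmetric_matrix = {
      n <- qtype$n
      idx <- outer(0:(n - 1), 0:(n - 1),
                   function(r, c) .sym_index(r, c, n))
      matrix(at[idx + 1L], n, n)
    })
}
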