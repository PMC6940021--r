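# Physical units: symbol grammar, dimensional algebra, scalar quantities.
#
# A unit is represented by a positive scale factor to coherent SI and a
# vector of 7 integer exponents over the SI base dimensions
# (length, mass, time, current, temperature, amount, luminous intensity).
# Affine temperature units (degC, degF) additionally carry an offset and are
# barred from * / ^ composition.

.dim_names <- c("length", "mass", "time", "current", "temperature",
                "amount", "luminous_intensity")

.dims0 <- stats::setNames(rep(0, 7L), .dim_names)

.mkdims <- function(...) {
  d <- .dims0
  args <- list(...)
  d[names(args)] <- unlist(args)
  d
}

# symbol -> list(scale, dims, prefixable, offset, affine)
.unit_registry <- local({
  ent <- function(scale, dims, prefixable = TRUE, offset = 0, affine = FALSE)
    list(scale = scale, dims = dims, prefixable = prefixable,
         offset = offset, affine = affine)
  L <- .mkdims(length = 1); M <- .mkdims(mass = 1); T <- .mkdims(time = 1)
  reg <- list(
    # SI base (gram is the prefixable mass symbol; kg arrives as k + g)
    m   = ent(1, L),
    g   = ent(1e-3, M),
    s   = ent(1, T),
    A   = ent(1, .mkdims(current = 1)),
    K   = ent(1, .mkdims(temperature = 1)),
    mol = ent(1, .mkdims(amount = 1)),
    cd  = ent(1, .mkdims(luminous_intensity = 1)),
    # SI derived symbols with special names
    Hz  = ent(1, .mkdims(time = -1)),
    Bq  = ent(1, .mkdims(time = -1)),
    N   = ent(1, .mkdims(mass = 1, length = 1, time = -2)),
    Pa  = ent(1, .mkdims(mass = 1, length = -1, time = -2)),
    J   = ent(1, .mkdims(mass = 1, length = 2, time = -2)),
    W   = ent(1, .mkdims(mass = 1, length = 2, time = -3)),
    C   = ent(1, .mkdims(current = 1, time = 1)),
    V   = ent(1, .mkdims(mass = 1, length = 2, time = -3, current = -1)),
    F   = ent(1, .mkdims(mass = -1, length = -2, time = 4, current = 2)),
    S   = ent(1, .mkdims(mass = -1, length = -2, time = 3, current = 2)),
    T   = ent(1, .mkdims(mass = 1, time = -2, current = -1)),
    Wb  = ent(1, .mkdims(mass = 1, length = 2, time = -2, current = -1)),
    lm  = ent(1, .mkdims(luminous_intensity = 1)),
    lx  = ent(1, .mkdims(luminous_intensity = 1, length = -2)),
    L   = ent(1e-3, .mkdims(length = 3)),
    # accepted non-SI
    bar = ent(1e5, .mkdims(mass = 1, length = -1, time = -2)),
    min = ent(60, T, prefixable = FALSE),
    h   = ent(3600, T, prefixable = FALSE),
    d   = ent(86400, T, prefixable = FALSE),
    yr  = ent(31557600, T, prefixable = FALSE),   # Julian year, 365.25 d
    # angle and ratio units: dimensionless with a retained display symbol
    rad = ent(1, .dims0, prefixable = FALSE),
    sr  = ent(1, .dims0, prefixable = FALSE),
    ppm = ent(1e-6, .dims0, prefixable = FALSE),
    # affine temperature units: parse, but flag and bar from composition
    degC = ent(1, .mkdims(temperature = 1), prefixable = FALSE,
               offset = 273.15, affine = TRUE),
    degF = ent(5 / 9, .mkdims(temperature = 1), prefixable = FALSE,
               offset = 273.15 - 32 * 5 / 9, affine = TRUE)
  )
  reg[["°"]]  <- ent(pi / 180, .dims0, prefixable = FALSE)  # degree sign
  reg[["%"]]       <- ent(1e-2, .dims0, prefixable = FALSE)
  reg[["Ω"]]  <- ent(1, .mkdims(mass = 1, length = 2, time = -3,
                                     current = -2), prefixable = FALSE)
  reg[["Ohm"]] <- reg[["Ω"]]
  reg[["°C"]] <- reg[["degC"]]
  reg[["°F"]] <- reg[["degF"]]
  reg[["deg"]] <- reg[["°"]]
  reg
})

# prefixes, longest first so "da" wins over "d" + remainder
.si_prefixes <- c(
  da = 1e1,
  y = 1e-24, z = 1e-21, a = 1e-18, f = 1e-15, p = 1e-12, n = 1e-9,
  "µ" = 1e-6, "μ" = 1e-6, u = 1e-6,
  m = 1e-3, c = 1e-2, d = 1e-1, h = 1e2, k = 1e3,
  M = 1e6, G = 1e9, T = 1e12, P = 1e15, E = 1e18, Z = 1e21, Y = 1e24)

.new_unit <- function(symbol, scale, dims, offset = 0, affine = FALSE) {
  stopifnot(scale > 0)
  structure(list(symbol = symbol, scale = scale,
                 dims = stats::setNames(as.numeric(dims), .dim_names),
                 offset = offset, affine = affine),
            class = "csd_unit")
}

.resolve_symbol <- function(tok) {
  hit <- .unit_registry[[tok]]
  if (!is.null(hit))
    return(.new_unit(tok, hit$scale, hit$dims, hit$offset, hit$affine))
  for (pf in names(.si_prefixes)) {
    if (startsWith(tok, pf) && nchar(tok) > nchar(pf)) {
      rest <- substring(tok, nchar(pf) + 1L)
      base <- .unit_registry[[rest]]
      if (!is.null(base) && isTRUE(base$prefixable))
        return(.new_unit(tok, unname(.si_prefixes[[pf]]) * base$scale,
                         base$dims))
    }
  }
  stop("unknown unit symbol: '", tok, "'", call. = FALSE)
}

.unit_tokenize <- function(text) {
  # letters plus the degree/micro/ohm/percent glyphs form symbol tokens
  sym_chars <- "[A-Za-z°µμΩ%]"
  toks <- list(); i <- 1L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("*", "/", "^", "(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch)
      i <- i + 1L
    } else if (grepl(sym_chars, ch)) {
      j <- i
      while (j <= n && grepl(sym_chars, chars[j])) j <- j + 1L
      toks[[length(toks) + 1L]] <-
        list(type = "sym", text = paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
    } else if (grepl("[0-9.+-]", ch)) {
      j <- i
      while (j <= n && grepl("[0-9.eE+-]", chars[j])) j <- j + 1L
      toks[[length(toks) + 1L]] <-
        list(type = "num", text = paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
    } else {
      stop("unexpected character '", ch, "' in unit expression", call. = FALSE)
    }
  }
  toks
}

.unit_mul <- function(a, b, op = "*") {
  if (a$affine || b$affine)
    stop("affine temperature units (°C/°F) cannot be composed ",
         "with other units", call. = FALSE)
  if (op == "*")
    .new_unit(paste0(a$symbol, "*", b$symbol), a$scale * b$scale,
              a$dims + b$dims)
  else
    .new_unit(paste0(a$symbol, "/", b$symbol), a$scale / b$scale,
              a$dims - b$dims)
}

.unit_pow <- function(u, k) {
  if (u$affine)
    stop("affine temperature units cannot be raised to a power",
         call. = FALSE)
  .new_unit(paste0(u$symbol, "^", k), u$scale^k, u$dims * k)
}

.parse_cache <- new.env(parent = emptyenv())

#' Parse a unit-symbol string
#'
#' Parses the unit grammar used by scalar quantities: case-sensitive
#' registered symbols with optional SI prefixes, composed with `*`, `/`, and
#' integer powers via `^`; parentheses set precedence. Implicit
#' multiplication (`"N m"`, `"kWh"`) is rejected. The empty string is the
#' dimensionless unit.
#'
#' @param text A unit symbol string, e.g. `"kg*m^2/s^2"` or `"J/(mol*K)"`.
#' @return A `csd_unit`: display symbol, positive scale factor to coherent
#'   SI, and a named vector of 7 integer dimension exponents.
#' @examples
#' parse_unit("m/s")$dims
#' parse_unit("J/(mol*K)")$scale
#' @export
parse_unit <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  key <- paste0("u:", text)
  hit <- .parse_cache[[key]]
  if (!is.null(hit)) return(hit)
  text <- trimws(text)
  if (nchar(text) == 0L) {
    u <- .new_unit("", 1, .dims0)
    .parse_cache[[key]] <- u
    return(u)
  }
  toks <- .unit_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }

  parse_factor <- function() {
    t <- peek()
    if (is.null(t)) stop("unexpected end of unit expression", call. = FALSE)
    if (t$type == "(") {
      take()
      u <- parse_expr()
      cl <- peek()
      if (is.null(cl) || cl$type != ")")
        stop("missing closing parenthesis", call. = FALSE)
      take()
      u$symbol <- paste0("(", u$symbol, ")")
      return(u)
    }
    if (t$type == "sym") { take(); return(.resolve_symbol(t$text)) }
    if (t$type == "num") {
      take()
      v <- suppressWarnings(as.numeric(t$text))
      if (is.na(v) || v <= 0)
        stop("invalid numeric factor '", t$text, "' in unit", call. = FALSE)
      return(.new_unit(t$text, v, .dims0))
    }
    stop("unexpected token '", t$text, "' in unit expression", call. = FALSE)
  }

  parse_power <- function() {
    u <- parse_factor()
    t <- peek()
    if (!is.null(t) && t$type == "^") {
      take()
      e <- peek()
      if (is.null(e) || e$type != "num" ||
          !grepl("^[+-]?[0-9]+$", e$text))
        stop("exponent after '^' must be a signed integer", call. = FALSE)
      take()
      u <- .unit_pow(u, as.integer(e$text))
    }
    u
  }

  parse_expr <- function() {
    u <- parse_power()
    repeat {
      t <- peek()
      if (is.null(t) || !(t$type %in% c("*", "/"))) break
      take()
      u <- .unit_mul(u, parse_power(), op = t$type)
    }
    u
  }

  u <- parse_expr()
  if (pos <= length(toks))
    stop("unexpected token '", toks[[pos]]$text,
         "' in unit expression (missing '*' or '/'?)", call. = FALSE)
  u$symbol <- text
  .parse_cache[[key]] <- u
  u
}

.as_unit <- function(x) {
  if (inherits(x, "csd_unit")) x else parse_unit(x)
}

#' Do two units share a dimensionality?
#'
#' True when the 7-exponent dimension vectors are equal componentwise; e.g.
#' `"Hz"`, `"Bq"`, and `"1/s"` all have dimensionality of inverse time.
#'
#' @param a,b Units (`csd_unit`) or unit strings.
#' @return Logical scalar.
#' @export
same_dimensionality <- function(a, b) {
  identical(unname(.as_unit(a)$dims), unname(.as_unit(b)$dims))
}

#' Scalar quantities
#'
#' A scalar quantity binds a real numerical value (64-bit float) to a unit.
#' Its serialized form is the number, one space, then the unit symbol,
#' e.g. `"3.4 m"` or `"2.3 bar"`.
#'
#' @param value Numeric scalar (may be `Inf` for the infinite-period
#'   sentinel).
#' @param unit A `csd_unit` or unit string.
#' @return A `csd_quantity`.
#' @export
scalar_quantity <- function(value, unit = "") {
  stopifnot(is.numeric(value), length(value) == 1L)
  structure(list(value = as.numeric(value), unit = .as_unit(unit)),
            class = "csd_quantity")
}

#' Parse a scalar-quantity string
#'
#' @param text A string of the form `"<number> <unit>"`; the unit may be
#'   absent, in which case the quantity is dimensionless.
#' @return A `csd_quantity`.
#' @examples
#' parse_scalar_quantity("0.08333 yr")
#' parse_scalar_quantity("2.3 bar")
#' @export
parse_scalar_quantity <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  m <- regexpr("^[+-]?(Inf|∞|[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)", s)
  if (m == -1L)
    stop("malformed number in scalar quantity: '", text, "'", call. = FALSE)
  numtxt <- regmatches(s, m)
  rest <- trimws(substring(s, attr(m, "match.length") + 1L))
  v <- if (grepl("∞", numtxt)) {
    if (startsWith(numtxt, "-")) -Inf else Inf
  } else as.numeric(numtxt)
  if (is.na(v))
    stop("malformed number in scalar quantity: '", text, "'", call. = FALSE)
  scalar_quantity(v, parse_unit(rest))
}

# shortest decimal string that round-trips to x exactly
.fmt_shortest <- function(x) {
  if (is.infinite(x)) return(if (x > 0) "∞" else "-∞")
  if (is.nan(x)) return("NaN")
  if (x == floor(x) && abs(x) < 1e15) {
    # keep a trailing ".0" for float values so the JSON type stays float-ish
    return(sprintf("%.1f", x))
  }
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g")
    if (as.numeric(s) == x) return(s)
  }
  sprintf("%.17g", x)
}

#' Format a scalar quantity as its serialized string
#'
#' Produces the shortest decimal that round-trips the stored 64-bit value,
#' one space, then the unit symbol. Infinite values format with the infinity
#' glyph for display; they are never written to files (an absent `period`
#' key means an infinite period).
#'
#' @param q A `csd_quantity`.
#' @return Character scalar.
#' @export
format_scalar_quantity <- function(q) {
  stopifnot(inherits(q, "csd_quantity"))
  num <- .fmt_shortest(q$value)
  if (nchar(q$unit$symbol) == 0L) num else paste(num, q$unit$symbol)
}

#' Convert a scalar quantity to another unit
#'
#' @param q A `csd_quantity`.
#' @param target Target unit (`csd_unit` or string) with the same
#'   dimensionality. Affine temperature units convert with their kelvin
#'   offset.
#' @return A `csd_quantity` in the target unit.
#' @examples
#' convert_quantity(parse_scalar_quantity("80 µs"), "ms")
#' @export
convert_quantity <- function(q, target) {
  stopifnot(inherits(q, "csd_quantity"))
  to <- .as_unit(target)
  if (!same_dimensionality(q$unit, to))
    stop("cannot convert '", q$unit$symbol, "' to '", to$symbol,
         "': dimensionality mismatch (",
         paste(q$unit$dims, collapse = ","), ") vs (",
         paste(to$dims, collapse = ","), ")", call. = FALSE)
  if (q$unit$offset == 0 && to$offset == 0) {
    # single rounding step: multiply by the scale ratio
    return(scalar_quantity(q$value * (q$unit$scale / to$scale), to))
  }
  kelvinish <- q$value * q$unit$scale + q$unit$offset
  scalar_quantity((kelvinish - to$offset) / to$scale, to)
}

# numeric value of q expressed in `unit`, as a plain double
.q_value_in <- function(q, unit) convert_quantity(q, unit)$value

#' @export
print.csd_unit <- function(x, ...) {
  nz <- x$dims[x$dims != 0]
  dimtxt <- if (length(nz) == 0L) "dimensionless"
  else paste(names(nz), nz, sep = "^", collapse = " ")
  cat("<unit> '", x$symbol, "'  scale ", format(x$scale), "  [", dimtxt,
      "]\n", sep = "")
  invisible(x)
}

#' @export
print.csd_quantity <- function(x, ...) {
  cat(format_scalar_quantity(x), "\n")
  invisible(x)
}

#' @export
format.csd_quantity <- function(x, ...) format_scalar_quantity(x)
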