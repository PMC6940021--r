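# JSON (de)serialization of the CSDM object graph: .csdf / .csdfe files,
# external binary sidecars, canonical key order, and default-key omission.
#
# Parsing goes through jsonlite; emission uses a small canonical writer so
# output is byte-stable: 2-space indent, fixed key order (type first, then
# required, then optional), shortest round-trip decimals, UTF-8, booleans
# written only when true, default-valued optional keys omitted.

# ---- canonical JSON emitter ------------------------------------------------

.json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  # remaining control characters
  for (code in 1:31) {
    ch <- intToUtf8(code)
    if (grepl(ch, s, fixed = TRUE))
      s <- gsub(ch, sprintf("\\u%04x", code), s, fixed = TRUE)
  }
  s
}

# generic JSON number: integers without a decimal point, floats shortest
.fmt_json_generic <- function(x) {
  if (is.integer(x)) return(as.character(x))
  if (!is.finite(x)) stop("cannot serialize non-finite number as JSON",
                          call. = FALSE)
  if (x == floor(x) && abs(x) < 1e15)
    return(format(x, scientific = FALSE))
  .fmt_shortest(x)
}

.verbatim <- function(x) structure(as.character(x), class = "json_verbatim")

# x: named list -> object; unnamed list -> array; atomic length 1 -> scalar;
# atomic length != 1 -> array; json_verbatim -> emitted as-is
.json_emit <- function(x, indent = 0L) {
  pad <- strrep("  ", indent)
  pad1 <- strrep("  ", indent + 1L)
  if (is.null(x)) return("null")
  if (inherits(x, "json_verbatim")) {
    if (length(x) == 1L) return(unclass(x))
    return(.json_emit_array(unclass(x), pad, pad1))
  }
  if (is.list(x)) {
    nms <- names(x)
    if (!is.null(nms)) {
      if (length(x) == 0L) return("{}")
      entries <- vapply(seq_along(x), function(i) {
        paste0(pad1, "\"", .json_escape(nms[i]), "\": ",
               .json_emit(x[[i]], indent + 1L))
      }, character(1))
      return(paste0("{\n", paste(entries, collapse = ",\n"), "\n", pad,
                    "}"))
    }
    if (length(x) == 0L) return("[]")
    entries <- vapply(x, .json_emit, character(1), indent = indent + 1L)
    if (sum(nchar(entries)) <= 72L && !any(grepl("\n", entries)))
      return(paste0("[", paste(entries, collapse = ", "), "]"))
    return(paste0("[\n", paste0(pad1, entries, collapse = ",\n"), "\n",
                  pad, "]"))
  }
  if (length(x) != 1L) {
    parts <- vapply(x, .json_scalar, character(1))
    return(.json_emit_array(parts, pad, pad1))
  }
  .json_scalar(x)
}

.json_emit_array <- function(parts, pad, pad1) {
  if (length(parts) == 0L) return("[]")
  if (sum(nchar(parts)) <= 72L)
    return(paste0("[", paste(parts, collapse = ", "), "]"))
  paste0("[\n", paste0(pad1, parts, collapse = ",\n"), "\n", pad, "]")
}

.json_scalar <- function(x) {
  if (is.null(x)) return("null")
  if (is.logical(x)) return(if (isTRUE(x)) "true" else "false")
  if (is.character(x)) return(paste0("\"", .json_escape(x), "\""))
  if (is.numeric(x)) return(.fmt_json_generic(x))
  stop("cannot serialize value of class ", class(x)[1], call. = FALSE)
}

# ---- building the serialization tree ---------------------------------------

.q_str <- function(q) format_scalar_quantity(q)

.q_default_zero <- function(q) is.null(q) || q$value == 0
.q_default_inf <- function(q) is.null(q) || is.infinite(q$value)

.tree_add <- function(tree, key, value) { tree[[key]] <- value; tree }

.reciprocal_to_tree <- function(r) {
  t <- list()
  if (!.q_default_zero(r$coordinates_offset))
    t$coordinates_offset <- .q_str(r$coordinates_offset)
  if (!is.null(r$description) && nzchar(r$description))
    t$description <- r$description
  if (!is.null(r[["label"]]) && nzchar(r[["label"]])) t$label <- r[["label"]]
  if (!.q_default_zero(r$origin_offset))
    t$origin_offset <- .q_str(r$origin_offset)
  if (!.q_default_inf(r$period)) t$period <- .q_str(r$period)
  if (nzchar(r$quantity_name %||% "")) t$quantity_name <- r$quantity_name
  if (!is.null(r$application) && length(r$application))
    t$application <- r$application
  if (!is.null(r$extra)) t <- c(t, r$extra)
  t
}

.dimension_to_tree <- function(dim) {
  t <- list(type = dim$type)
  if (dim$type == "linear") {
    t$count <- as.integer(dim$count)
    t$increment <- .q_str(dim$increment)
    if (!is.null(dim$application) && length(dim$application))
      t$application <- dim$application
    if (isTRUE(dim$complex_fft)) t$complex_fft <- TRUE
    if (!.q_default_zero(dim$coordinates_offset))
      t$coordinates_offset <- .q_str(dim$coordinates_offset)
  } else if (dim$type == "monotonic") {
    t$coordinates <- lapply(dim$coordinates, .q_str)
    if (!is.null(dim$application) && length(dim$application))
      t$application <- dim$application
  } else if (dim$type == "labeled") {
    t$labels <- as.list(dim$labels)
    if (!is.null(dim$application) && length(dim$application))
      t$application <- dim$application
  }
  if (nzchar(dim$description %||% "")) t$description <- dim$description
  if (nzchar(dim[["label"]] %||% "")) t$label <- dim[["label"]]
  if (dim$type != "labeled") {
    if (!.q_default_zero(dim$origin_offset))
      t$origin_offset <- .q_str(dim$origin_offset)
    if (!.q_default_inf(dim$period)) t$period <- .q_str(dim$period)
    if (nzchar(dim$quantity_name %||% ""))
      t$quantity_name <- dim$quantity_name
    if (!is.null(dim$reciprocal)) {
      rt <- .reciprocal_to_tree(dim$reciprocal)
      if (length(rt)) t$reciprocal <- rt
    }
  }
  if (!is.null(dim$extra)) t <- c(t, dim$extra)
  t
}

.sparse_to_tree <- function(ss) {
  t <- list()
  t$dimension_indexes <- as.list(ss$dimension_indexes)
  if (identical(ss$encoding, "base64")) {
    t$encoding <- "base64"
    t$sparse_grid_vertexes <- base64_encode(.numerals_to_bytes(
      as.numeric(ss$sparse_grid_vertexes), ss$unsigned_integer_type))
  } else {
    t$sparse_grid_vertexes <-
      .verbatim(vapply(as.integer(ss$sparse_grid_vertexes), .fmt_json_generic,
                       character(1)))
  }
  t$unsigned_integer_type <- ss$unsigned_integer_type
  if (nzchar(ss$description %||% "")) t$description <- ss$description
  if (!is.null(ss$application) && length(ss$application))
    t$application <- ss$application
  if (!is.null(ss$extra)) t <- c(t, ss$extra)
  t
}

# format one decoded component as its encoding="none" JSON numeral array
.component_to_numbers <- function(values, numeric_type) {
  nt <- numeric_type_info(numeric_type)
  flat <- encode_component(values, "none", numeric_type)
  if (nt$is_integer)
    .verbatim(vapply(flat, .fmt_json_generic, character(1)))
  else
    .verbatim(vapply(flat, .fmt_shortest, character(1)))
}

.dv_to_tree <- function(dv, encoding_policy = "preserve") {
  t <- list(type = dv$type)
  t$quantity_type <- dv$quantity_type
  t$numeric_type <- dv$numeric_type
  enc <- dv$encoding %||% "none"
  if (encoding_policy %in% c("none", "base64")) enc <- encoding_policy
  if (dv$type == "internal") {
    nt <- numeric_type_info(dv$numeric_type)
    vals <- dv[["components"]]
    if (enc == "none" && !nt$is_integer) {
      flatvals <- unlist(lapply(vals, function(v)
        encode_component(v, "none", dv$numeric_type)))
      if (length(flatvals) && any(!is.finite(flatvals))) {
        message("component contains non-finite values; switching to base64")
        enc <- "base64"
      }
    }
    if (enc == "base64") {
      t$components <- lapply(vals, function(v)
        encode_component(v, "base64", dv$numeric_type))
      t$encoding <- "base64"
    } else {
      t$components <- lapply(vals, function(v)
        .component_to_numbers(v, dv$numeric_type))
    }
  } else {
    t$components_url <- dv$components_url
  }
  if (!is.null(dv$application) && length(dv$application))
    t$application <- dv$application
  if (!is.null(dv$component_labels) &&
      any(nzchar(dv$component_labels)))
    t$component_labels <- as.list(dv$component_labels)
  if (nzchar(dv$description %||% "")) t$description <- dv$description
  if (nzchar(dv$name %||% "")) t$name <- dv$name
  if (nzchar(dv$quantity_name %||% "")) t$quantity_name <- dv$quantity_name
  if (!is.null(dv$sparse_sampling))
    t$sparse_sampling <- .sparse_to_tree(dv$sparse_sampling)
  if (nzchar(dv$unit %||% "")) t$unit <- dv$unit
  if (!is.null(dv$extra)) t <- c(t, dv$extra)
  t
}

.csdm_to_tree <- function(x, encoding_policy = "preserve",
                          timestamp = NULL) {
  t <- list(version = x$version)
  ts <- timestamp %||% x$timestamp
  if (!is.null(ts)) t$timestamp <- ts
  if (!is.null(x$geographic_coordinate)) {
    g <- x$geographic_coordinate
    gt <- list(latitude = .q_str(g$latitude),
               longitude = .q_str(g$longitude))
    if (!is.null(g$altitude)) gt$altitude <- .q_str(g$altitude)
    if (!is.null(g$extra)) gt <- c(gt, g$extra)
    t$geographic_coordinate <- gt
  }
  if (isTRUE(x$read_only)) t$read_only <- TRUE
  if (!is.null(x$tags) && length(x$tags)) t$tags <- as.list(x$tags)
  if (nzchar(x$description %||% "")) t$description <- x$description
  if (!is.null(x$application) && length(x$application))
    t$application <- x$application
  if (length(x$dimensions))
    t$dimensions <- lapply(x$dimensions, .dimension_to_tree)
  t$dependent_variables <- lapply(x$dependent_variables, .dv_to_tree,
                                  encoding_policy = encoding_policy)
  if (!is.null(x$extra)) t <- c(t, x$extra)
  list(csdm = t)
}

#' Serialize a CSDM object to JSON text
#'
#' @param x A `csdm` object.
#' @param encoding_policy `"preserve"` (each dependent variable's own
#'   encoding), `"none"`, or `"base64"`.
#' @param timestamp Optional replacement timestamp string.
#' @return A single JSON string (no trailing newline).
#' @export
csdm_to_json <- function(x, encoding_policy = "preserve",
                         timestamp = NULL) {
  .json_emit(.csdm_to_tree(x, encoding_policy, timestamp))
}

# ---- reading ---------------------------------------------------------------

.take <- function(obj, keys) {
  known <- intersect(keys, names(obj))
  extra <- obj[setdiff(names(obj), keys)]
  list(known = obj[known], extra = if (length(extra)) extra else NULL)
}

.req <- function(obj, key, path) {
  if (is.null(obj[[key]]))
    stop("missing required attribute '", key, "' at ", path, call. = FALSE)
  obj[[key]]
}

.parse_reciprocal <- function(obj) {
  sp <- .take(obj, c("coordinates_offset", "origin_offset", "period",
                     "quantity_name", "label", "description",
                     "application"))
  o <- sp$known
  r <- reciprocal_dimension(
    coordinates_offset = o$coordinates_offset,
    origin_offset = o$origin_offset, period = o$period,
    quantity_name = o$quantity_name %||% "", label = o[["label"]] %||% "",
    description = o$description %||% "", application = o$application)
  r$extra <- sp$extra
  r
}

.parse_dimension <- function(obj, k) {
  path <- sprintf("dimensions[%d]", k)
  type <- .req(obj, "type", path)
  if (type == "linear") {
    sp <- .take(obj, c("type", "count", "increment", "coordinates_offset",
                       "origin_offset", "complex_fft", "period",
                       "quantity_name", "label", "description",
                       "reciprocal", "application"))
    o <- sp$known
    dim <- linear_dimension(
      count = .req(o, "count", path),
      increment = .req(o, "increment", path),
      coordinates_offset = o$coordinates_offset,
      origin_offset = o$origin_offset,
      complex_fft = isTRUE(o$complex_fft), period = o$period,
      quantity_name = o$quantity_name %||% "", label = o[["label"]] %||% "",
      description = o$description %||% "",
      reciprocal = if (!is.null(o$reciprocal))
        .parse_reciprocal(o$reciprocal),
      application = o$application)
    dim$extra <- sp$extra
    return(dim)
  }
  if (type == "monotonic") {
    sp <- .take(obj, c("type", "coordinates", "origin_offset", "period",
                       "quantity_name", "label", "description",
                       "reciprocal", "application"))
    o <- sp$known
    dim <- monotonic_dimension(
      coordinates = .req(o, "coordinates", path),
      origin_offset = o$origin_offset, period = o$period,
      quantity_name = o$quantity_name %||% "", label = o[["label"]] %||% "",
      description = o$description %||% "",
      reciprocal = if (!is.null(o$reciprocal))
        .parse_reciprocal(o$reciprocal),
      application = o$application)
    dim$extra <- sp$extra
    return(dim)
  }
  if (type == "labeled") {
    sp <- .take(obj, c("type", "labels", "label", "description",
                       "application"))
    o <- sp$known
    dim <- labeled_dimension(
      labels = unlist(.req(o, "labels", path)),
      label = o[["label"]] %||% "", description = o$description %||% "",
      application = o$application)
    dim$extra <- sp$extra
    return(dim)
  }
  stop("unknown dimension type '", type, "' at ", path, ".type",
       call. = FALSE)
}

.parse_sparse <- function(obj, strict) {
  sp <- .take(obj, c("dimension_indexes", "sparse_grid_vertexes",
                     "unsigned_integer_type", "encoding", "description",
                     "application"))
  o <- sp$known
  uit <- o$unsigned_integer_type %||% "uint64"
  enc <- o$encoding %||% "none"
  verts <- o$sparse_grid_vertexes
  if (identical(enc, "base64")) {
    verts <- .bytes_to_numerals(base64_decode(verts, strict = strict), uit)
  } else {
    verts <- as.numeric(unlist(verts))
  }
  ss <- sparse_sampling(
    dimension_indexes = as.integer(unlist(o$dimension_indexes)),
    sparse_grid_vertexes = as.integer(verts),
    unsigned_integer_type = uit, encoding = enc,
    description = o$description %||% "", application = o$application)
  ss$extra <- sp$extra
  ss
}

.parse_dv <- function(obj, v, strict) {
  path <- sprintf("dependent_variables[%d]", v)
  type <- .req(obj, "type", path)
  keys <- c("type", "quantity_type", "numeric_type", "unit",
            "quantity_name", "name", "description", "component_labels",
            "sparse_sampling", "application",
            if (type == "internal") c("components", "encoding")
            else "components_url")
  sp <- .take(obj, keys)
  o <- sp$known
  numeric_type <- .req(o, "numeric_type", path)
  enc <- o$encoding %||% "none"
  comps <- NULL
  if (type == "internal") {
    payloads <- .req(o, "components", path)
    comps <- lapply(payloads, function(pl) {
      if (identical(enc, "none")) pl <- as.numeric(unlist(pl %||% list()))
      decode_component(pl, numeric_type, enc, strict = strict)$values
    })
  }
  dv <- dependent_variable(
    type = type, quantity_type = .req(o, "quantity_type", path),
    numeric_type = numeric_type, components = comps,
    components_url = o$components_url, unit = o$unit %||% "",
    encoding = enc, quantity_name = o$quantity_name %||% "",
    name = o$name %||% "", description = o$description %||% "",
    component_labels = if (!is.null(o$component_labels))
      unlist(o$component_labels),
    sparse_sampling = if (!is.null(o$sparse_sampling))
      .parse_sparse(o$sparse_sampling, strict),
    application = o$application)
  dv$extra <- sp$extra
  dv
}

#' Read a CSDM file or JSON text
#'
#' Constructs the full object graph with defaults applied for absent
#' optional keys (absent booleans are false). Internal component payloads
#' are decoded eagerly; external component data is left unresolved until
#' [csdm_load_components()] or [internalize()] is called.
#'
#' @param x Path to a `.csdf`/`.csdfe` file, or a JSON string.
#' @param strictness `"strict"` (unsupported version and malformed base64
#'   are errors) or `"lenient"` (warnings; whitespace in base64 stripped).
#' @return A `csdm` object. When read from a file, the source path is kept
#'   in the `"source_path"` attribute for sidecar resolution.
#' @export
read_csdm <- function(x, strictness = c("strict", "lenient")) {
  strictness <- match.arg(strictness)
  strict <- strictness == "strict"
  from_file <- length(x) == 1L && !grepl("[{\n]", x) && file.exists(x)
  txt <- if (from_file) paste(readLines(x, warn = FALSE, encoding = "UTF-8"),
                              collapse = "\n") else x
  parsed <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                     error = function(e)
                       stop("not valid JSON: ", conditionMessage(e),
                            call. = FALSE))
  if (!is.list(parsed) || is.null(names(parsed)))
    stop("root must be a JSON object with key 'csdm' (an array of CSDM ",
         "objects is not supported)", call. = FALSE)
  root <- parsed[["csdm"]]
  if (is.null(root))
    stop("missing root key 'csdm'", call. = FALSE)
  version <- .req(root, "version", "csdm")
  if (!identical(version, "1.0")) {
    msg <- paste0("unsupported CSD model version '", version, "'")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  sp <- .take(root, c("version", "timestamp", "geographic_coordinate",
                      "read_only", "tags", "description", "application",
                      "dimensions", "dependent_variables"))
  o <- sp$known
  gc_ <- NULL
  if (!is.null(o$geographic_coordinate)) {
    g <- o$geographic_coordinate
    gsp <- .take(g, c("latitude", "longitude", "altitude"))
    gc_ <- geographic_coordinate(
      latitude = .req(g, "latitude", "geographic_coordinate"),
      longitude = .req(g, "longitude", "geographic_coordinate"),
      altitude = gsp$known$altitude)
    gc_$extra <- gsp$extra
  }
  dims <- list()
  if (!is.null(o$dimensions))
    dims <- lapply(seq_along(o$dimensions), function(k)
      .parse_dimension(o$dimensions[[k]], k - 1L))
  dvs <- list()
  if (!is.null(o$dependent_variables))
    dvs <- lapply(seq_along(o$dependent_variables), function(v)
      .parse_dv(o$dependent_variables[[v]], v - 1L, strict))
  out <- csdm(dimensions = dims, dependent_variables = dvs,
              version = version, timestamp = o$timestamp,
              geographic_coordinate = gc_,
              read_only = isTRUE(o$read_only),
              tags = if (!is.null(o$tags)) unlist(o$tags),
              description = o$description %||% "",
              application = o$application)
  out$extra <- sp$extra
  if (from_file) attr(out, "source_path") <- normalizePath(x)
  out
}

# ---- external components ---------------------------------------------------

#' Resolve a components_url against the file's directory
#'
#' `file:` URLs must be relative (`file:./...`) and resolve inside the
#' directory holding the `.csdfe` file (or a subfolder); escaping paths are
#' a security error. `https:` URLs require `allow_network = TRUE`.
#'
#' @param url URL string.
#' @param base Directory containing the `.csdfe` file.
#' @param allow_network Permit https fetches?
#' @return For `file:` URLs, the resolved local path. For `https:` URLs, a
#'   raw vector of the fetched bytes.
#' @export
resolve_components_url <- function(url, base, allow_network = FALSE) {
  stopifnot(is.character(url), length(url) == 1L)
  if (startsWith(url, "file:")) {
    rel <- substring(url, 6L)
    if (!startsWith(rel, "./"))
      stop("file: components_url must be relative ('file:./...'): ", url,
           call. = FALSE)
    parts <- strsplit(rel, "/", fixed = TRUE)[[1]]
    if (any(parts == ".."))
      stop("components_url escapes the dataset directory: ", url,
           call. = FALSE)
    path <- file.path(base, substring(rel, 3L))
    if (!file.exists(path))
      stop("external component file not found: ", path, call. = FALSE)
    resolved <- normalizePath(path)
    based <- normalizePath(base)
    if (!startsWith(resolved, based))
      stop("components_url escapes the dataset directory: ", url,
           call. = FALSE)
    return(resolved)
  }
  if (startsWith(url, "https:")) {
    if (!allow_network)
      stop("network access is disabled; cannot fetch ", url, call. = FALSE)
    con <- url(url, open = "rb")
    on.exit(close(con))
    chunks <- list()
    repeat {
      b <- readBin(con, raw(), n = 1048576L)
      if (length(b) == 0L) break
      chunks[[length(chunks) + 1L]] <- b
    }
    return(do.call(c, chunks))
  }
  stop("unsupported URL scheme in components_url: ", url, call. = FALSE)
}

#' Load external component data into a CSDM object
#'
#' Reads each external dependent variable's binary sidecar (little-endian,
#' components stored contiguously in component order) and attaches the
#' decoded numerals. Internal variables are untouched.
#'
#' @param x A `csdm` object read from a file (or `base` given).
#' @param base Directory for resolving `file:` URLs; defaults to the
#'   directory the object was read from.
#' @param allow_network Permit https fetches?
#' @return The `csdm` object with all components populated.
#' @export
csdm_load_components <- function(x, base = NULL, allow_network = FALSE) {
  stopifnot(inherits(x, "csdm"))
  src <- attr(x, "source_path")
  base <- base %||% (if (!is.null(src)) dirname(src))
  for (v in seq_along(x$dependent_variables)) {
    dv <- x$dependent_variables[[v]]
    if (dv$type != "external" || !is.null(dv[["components"]])) next
    if (is.null(base))
      stop("no base directory to resolve ", dv$components_url,
           call. = FALSE)
    res <- resolve_components_url(dv$components_url, base, allow_network)
    bytes <- if (is.raw(res)) res else
      readBin(res, raw(), n = file.info(res)$size)
    p <- parse_quantity_type(dv$quantity_type)$p
    vals <- .bytes_to_numerals(bytes, dv$numeric_type)
    if (length(vals) %% p != 0L)
      stop("external payload length ", length(vals),
           " is not divisible by p = ", p, " (", dv$components_url, ")",
           call. = FALSE)
    M <- length(vals) %/% p
    dv[["components"]] <- lapply(seq_len(p), function(q)
      vals[((q - 1L) * M + 1L):(q * M)])
    x$dependent_variables[[v]] <- dv
  }
  x
}

#' Convert a dependent variable between internal and external storage
#'
#' `internalize()` turns a loaded external variable into an internal one
#' (base64 by default); `externalize()` marks an internal variable external
#' and records the sidecar URL — the binary sidecar itself (components
#' concatenated in order, little-endian) is written by [write_csdm()].
#'
#' @param dv A `csd_dependent_variable` with components loaded.
#' @param encoding Encoding for the internalized components.
#' @return The converted dependent variable; decoded numerals are
#'   unchanged.
#' @export
internalize <- function(dv, encoding = "base64") {
  stopifnot(inherits(dv, "csd_dependent_variable"))
  if (dv$type == "internal") return(dv)
  if (is.null(dv[["components"]]))
    stop("external component data not loaded; call csdm_load_components() ",
         "first (url: ", dv$components_url %||% "<none>", ")",
         call. = FALSE)
  dv$type <- "internal"
  dv$components_url <- NULL
  dv$encoding <- encoding
  dv
}

#' @rdname internalize
#' @param url Relative sidecar URL (`file:./...`).
#' @export
externalize <- function(dv, url) {
  stopifnot(inherits(dv, "csd_dependent_variable"))
  if (is.null(dv[["components"]]))
    stop("cannot externalize a dependent variable without loaded components",
         call. = FALSE)
  if (!startsWith(url, "file:./"))
    stop("sidecar url must be of the form 'file:./...'", call. = FALSE)
  dv$type <- "external"
  dv$components_url <- url
  dv
}

# ---- writing ---------------------------------------------------------------

.has_external <- function(x)
  any(vapply(x$dependent_variables, function(dv)
    identical(dv$type, "external"), logical(1)))

#' Write a CSDM object to a .csdf or .csdfe file
#'
#' The instance must validate with zero errors in strict mode. Optional
#' keys at their default values are omitted; booleans appear only when
#' true; key order and number formatting are canonical, so writing the same
#' object twice (with `update_timestamp = FALSE`) is byte-identical.
#' External dependent variables with loaded components get their binary
#' sidecars written next to the file.
#'
#' @param x A `csdm` object.
#' @param path Output path; must end in `.csdfe` when any dependent
#'   variable is external, `.csdf` otherwise.
#' @param encoding_policy `"preserve"`, `"none"`, or `"base64"`.
#' @param update_timestamp Refresh the timestamp to the current UTC time?
#' @return Invisibly, the output path.
#' @export
write_csdm <- function(x, path, encoding_policy = "preserve",
                       update_timestamp = FALSE) {
  stopifnot(inherits(x, "csdm"))
  diags <- csdm_validate(x, "strict")
  errs <- diags[diags$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0L)
    stop("refusing to write an invalid instance: ", errs$path[1L], ": ",
         errs$message[1L], call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (.has_external(x)) {
    if (ext != "csdfe")
      stop("dataset holds external dependent variables; path must use the ",
           "'.csdfe' extension", call. = FALSE)
  } else if (ext != "csdf") {
    stop("fully internal dataset; path must use the '.csdf' extension",
         call. = FALSE)
  }
  src <- attr(x, "source_path")
  if (isTRUE(x$read_only) && !is.null(src) && file.exists(path) &&
      normalizePath(path) == src)
    stop("refusing to overwrite a read_only dataset in place", call. = FALSE)
  # sidecars for external variables whose data is in memory
  outdir <- dirname(path)
  for (dv in x$dependent_variables) {
    if (identical(dv$type, "external") && !is.null(dv[["components"]]) &&
        startsWith(dv$components_url %||% "", "file:./")) {
      rel <- substring(dv$components_url, 8L)
      sidecar <- file.path(outdir, rel)
      dir.create(dirname(sidecar), recursive = TRUE, showWarnings = FALSE)
      bytes <- do.call(c, lapply(dv[["components"]], function(v)
        .numerals_to_bytes(v, dv$numeric_type)))
      writeBin(bytes, sidecar)
    }
  }
  ts <- if (update_timestamp)
    format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  txt <- csdm_to_json(x, encoding_policy, timestamp = ts)
  con <- file(path, open = "wb")
  writeBin(charToRaw(paste0(txt, "\n")), con)
  close(con)
  invisible(path)
}
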