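# The CSDM object graph: dimensions, dependent variables, sparse sampling,
# and the root container, plus strict/lenient validation.
#
# Objects are plain S3 lists mirroring the file attributes; quantities are
# csd_quantity objects, units are strings as written in the file. Unknown
# keys encountered on read are preserved under $extra and re-emitted.

# drop NULL members so constructed and re-read objects have identical shape
.compact <- function(x) x[!vapply(x, is.null, logical(1))]

.as_quantity <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "csd_quantity")) x else parse_scalar_quantity(x)
}

#' Linear dimension
#'
#' A uniformly sampled grid axis: coordinates are
#' `increment * (j - Z) + coordinates_offset` for `j = 0 ... count-1`,
#' where `Z = 0` normally and `Z = T/2` (`T = count` for even, `count - 1`
#' for odd counts) when `complex_fft` is true, associating
#' `coordinates_offset` with the zero frequency after a complex FFT.
#'
#' @param count Positive integer number of grid points.
#' @param increment Nonzero scalar quantity (string or `csd_quantity`).
#' @param coordinates_offset,origin_offset Scalar quantities; default zero
#'   in the increment's unit.
#' @param complex_fft Logical, default `FALSE`.
#' @param period Scalar quantity; default infinite (non-periodic). A zero
#'   period is invalid.
#' @param quantity_name,label,description Strings.
#' @param reciprocal Optional `csd_reciprocal_dimension`.
#' @param application Optional named list of reverse-DNS keyed metadata.
#' @return A `csd_dimension` of subtype linear.
#' @export
linear_dimension <- function(count, increment, coordinates_offset = NULL,
                             origin_offset = NULL, complex_fft = FALSE,
                             period = NULL, quantity_name = "",
                             label = "", description = "",
                             reciprocal = NULL, application = NULL) {
  structure(.compact(list(type = "linear", count = as.integer(count),
                 increment = .as_quantity(increment),
                 coordinates_offset = .as_quantity(coordinates_offset),
                 origin_offset = .as_quantity(origin_offset),
                 complex_fft = isTRUE(complex_fft),
                 period = .as_quantity(period),
                 quantity_name = quantity_name, label = label,
                 description = description, reciprocal = reciprocal,
                 application = application, extra = NULL)),
            class = c("csd_linear_dimension", "csd_dimension"))
}

#' Monotonic dimension
#'
#' A non-uniformly sampled axis: the stored coordinates must be strictly
#' increasing or strictly decreasing and mutually dimensionality-equal.
#'
#' @param coordinates Character vector or list of scalar quantities.
#' @inheritParams linear_dimension
#' @return A `csd_dimension` of subtype monotonic.
#' @export
monotonic_dimension <- function(coordinates, origin_offset = NULL,
                                period = NULL, quantity_name = "",
                                label = "", description = "",
                                reciprocal = NULL, application = NULL) {
  coords <- lapply(coordinates, .as_quantity)
  structure(.compact(list(type = "monotonic", coordinates = coords,
                 origin_offset = .as_quantity(origin_offset),
                 period = .as_quantity(period),
                 quantity_name = quantity_name, label = label,
                 description = description, reciprocal = reciprocal,
                 application = application, extra = NULL)),
            class = c("csd_monotonic_dimension", "csd_dimension"))
}

#' Labeled dimension
#'
#' A purely qualitative axis of unique string labels; spacing carries no
#' physical meaning.
#'
#' @param labels Character vector of unique labels.
#' @inheritParams linear_dimension
#' @return A `csd_dimension` of subtype labeled.
#' @export
labeled_dimension <- function(labels, label = "", description = "",
                              application = NULL) {
  structure(.compact(list(type = "labeled", labels = as.character(labels),
                 label = label, description = description,
                 application = application, extra = NULL)),
            class = c("csd_labeled_dimension", "csd_dimension"))
}

#' Reciprocal dimension metadata
#'
#' Metadata describing the axis reciprocal to its parent dimension (e.g.
#' frequency for a time axis); holds no coordinates of its own.
#'
#' @inheritParams linear_dimension
#' @export
reciprocal_dimension <- function(coordinates_offset = NULL,
                                 origin_offset = NULL, period = NULL,
                                 quantity_name = "", label = "",
                                 description = "", application = NULL) {
  structure(.compact(list(coordinates_offset = .as_quantity(coordinates_offset),
                 origin_offset = .as_quantity(origin_offset),
                 period = .as_quantity(period),
                 quantity_name = quantity_name, label = label,
                 description = description, application = application,
                 extra = NULL)),
            class = "csd_reciprocal_dimension")
}

#' Sparse-sampling descriptor
#'
#' @param dimension_indexes 0-based indexes of the sparsely sampled
#'   dimensions.
#' @param sparse_grid_vertexes Flat integer vector (groups of
#'   `length(dimension_indexes)` form one vertex) or a vertex matrix.
#' @param unsigned_integer_type Storage type for the vertex array.
#' @param encoding `"none"` or `"base64"`.
#' @param description,application As elsewhere.
#' @export
sparse_sampling <- function(dimension_indexes, sparse_grid_vertexes,
                            unsigned_integer_type = "uint8",
                            encoding = "none", description = "",
                            application = NULL) {
  if (is.matrix(sparse_grid_vertexes))
    sparse_grid_vertexes <- flatten_sparse_vertexes(sparse_grid_vertexes)
  structure(.compact(list(dimension_indexes = as.integer(dimension_indexes),
                 sparse_grid_vertexes = as.integer(sparse_grid_vertexes),
                 unsigned_integer_type = unsigned_integer_type,
                 encoding = encoding, description = description,
                 application = application, extra = NULL)),
            class = "csd_sparse_sampling")
}

#' Dependent variable
#'
#' Holds the p component arrays sampled on the common grid, either inline
#' (`type = "internal"`) or in an external little-endian binary file
#' addressed by `components_url` (`type = "external"`).
#'
#' @param type `"internal"` or `"external"`.
#' @param quantity_type Quantity-type literal (fixes p).
#' @param numeric_type Numeric-type literal.
#' @param components For internal variables, a list of p numeric/complex
#'   vectors (decoded numerals). May be `NULL` for external variables whose
#'   data has not been loaded.
#' @param components_url URL string (`file:./...` or `https://...`),
#'   external only.
#' @param unit Unit string; default dimensionless.
#' @param encoding Preferred storage encoding for internal serialization.
#' @param quantity_name,name,description Strings.
#' @param component_labels Character vector of length p.
#' @param sparse_sampling Optional `csd_sparse_sampling`.
#' @param application Optional named list.
#' @export
dependent_variable <- function(type = "internal", quantity_type = "scalar",
                               numeric_type = "float64", components = NULL,
                               components_url = NULL, unit = "",
                               encoding = "none", quantity_name = "",
                               name = "", description = "",
                               component_labels = NULL,
                               sparse_sampling = NULL, application = NULL) {
  structure(.compact(list(type = type, quantity_type = quantity_type,
                 numeric_type = numeric_type, components = components,
                 components_url = components_url, unit = unit,
                 encoding = encoding, quantity_name = quantity_name,
                 name = name, description = description,
                 component_labels = component_labels,
                 sparse_sampling = sparse_sampling,
                 application = application, extra = NULL)),
            class = "csd_dependent_variable")
}

#' Geographic coordinate
#'
#' @param latitude,longitude Required angle quantities (strings or
#'   `csd_quantity`).
#' @param altitude Optional length quantity.
#' @export
geographic_coordinate <- function(latitude, longitude, altitude = NULL) {
  structure(.compact(list(latitude = .as_quantity(latitude),
                 longitude = .as_quantity(longitude),
                 altitude = .as_quantity(altitude), extra = NULL)),
            class = "csd_geographic_coordinate")
}

#' CSDM root container
#'
#' @param dimensions Ordered list of `csd_dimension` objects (may be empty:
#'   d = 0 datasets are legal and have a single-sample grid).
#' @param dependent_variables Ordered list of `csd_dependent_variable`s.
#' @param version Model version string; this package writes "1.0".
#' @param timestamp Optional ISO-8601 UTC string.
#' @param geographic_coordinate Optional `csd_geographic_coordinate`.
#' @param read_only Logical; archived files must not be overwritten.
#' @param tags Character vector of unique keywords.
#' @param description String.
#' @param application Optional named list keyed by reverse-DNS names.
#' @return A `csdm` object.
#' @export
csdm <- function(dimensions = list(), dependent_variables = list(),
                 version = "1.0", timestamp = NULL,
                 geographic_coordinate = NULL, read_only = FALSE,
                 tags = NULL, description = "", application = NULL) {
  structure(.compact(list(version = version, timestamp = timestamp,
                 geographic_coordinate = geographic_coordinate,
                 read_only = isTRUE(read_only), tags = tags,
                 description = description, application = application,
                 dimensions = dimensions,
                 dependent_variables = dependent_variables, extra = NULL)),
            class = "csdm")
}

#' Grid shape of a CSDM object
#'
#' @param x A `csdm` object.
#' @return Integer vector of per-dimension counts (length d).
#' @export
csdm_shape <- function(x) {
  vapply(x$dimensions, dimension_count, integer(1))
}

#' Number of grid points along one dimension
#'
#' @param dim A `csd_dimension`.
#' @export
dimension_count <- function(dim) {
  switch(dim$type,
         linear = as.integer(dim$count),
         monotonic = length(dim$coordinates),
         labeled = length(dim$labels),
         stop("unknown dimension type", call. = FALSE))
}

#' Expected per-component sample count of a dependent variable
#'
#' For full sampling this is the grid size `M = prod(N_k)` (1 when d = 0);
#' under sparse sampling it is the number of sparse-grid vertexes times the
#' product of counts over the fully sampled dimensions. For complex numeric
#' types the flat serialized array holds twice this many numerals.
#'
#' @param dv A `csd_dependent_variable`.
#' @param dimensions List of `csd_dimension`s defining the grid.
#' @return Expected number of data values per component.
#' @export
dependent_variable_sample_count <- function(dv, dimensions) {
  counts <- vapply(dimensions, dimension_count, integer(1))
  ss <- dv$sparse_sampling
  if (is.null(ss)) return(grid_size(counts))
  sdims <- ss$dimension_indexes
  if (any(sdims < 0 | sdims >= length(counts)))
    stop("sparse dimension index out of range", call. = FALSE)
  verts <- unflatten_sparse_vertexes(ss$sparse_grid_vertexes, length(sdims))
  full_dims <- setdiff(seq_along(counts) - 1L, sdims)
  nrow(verts) * grid_size(counts[full_dims + 1L])
}

# ---- validation ------------------------------------------------------------

.diag <- function(severity, path, message)
  data.frame(severity = severity, path = path, message = message,
             stringsAsFactors = FALSE)

.no_diags <- data.frame(severity = character(0), path = character(0),
                        message = character(0), stringsAsFactors = FALSE)

.validate_quantity_dims <- function(quantities, path, attr_names) {
  # all non-NULL quantities must share dimensionality
  out <- .no_diags
  present <- !vapply(quantities, is.null, logical(1))
  qs <- quantities[present]
  nms <- attr_names[present]
  if (length(qs) >= 2L) {
    ref <- qs[[1L]]
    for (t in seq_along(qs)[-1L]) {
      if (!same_dimensionality(qs[[t]]$unit, ref$unit))
        out <- rbind(out, .diag("error",
          paste0(path, ".", nms[t]),
          sprintf("dimensionality mismatch: '%s' vs '%s'",
                  qs[[t]]$unit$symbol, ref$unit$symbol)))
    }
  }
  out
}

.validate_dimension <- function(dim, k) {
  path <- sprintf("dimensions[%d]", k)
  out <- .no_diags
  add <- function(sev, attr, msg)
    out <<- rbind(out, .diag(sev, paste0(path, ".", attr), msg))
  if (dim$type == "linear") {
    if (is.null(dim$count) || is.na(dim$count) || dim$count < 1L)
      add("error", "count", "count must be a positive integer")
    if (is.null(dim$increment))
      add("error", "increment", "increment is required")
    else if (dim$increment$value == 0)
      add("error", "increment", "increment must be nonzero")
    if (!is.null(dim$period) && is.finite(dim$period$value) &&
        dim$period$value == 0)
      add("error", "period", "a period of zero is invalid")
    if (!is.null(dim$increment))
      out <- rbind(out, .validate_quantity_dims(
        list(dim$increment, dim$coordinates_offset, dim$origin_offset,
             dim$period),
        path, c("increment", "coordinates_offset", "origin_offset",
                "period")))
    if (!is.null(dim$reciprocal) && !is.null(dim$increment)) {
      rq <- Filter(Negate(is.null),
                   list(dim$reciprocal$coordinates_offset,
                        dim$reciprocal$origin_offset,
                        dim$reciprocal$period))
      if (length(rq) > 0L) {
        inv <- -dim$increment$unit$dims
        if (!identical(unname(rq[[1L]]$unit$dims), unname(inv)))
          add("warning", "reciprocal",
              "reciprocal dimensionality is not the inverse of the parent's")
      }
    }
  } else if (dim$type == "monotonic") {
    coords <- dim$coordinates
    if (length(coords) == 0L) {
      add("error", "coordinates", "coordinates must be non-empty")
    } else {
      u0 <- coords[[1L]]$unit
      bad_dim <- FALSE
      for (qq in coords[-1L])
        if (!same_dimensionality(qq$unit, u0)) bad_dim <- TRUE
      if (bad_dim) {
        add("error", "coordinates",
            "coordinates must share one dimensionality")
      } else if (length(coords) > 1L) {
        v <- vapply(coords, .q_value_in, numeric(1), unit = u0)
        dv <- diff(v)
        if (any(dv == 0))
          add("error", "coordinates",
              "coordinates must be unique (duplicate after unit conversion)")
        else if (!(all(dv > 0) || all(dv < 0)))
          add("error", "coordinates",
              "coordinates must be strictly increasing or decreasing")
      }
      out <- rbind(out, .validate_quantity_dims(
        list(coords[[1L]], dim$origin_offset, dim$period), path,
        c("coordinates", "origin_offset", "period")))
    }
    if (!is.null(dim$period) && is.finite(dim$period$value) &&
        dim$period$value == 0)
      add("error", "period", "a period of zero is invalid")
  } else if (dim$type == "labeled") {
    if (length(dim$labels) == 0L)
      add("error", "labels", "labels must be non-empty")
    else if (anyDuplicated(dim$labels))
      add("error", "labels", "labels must be pairwise distinct")
  } else {
    add("error", "type", paste0("unknown dimension type '", dim$type, "'"))
  }
  # affine temperature units are flagged, not fatal
  qs <- Filter(function(q) inherits(q, "csd_quantity"), dim)
  if (dim$type == "monotonic" && length(dim$coordinates))
    qs <- c(qs, dim$coordinates[1])
  for (q in qs)
    if (isTRUE(q$unit$affine))
      add("warning", "unit",
          "affine temperature unit (°C/°F) is discouraged")
  out
}

.validate_dv <- function(dv, v, dimensions, lenient) {
  path <- sprintf("dependent_variables[%d]", v)
  out <- .no_diags
  add <- function(sev, attr, msg)
    out <<- rbind(out, .diag(sev, paste0(path, ".", attr), msg))
  if (!dv$type %in% c("internal", "external"))
    add("error", "type", "type must be 'internal' or 'external'")
  qt <- tryCatch(parse_quantity_type(dv$quantity_type), error = identity)
  if (inherits(qt, "error")) {
    add("error", "quantity_type", conditionMessage(qt))
    qt <- NULL
  }
  nt <- tryCatch(numeric_type_info(dv$numeric_type), error = identity)
  if (inherits(nt, "error")) {
    add("error", "numeric_type", conditionMessage(nt))
    nt <- NULL
  }
  tryCatch(parse_unit(dv$unit), error = function(e)
    add("error", "unit", conditionMessage(e)))
  if (dv$type == "external" && is.null(dv$components_url) &&
      is.null(dv[["components"]]))
    add("error", "components_url",
        "components_url is required for external dependent variables")
  if (dv$type == "internal" && is.null(dv[["components"]]))
    add("error", "components",
        "components are required for internal dependent variables")
  if (!is.null(dv$component_labels) && !is.null(qt)) {
    if (length(dv$component_labels) > qt$p)
      add("error", "component_labels",
          sprintf("expected at most %d component labels, got %d", qt$p,
                  length(dv$component_labels)))
    else if (length(dv$component_labels) < qt$p && !lenient)
      add("error", "component_labels",
          sprintf("expected %d component labels, got %d", qt$p,
                  length(dv$component_labels)))
  }
  ss <- dv$sparse_sampling
  if (!is.null(ss)) {
    d <- length(dimensions)
    if (any(ss$dimension_indexes < 0 | ss$dimension_indexes >= d))
      add("error", "sparse_sampling.dimension_indexes",
          "sparse dimension index out of range")
    else if (anyDuplicated(ss$dimension_indexes))
      add("error", "sparse_sampling.dimension_indexes",
          "sparse dimension indexes must be unique")
    else {
      s <- length(ss$dimension_indexes)
      if (length(ss$sparse_grid_vertexes) %% s != 0L) {
        add("error", "sparse_sampling.sparse_grid_vertexes",
            "flat vertex array length must be a multiple of the number of sparse dimensions")
      } else {
        verts <- unflatten_sparse_vertexes(ss$sparse_grid_vertexes, s)
        counts <- vapply(dimensions, dimension_count, integer(1))
        for (t in seq_len(s)) {
          Nk <- counts[ss$dimension_indexes[t] + 1L]
          if (nrow(verts) > 0 && any(verts[, t] < 0 | verts[, t] >= Nk))
            add("error", "sparse_sampling.sparse_grid_vertexes",
                sprintf("vertex index out of range for dimension %d",
                        ss$dimension_indexes[t]))
        }
      }
    }
  }
  if (!is.null(dv[["components"]]) && !is.null(qt)) {
    if (length(dv[["components"]]) != qt$p)
      add("error", "components",
          sprintf("quantity_type '%s' implies %d components, got %d",
                  dv$quantity_type, qt$p, length(dv[["components"]])))
    lens <- vapply(dv[["components"]], length, integer(1))
    if (length(unique(lens)) > 1L)
      add("error", "components",
          "all components must have the same sample count")
    else if (length(lens) > 0L) {
      expected <- tryCatch(
        dependent_variable_sample_count(dv, dimensions),
        error = function(e) NA_real_)
      if (!is.na(expected) && lens[1L] != expected)
        add("error", "components",
            sprintf("expected %s samples per component, got %d",
                    format(expected), lens[1L]))
    }
  }
  out
}

#' Validate a CSDM object graph
#'
#' Checks every required-attribute, uniqueness, monotonicity,
#' dimensionality, and cross-object length rule of the model. Diagnostics
#' are returned, never thrown, ordered by (dimension index,
#' dependent-variable index, attribute). Lenient mode downgrades
#' warning-class findings but never required-attribute violations.
#'
#' @param x A `csdm` object.
#' @param strictness `"strict"` or `"lenient"`.
#' @return A data frame with columns `severity`, `path`, `message`;
#'   zero rows when the instance is fully valid.
#' @export
csdm_validate <- function(x, strictness = c("strict", "lenient")) {
  strictness <- match.arg(strictness)
  lenient <- strictness == "lenient"
  stopifnot(inherits(x, "csdm"))
  out <- .no_diags
  if (!is.character(x$version) || length(x$version) != 1L)
    out <- rbind(out, .diag("error", "version", "version is required"))
  if (!is.null(x$timestamp) &&
      !grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}", x$timestamp))
    out <- rbind(out, .diag("error", "timestamp",
                            "timestamp must be ISO-8601"))
  if (!is.null(x$tags) && anyDuplicated(x$tags))
    out <- rbind(out, .diag("error", "tags", "tags must be unique"))
  gc_ <- x$geographic_coordinate
  if (!is.null(gc_)) {
    deg <- parse_unit("°")
    chk <- function(q, nm, lo, hi) {
      if (is.null(q))
        return(.diag("error", paste0("geographic_coordinate.", nm),
                     paste(nm, "is required")))
      v <- tryCatch(.q_value_in(q, deg), error = function(e) NA_real_)
      if (is.na(v))
        return(.diag("error", paste0("geographic_coordinate.", nm),
                     paste(nm, "must be an angle")))
      if (v < lo || v > hi)
        return(.diag("error", paste0("geographic_coordinate.", nm),
                     sprintf("%s out of range [%g°, %g°]",
                             nm, lo, hi)))
      .no_diags
    }
    out <- rbind(out, chk(gc_$latitude, "latitude", -90, 90),
                 chk(gc_$longitude, "longitude", -180, 180))
  }
  for (k in seq_along(x$dimensions))
    out <- rbind(out, .validate_dimension(x$dimensions[[k]], k - 1L))
  for (v in seq_along(x$dependent_variables))
    out <- rbind(out, .validate_dv(x$dependent_variables[[v]], v - 1L,
                                   x$dimensions, lenient))
  if (lenient)
    out <- out[out$severity != "warning", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.csdm <- function(x, ...) {
  shape <- csdm_shape(x)
  cat("<csdm> version", x$version, "\n")
  cat("  dimensions:", length(x$dimensions),
      if (length(shape)) paste0("(", paste(shape, collapse = " x "), ")")
      else "(0-dimensional, single sample)", "\n")
  for (k in seq_along(x$dimensions)) {
    d <- x$dimensions[[k]]
    cat(sprintf("    [%d] %s", k - 1L, d$type))
    if (d$type == "linear")
      cat(sprintf(" count=%d increment=%s", d$count,
                  format_scalar_quantity(d$increment)))
    if (nzchar(d[["label"]] %||% "")) cat(" label=", d[["label"]], sep = "")
    cat("\n")
  }
  cat("  dependent variables:", length(x$dependent_variables), "\n")
  for (v in seq_along(x$dependent_variables)) {
    dv <- x$dependent_variables[[v]]
    cat(sprintf("    [%d] %s %s %s", v - 1L, dv$type, dv$quantity_type,
                dv$numeric_type))
    if (nzchar(dv$unit %||% "")) cat(" unit=", dv$unit, sep = "")
    if (!is.null(dv$sparse_sampling)) cat(" (sparse)")
    cat("\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
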