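# Column-major mapping between flat component storage and the d-dimensional
# grid, plus sparse-grid vertex handling.
#
# Storage order is column-major relative to the ordered dimensions:
# dimension 0 varies fastest. Offsets and grid indexes are 0-based, matching
# the file form; d = 0 is legal (single-sample grid, empty product = 1).

#' Total sample count of a grid
#'
#' @param counts Integer vector (N_0, ..., N_{d-1}); may be empty (d = 0).
#' @return The product of the counts (1 for d = 0).
#' @export
grid_size <- function(counts) {
  stopifnot(all(counts >= 1))
  prod(as.numeric(counts))
}

#' Flat offset to grid indexes
#'
#' @param i 0-based flat offset(s), `0 <= i < prod(counts)`.
#' @param counts Grid shape (N_0, ..., N_{d-1}).
#' @return For scalar `i` an integer vector (j_0, ..., j_{d-1}); for vector
#'   `i` a matrix with one row per offset.
#' @export
offset_to_indexes <- function(i, counts) {
  M <- grid_size(counts)
  if (any(i < 0 | i >= M)) stop("flat offset out of range", call. = FALSE)
  d <- length(counts)
  out <- matrix(0L, nrow = length(i), ncol = d)
  rem <- as.numeric(i)
  for (k in seq_len(d)) {
    out[, k] <- as.integer(rem %% counts[k])
    rem <- rem %/% counts[k]
  }
  if (length(i) == 1L) out[1L, ] else out
}

#' Grid indexes to flat offset
#'
#' Exact inverse of [offset_to_indexes()].
#'
#' @param j Integer vector (j_0, ..., j_{d-1}), 0-based, or a matrix with
#'   one such row per sample.
#' @param counts Grid shape.
#' @return 0-based flat offset(s).
#' @export
indexes_to_offset <- function(j, counts) {
  d <- length(counts)
  if (is.matrix(j)) {
    stopifnot(ncol(j) == d)
  } else {
    stopifnot(length(j) == d)
    j <- matrix(j, nrow = 1L)
  }
  if (d == 0L) return(rep(0, nrow(j)))
  for (k in seq_len(d))
    if (any(j[, k] < 0 | j[, k] >= counts[k]))
      stop("grid index out of range along dimension ", k - 1L,
           call. = FALSE)
  strides <- cumprod(c(1, counts[-d]))
  off <- as.numeric(j %*% strides)
  if (nrow(j) == 1L) off[1L] else off
}

#' Unflatten a sparse-grid vertex array
#'
#' The file stores the ordered set of sparse-grid vertexes flattened into a
#' single integer array; consecutive groups of `s_count` integers form one
#' vertex.
#'
#' @param flat Integer vector, length a multiple of `s_count`.
#' @param s_count Number of sparsely sampled dimensions.
#' @return A matrix with `s_count` columns, one row per vertex (0 rows for
#'   an empty array).
#' @export
unflatten_sparse_vertexes <- function(flat, s_count) {
  stopifnot(s_count >= 1)
  if (length(flat) %% s_count != 0L)
    stop("sparse vertex array length ", length(flat),
         " is not a multiple of ", s_count, call. = FALSE)
  matrix(as.integer(flat), ncol = s_count, byrow = TRUE)
}

#' Flatten sparse-grid vertexes for serialization
#'
#' Inverse of [unflatten_sparse_vertexes()].
#'
#' @param vertexes Matrix with one 0-based vertex per row.
#' @return Integer vector.
#' @export
flatten_sparse_vertexes <- function(vertexes) {
  stopifnot(is.matrix(vertexes))
  as.integer(t(vertexes))
}

# flat 0-based offsets (into the full grid) covered by a sparse layout, in
# the storage order of the sparse component array: within each vertex the
# fully sampled dimensions run column-major, and vertexes follow file order
.sparse_offsets <- function(sparse_dims, vertexes, counts) {
  d <- length(counts)
  if (any(sparse_dims < 0 | sparse_dims >= d))
    stop("sparse dimension index out of range", call. = FALSE)
  if (anyDuplicated(sparse_dims))
    stop("duplicate sparse dimension indexes", call. = FALSE)
  nv <- nrow(vertexes)
  for (t in seq_along(sparse_dims))
    if (nv > 0 && any(vertexes[, t] < 0 |
                      vertexes[, t] >= counts[sparse_dims[t] + 1L]))
      stop("sparse vertex index out of bounds for dimension ",
           sparse_dims[t], call. = FALSE)
  if (anyDuplicated(vertexes) > 0)
    stop("duplicate sparse-grid vertexes", call. = FALSE)
  full_dims <- setdiff(seq_len(d) - 1L, sparse_dims)
  cross <- if (length(full_dims) == 0L) {
    matrix(integer(0), nrow = 1L, ncol = 0L)
  } else {
    # expand.grid varies its first factor fastest = column-major
    as.matrix(expand.grid(lapply(counts[full_dims + 1L],
                                 function(n) 0:(n - 1L))))
  }
  cs <- nrow(cross)
  offs <- numeric(nv * cs)
  J <- matrix(0L, nrow = cs, ncol = d)
  for (v in seq_len(nv)) {
    if (length(full_dims) > 0L) J[, full_dims + 1L] <- cross
    J[, sparse_dims + 1L] <- matrix(vertexes[v, ], nrow = cs,
                                    ncol = length(sparse_dims), byrow = TRUE)
    offs[((v - 1L) * cs + 1L):(v * cs)] <- indexes_to_offset(J, counts)
  }
  offs
}

#' Scatter sparse component values onto the full grid
#'
#' Places each fully sampled cross-section of a sparsely sampled component
#' at its sparse-grid vertex. Cross-sections are packed column-major over
#' the fully sampled dimensions; vertexes follow file order.
#'
#' @param values Numeric or complex vector of sampled values, length
#'   `nrow(vertexes) * prod(counts[full dims])`.
#' @param sparse_dims 0-based indexes of the sparsely sampled dimensions.
#' @param vertexes Vertex matrix (one row per sparse-grid vertex).
#' @param counts Full grid shape.
#' @param fill Value for unsampled positions (default 0).
#' @return List with `values` (length `prod(counts)`, column-major over the
#'   full grid) and `mask` (logical, `TRUE` where a sample was placed).
#' @export
scatter_sparse <- function(values, sparse_dims, vertexes, counts, fill = 0) {
  offs <- .sparse_offsets(sparse_dims, vertexes, counts)
  if (length(values) != length(offs))
    stop("sample-count mismatch: got ", length(values), " values, layout ",
         "requires ", length(offs), call. = FALSE)
  M <- grid_size(counts)
  full <- rep(if (is.complex(values)) as.complex(fill) else fill, M)
  mask <- rep(FALSE, M)
  full[offs + 1L] <- values
  mask[offs + 1L] <- TRUE
  list(values = full, mask = mask)
}

#' Gather sparse component values from the full grid
#'
#' Inverse of [scatter_sparse()]: extracts the sampled values in storage
#' order.
#'
#' @inheritParams scatter_sparse
#' @param full Vector of length `prod(counts)`.
#' @return Vector of sampled values.
#' @export
gather_sparse <- function(full, sparse_dims, vertexes, counts) {
  offs <- .sparse_offsets(sparse_dims, vertexes, counts)
  stopifnot(length(full) == grid_size(counts))
  full[offs + 1L]
}
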