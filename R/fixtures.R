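# Deterministic miniature example datasets covering each serialization
# pattern, plus metadata skeletons of the canonical published examples.
#
# The synthetic content is seeded pseudo-random (decaying complex
# exponentials for the NMR-like patterns); its values are irrelevant to
# format behaviour, but determinism is not — every numeral regenerates
# identically for a fixed seed.

.fixture_patterns <- c("gmsl_like", "decay_like", "sparse_1d", "sparse_2d",
                       "image_2d", "tensor_3d", "vector_3d",
                       "correlated_2d", "no_dim_0d", "monotonic_2d")

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

.decay_signal <- function(n, rate = 20) {
  t <- seq(0, 1, length.out = n)
  amp <- stats::runif(1, 50, 150)
  f <- stats::runif(1, 2, 8)
  sig <- amp * exp(-rate * t / 4) * exp(2i * pi * f * t) +
    complex(real = stats::rnorm(n, sd = 0.5),
            imaginary = stats::rnorm(n, sd = 0.5))
  # snap to float32 so base64 round trips are bit-exact
  decode_component(encode_component(sig, "raw", "complex64"), "complex64",
                   "raw")$values
}

.f32 <- function(x)
  decode_component(encode_component(x, "raw", "float32"), "float32",
                   "raw")$values

#' Build one synthetic fixture dataset in memory
#'
#' Each pattern exercises one serialization feature: linear axes,
#' complex signals with reciprocal metadata, sparse sampling in one and two
#' dimensions, pixel images, symmetric tensors, external vector data with a
#' labeled axis, correlated dependent variables, 0-dimensional datasets,
#' and monotonic axes.
#'
#' @param pattern One of `"gmsl_like"`, `"decay_like"`, `"sparse_1d"`,
#'   `"sparse_2d"`, `"image_2d"`, `"tensor_3d"`, `"vector_3d"`,
#'   `"correlated_2d"`, `"no_dim_0d"`, `"monotonic_2d"`.
#' @param seed Integer seed; the generated numerals are a pure function of
#'   `(pattern, sizes, seed)`.
#' @param sizes Optional integer vector overriding the pattern's default
#'   grid counts.
#' @return A `csdm` object that validates strictly.
#' @export
fixture_csdm <- function(pattern, seed = 42L, sizes = NULL) {
  pattern <- match.arg(pattern, .fixture_patterns)
  .with_seed(seed, switch(pattern,
    gmsl_like = {
      n <- (sizes %||% 16L)[1]
      csdm(
        dimensions = list(linear_dimension(
          n, "0.08333 yr", coordinates_offset = "1880.0417 yr",
          quantity_name = "time", label = "time")),
        dependent_variables = list(dependent_variable(
          "internal", "scalar", "float32",
          components = list(.f32(cumsum(stats::rnorm(n)))),
          unit = "mm", name = "Synthetic sea level",
          component_labels = "GMSL")),
        tags = c("sea level", "synthetic"),
        description = "Synthetic stand-in for a global mean sea level record")
    },
    decay_like = {
      n <- (sizes %||% 32L)[1]
      csdm(
        dimensions = list(linear_dimension(
          n, "0.1 ms", coordinates_offset = "-0.3 ms",
          quantity_name = "time",
          reciprocal = reciprocal_dimension(
            coordinates_offset = "-3005.363 Hz", origin_offset = "75.43 MHz",
            quantity_name = "frequency"))),
        dependent_variables = list(dependent_variable(
          "internal", "scalar", "complex64",
          components = list(.decay_signal(n)), encoding = "base64",
          name = "Synthetic free induction decay")),
        description = "Synthetic NMR decay with reciprocal metadata")
    },
    sparse_1d = {
      n <- (sizes %||% 12L)[1]
      verts <- sort(sample(0:(n - 1L), max(3L, n %/% 3L)))
      csdm(
        dimensions = list(linear_dimension(n, "1 s")),
        dependent_variables = list(dependent_variable(
          "internal", "scalar", "float64",
          components = list(round(stats::rnorm(length(verts)), 6)),
          sparse_sampling = sparse_sampling(0L, verts,
                                            unsigned_integer_type = "uint8"))))
    },
    sparse_2d = {
      sz <- sizes %||% c(6L, 8L)
      nv <- 4L
      verts <- cbind(sample(0:(sz[1] - 1L), nv),
                     sample(0:(sz[2] - 1L), nv))
      csdm(
        dimensions = list(linear_dimension(sz[1], "50 µs"),
                          linear_dimension(sz[2], "80 µs")),
        dependent_variables = list(dependent_variable(
          "internal", "scalar", "complex64",
          components = list(.decay_signal(nv)), encoding = "base64",
          sparse_sampling = sparse_sampling(
            c(0L, 1L), verts, unsigned_integer_type = "uint16"))))
    },
    image_2d = {
      sz <- sizes %||% c(8L, 6L)
      m <- prod(sz)
      csdm(
        dimensions = list(linear_dimension(sz[1], "1 µm"),
                          linear_dimension(sz[2], "1 µm")),
        dependent_variables = list(dependent_variable(
          "internal", "pixel_3", "uint8",
          components = lapply(1:3, function(q) sample(0:255, m,
                                                      replace = TRUE)),
          encoding = "base64",
          component_labels = c("red", "green", "blue"),
          name = "Synthetic RGB image")))
    },
    tensor_3d = {
      sz <- sizes %||% c(4L, 3L, 2L)
      m <- prod(sz)
      csdm(
        dimensions = lapply(sz, function(n)
          linear_dimension(n, "1 mm", quantity_name = "length")),
        dependent_variables = list(dependent_variable(
          "internal", "symmetric_matrix_3", "float32",
          components = lapply(1:6, function(q) .f32(stats::rnorm(m))),
          encoding = "base64", unit = "mm^2/s",
          component_labels = c("Dxx", "Dxy", "Dxz", "Dyy", "Dyz", "Dzz"),
          name = "Synthetic diffusion tensor")))
    },
    vector_3d = {
      sz <- sizes %||% c(5L, 4L, 3L)
      m <- prod(sz)
      csdm(
        dimensions = list(
          linear_dimension(sz[1], "0.5 °", coordinates_offset = "-102.5 °",
                           label = "longitude"),
          linear_dimension(sz[2], "0.5 °", coordinates_offset = "13.5 °",
                           label = "latitude"),
          labeled_dimension(sprintf("2019-09-%02dT12:00:00Z",
                                    seq_len(sz[3])))),
        dependent_variables = list(dependent_variable(
          "external", "vector_2", "float32",
          components = lapply(1:2, function(q) .f32(stats::rnorm(m))),
          components_url = "file:./wind/components.bin", unit = "m/s",
          component_labels = c("eastward_wind", "northward_wind"),
          name = "Synthetic wind velocity")))
    },
    correlated_2d = {
      sz <- sizes %||% c(6L, 5L)
      m <- prod(sz)
      dv <- function(name, p, unit, q_type) dependent_variable(
        "internal", q_type, "float32",
        components = lapply(seq_len(p), function(q) .f32(stats::rnorm(m))),
        encoding = "base64", unit = unit, name = name)
      csdm(
        dimensions = list(
          linear_dimension(sz[1], "2.5 °", coordinates_offset = "-130 °",
                           label = "longitude"),
          linear_dimension(sz[2], "2.5 °", coordinates_offset = "5 °",
                           label = "latitude")),
        dependent_variables = list(
          dv("surface temperature", 1L, "K", "scalar"),
          dv("air temperature at 2 m", 1L, "K", "scalar"),
          dv("wind velocity", 2L, "m/s", "vector_2"),
          dv("relative humidity", 1L, "%", "scalar"),
          dv("air pressure at sea level", 1L, "Pa", "scalar")))
    },
    no_dim_0d = {
      csdm(
        dimensions = list(),
        dependent_variables = list(
          dependent_variable("internal", "scalar", "float32",
                             components = list(.f32(stats::rnorm(1))),
                             unit = "Hz", name = "coupling constant"),
          dependent_variable("internal", "scalar", "float32",
                             components = list(.f32(stats::runif(1))),
                             name = "s-character product")),
        description = "0-dimensional correlated pair (single sample)")
    },
    monotonic_2d = {
      n2 <- (sizes %||% c(8L, 5L))[1]
      delays <- c("1 s", "5 s", "10 s", "30 s", "100 s")
      csdm(
        dimensions = list(
          linear_dimension(n2, "80 µs", coordinates_offset = "-41.04 ms",
                           label = "t2"),
          monotonic_dimension(delays, label = "t1",
                              quantity_name = "time")),
        dependent_variables = list(dependent_variable(
          "internal", "scalar", "complex64",
          components = list(.decay_signal(n2 * length(delays))),
          encoding = "base64")),
        application = list("com.example.csdmr" = list(
          focus = list(dimension = 0L),
          dimension_precedence = list(1L, 0L))))
    }))
}

#' Generate fixture files on disk
#'
#' Writes each requested pattern (all ten by default) into `dir`, producing
#' `.csdf`/`.csdfe` files plus binary sidecars where the pattern uses
#' external storage. Output is deterministic for a fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param patterns Character vector of pattern names.
#' @param seed Integer seed.
#' @return Invisibly, the paths written.
#' @export
generate_fixtures <- function(dir, patterns = .fixture_patterns,
                              seed = 42L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (p in patterns) {
    x <- fixture_csdm(p, seed = seed)
    ext <- if (.has_external(x)) ".csdfe" else ".csdf"
    path <- file.path(dir, paste0(p, ext))
    write_csdm(x, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Metadata skeletons of the canonical published example datasets
#'
#' Reconstructs, at full printed size, the attribute skeletons of the
#' standard example datasets: the global mean sea level record (1608 monthly
#' samples from 1880.0417 yr), a 13C Bloch-decay NMR signal (4096 points
#' every 0.1 ms from -0.3 ms), a 29Si saturation-recovery experiment (t2:
#' 1024 points every 80 µs from -41.04 ms; t1 monotonic), a TEM image (512
#' x 512 at 4 nm), an RGB image (1024 x 768 pixel_3), a wind-velocity
#' vector field (49 x 49 at 0.5° from -102.5° longitude / 13.5° latitude,
#' six date-time labels), and a diffusion-tensor brain MRI (148 x 190 x 160
#' at 1 mm, symmetric_matrix_3). Data arrays are synthetic stand-ins where
#' the source prints attribute values only; external datasets (wind
#' velocity) carry an unresolved components_url.
#'
#' @param which Names to build (default all): `"GMSL"`, `"blochDecay"`,
#'   `"satRec"`, `"TEM"`, `"RGB_image"`, `"wind_velocity"`, `"brain_MRI"`.
#' @param seed Seed for the synthetic payloads.
#' @return Named list of `csdm` objects.
#' @export
published_examples <- function(which = NULL, seed = 7L) {
  builders <- list(
    GMSL = function() csdm(
      dimensions = list(linear_dimension(
        1608L, "0.08333 yr", coordinates_offset = "1880.0417 yr",
        quantity_name = "time")),
      dependent_variables = list(dependent_variable(
        "internal", "scalar", "float32",
        components = list(.f32(cumsum(stats::rnorm(1608)))),
        unit = "mm", component_labels = "GMSL",
        name = "Global Mean Sea Level")),
      description = "Global mean sea level record (synthetic data values)"),
    blochDecay = function() csdm(
      dimensions = list(linear_dimension(
        4096L, "0.1 ms", coordinates_offset = "-0.3 ms",
        quantity_name = "time",
        reciprocal = reciprocal_dimension(
          origin_offset = "75.43 MHz", quantity_name = "frequency"))),
      dependent_variables = list(dependent_variable(
        "internal", "scalar", "complex64",
        components = list(.decay_signal(4096)), encoding = "base64",
        name = "13C Bloch decay (synthetic data values)"))),
    satRec = function() {
      delays <- c("0.1 s", "0.5 s", "1 s", "2 s", "5 s", "10 s", "20 s",
                  "40 s", "80 s", "160 s")
      csdm(
        dimensions = list(
          linear_dimension(1024L, "80 µs",
                           coordinates_offset = "-41.04 ms", label = "t2",
                           quantity_name = "time",
                           reciprocal = reciprocal_dimension(
                             quantity_name = "frequency")),
          monotonic_dimension(delays, label = "t1",
                              quantity_name = "time")),
        dependent_variables = list(dependent_variable(
          "internal", "scalar", "complex64",
          components = list(.decay_signal(1024L * length(delays))),
          encoding = "base64",
          name = "29Si saturation recovery (synthetic data values)")))
    },
    TEM = function() csdm(
      dimensions = list(
        linear_dimension(512L, "4 nm", quantity_name = "length"),
        linear_dimension(512L, "4 nm", quantity_name = "length")),
      dependent_variables = list(dependent_variable(
        "internal", "scalar", "uint8",
        components = list(sample(0:255, 512L * 512L, replace = TRUE)),
        encoding = "base64", name = "TEM image (synthetic data values)"))),
    RGB_image = function() csdm(
      dimensions = list(linear_dimension(1024L, "1"),
                        linear_dimension(768L, "1")),
      dependent_variables = list(dependent_variable(
        "internal", "pixel_3", "uint8",
        components = lapply(1:3, function(q)
          sample(0:255, 1024L * 768L, replace = TRUE)),
        encoding = "base64",
        component_labels = c("red", "green", "blue"),
        name = "RGB image (synthetic data values)"))),
    wind_velocity = function() csdm(
      dimensions = list(
        linear_dimension(49L, "0.5 °", coordinates_offset = "-102.5 °",
                         label = "longitude"),
        linear_dimension(49L, "0.5 °", coordinates_offset = "13.5 °",
                         label = "latitude"),
        labeled_dimension(sprintf("2019-09-%02dT%02d:00:00Z",
                                  rep(17:19, each = 2), rep(c(0, 12), 3)))),
      dependent_variables = list(dependent_variable(
        "external", "vector_2", "float32",
        components_url = "file:./wind_velocity/components.bin",
        unit = "m/s",
        component_labels = c("ugrd10m-eastward_wind",
                             "vgrd10m-northward_wind"),
        name = "wind velocity"))),
    brain_MRI = function() csdm(
      dimensions = lapply(c(148L, 190L, 160L), function(n)
        linear_dimension(n, "1 mm", quantity_name = "length")),
      dependent_variables = list(dependent_variable(
        "internal", "symmetric_matrix_3", "float32",
        components = lapply(1:6, function(q)
          .f32(stats::rnorm(148L * 190L * 160L, sd = 1e-4))),
        encoding = "base64", unit = "mm^2/s",
        component_labels = c("Dxx", "Dxy", "Dxz", "Dyy", "Dyz", "Dzz"),
        name = "Diffusion tensor MRI (synthetic data values)"))))
  which <- which %||% names(builders)
  stopifnot(all(which %in% names(builders)))
  .with_seed(seed, {
    out <- lapply(which, function(nm) builders[[nm]]())
    names(out) <- which
    out
  })
}
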