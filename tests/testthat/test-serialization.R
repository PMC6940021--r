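test_that("reading applies defaults and reports missing requirements", {
  txt <- '
  {"csdm": {
    "version": "1.0",
    "timestamp": "2019-10-21T13:43:00Z",
    "tags": ["sea level"],
    "description": "example",
    "dimensions": [{
      "type": "linear", "count": 5, "increment": "0.08333 yr",
      "coordinates_offset": "1880.0417 yr"
    }],
    "dependent_variables": [{
      "type": "internal", "quantity_type": "scalar",
      "numeric_type": "float32", "unit": "mm",
      "components": [[1.5, 2.5, 3.5, 4.5, 5.5]]
    }]
  }}'
  x <- read_csdm(txt)
  expect_s3_class(x, "csdm")
  expect_equal(x$version, "1.0")
  expect_equal(x$tags, "sea level")
  expect_length(x$dimensions, 1)
  expect_length(x$dependent_variables, 1)
  dim <- x$dimensions[[1]]
  expect_equal(dim$count, 5L)
  # absent booleans are false, absent offsets are zero-defaults
  expect_false(dim$complex_fft)
  expect_null(dim$origin_offset)
  expect_false(x$read_only)
  expect_equal(x$dependent_variables[[1]][["components"]][[1]],
               c(1.5, 2.5, 3.5, 4.5, 5.5))
  expect_equal(nrow(csdm_validate(x)), 0L)

  expect_error(read_csdm('{"csdm": {"version": "1.0",
    "dimensions": [{"count": 3}], "dependent_variables": []}}'),
    "dimensions\\[0\\]")
  expect_error(read_csdm('{"notcsdm": {}}'), "csdm")
  expect_error(read_csdm('[{"csdm": {}}]'), "array|object")
  expect_error(read_csdm("not json at all {"), "JSON")
})

test_that("unsupported versions error in strict mode, warn in lenient", {
  txt <- '{"csdm": {"version": "1.1", "dependent_variables": []}}'
  expect_error(read_csdm(txt, "strict"), "version")
  expect_warning(x <- read_csdm(txt, "lenient"), "version")
  expect_equal(x$version, "1.1")
})

test_that("default-valued optional keys are omitted and booleans appear
           only when true", {
  x <- csdm(
    dimensions = list(linear_dimension(4, "1 Hz")),
    dependent_variables = list(
      dependent_variable("internal", "scalar", "float64",
                         components = list(c(1, 2, 3, 4)))))
  txt <- csdm_to_json(x)
  expect_false(grepl("complex_fft", txt))
  expect_false(grepl("origin_offset", txt))
  expect_false(grepl("coordinates_offset", txt))
  expect_false(grepl("period", txt))
  expect_false(grepl("read_only", txt))
  expect_false(grepl("encoding", txt))
  expect_false(grepl("\"unit\"", txt))

  y <- csdm(dimensions = list(
    linear_dimension(4, "1 Hz", complex_fft = TRUE)),
    dependent_variables = x$dependent_variables, read_only = TRUE)
  ty <- csdm_to_json(y)
  expect_match(ty, "\"complex_fft\": true")
  expect_match(ty, "\"read_only\": true")
})

test_that("file extension must match the storage subtype", {
  internal <- fixture_csdm("gmsl_like")
  external <- fixture_csdm("vector_3d")
  td <- withr::local_tempdir()
  expect_error(write_csdm(external, file.path(td, "x.csdf")), "csdfe")
  expect_error(write_csdm(internal, file.path(td, "x.csdfe")), "csdf")
  expect_silent(write_csdm(internal, file.path(td, "x.csdf")))
  expect_silent(write_csdm(external, file.path(td, "x.csdfe")))
  expect_true(file.exists(file.path(td, "wind", "components.bin")))
})

test_that("every fixture survives read(write(x)) with byte-stable
           rewrites", {
  td <- withr::local_tempdir()
  paths <- generate_fixtures(td, all_fixture_patterns, seed = 42)
  for (pth in paths) {
    x <- csdm_load_components(read_csdm(pth))
    expect_equal(sum(csdm_validate(x)$severity == "error"), 0L,
                 info = basename(pth))
    out <- file.path(td, paste0("rw_", basename(pth)))
    write_csdm(x, out)
    expect_identical(readLines(out), readLines(pth), info = basename(pth))
    y <- csdm_load_components(read_csdm(out))
    expect_equal(strip_source(y), strip_source(x), info = basename(pth))
    # writing twice is byte-identical
    out2 <- file.path(td, paste0("rw2_", basename(pth)))
    write_csdm(y, out2)
    expect_identical(readLines(out2), readLines(out))
  }
})

test_that("foreign application blocks survive a read/write cycle intact", {
  app <- list("com.example.otherapp" = list(
    focus = list(index = 42L, window = "main"),
    pipeline = list("fft", "phase", list(step = "baseline", order = 3L))))
  x <- fixture_csdm("gmsl_like")
  x$application <- app
  x$dimensions[[1]]$application <- list("org.lab.acquire" = list(rg = 101L))
  td <- withr::local_tempdir()
  p1 <- file.path(td, "app.csdf")
  write_csdm(x, p1)
  y <- read_csdm(p1)
  expect_identical(y$application, app)
  expect_identical(y$dimensions[[1]]$application,
                   list("org.lab.acquire" = list(rg = 101L)))
  p2 <- file.path(td, "app2.csdf")
  write_csdm(y, p2)
  expect_identical(readLines(p2), readLines(p1))
})

test_that("unknown keys are preserved verbatim across read/write", {
  txt <- '{"csdm": {"version": "1.0",
    "future_key": {"a": [1, 2], "b": "x"},
    "dimensions": [{"type": "linear", "count": 2, "increment": "1 s",
                    "novel": true}],
    "dependent_variables": [{"type": "internal",
      "quantity_type": "scalar", "numeric_type": "float64",
      "components": [[1.0, 2.0]]}]}}'
  x <- read_csdm(txt)
  expect_equal(x$extra$future_key$b, "x")
  out <- csdm_to_json(x)
  expect_match(out, "future_key")
  expect_match(out, "\"novel\": true")
  y <- read_csdm(out)
  expect_identical(strip_source(y), strip_source(x))
})

test_that("components_url resolution is confined to the dataset folder", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "wind"))
  writeBin(as.raw(1:8), file.path(td, "wind", "data.bin"))
  expect_equal(resolve_components_url("file:./wind/data.bin", td),
               normalizePath(file.path(td, "wind", "data.bin")))
  expect_error(resolve_components_url("file:../../etc/x", td),
               "relative|escapes")
  expect_error(resolve_components_url("file:./a/../../x.bin", td),
               "escapes")
  expect_error(resolve_components_url("file:/abs/path.bin", td),
               "relative")
  expect_error(resolve_components_url("file:./missing.bin", td),
               "not found")
  expect_error(resolve_components_url("https://example.org/x.bin", td),
               "network")
  expect_error(resolve_components_url("ftp://example.org/x.bin", td),
               "scheme")
})

test_that("internalize/externalize preserve decoded numerals exactly", {
  td <- withr::local_tempdir()
  generate_fixtures(td, "vector_3d", seed = 9)
  x <- csdm_load_components(read_csdm(file.path(td, "vector_3d.csdfe")))
  ext_dv <- x$dependent_variables[[1]]
  int_dv <- internalize(ext_dv)
  expect_equal(int_dv$type, "internal")
  expect_null(int_dv$components_url)
  expect_identical(int_dv[["components"]], ext_dv[["components"]])

  # external binary layout: p component blocks, column-major samples each
  bytes <- readBin(file.path(td, "wind", "components.bin"), raw(),
                   n = file.info(file.path(td, "wind",
                                           "components.bin"))$size)
  M <- prod(csdm_shape(x))
  vals <- readBin(bytes, "double", size = 4, n = 2 * M, endian = "little")
  expect_equal(vals[1:M], ext_dv[["components"]][[1]])
  expect_equal(vals[(M + 1):(2 * M)], ext_dv[["components"]][[2]])

  back <- externalize(int_dv, "file:./wind/components.bin")
  expect_equal(back$type, "external")
  expect_identical(back[["components"]], ext_dv[["components"]])

  # writing the internalized variant produces a .csdf dataset
  x$dependent_variables[[1]] <- int_dv
  p <- file.path(td, "internalized.csdf")
  write_csdm(x, p)
  y <- read_csdm(p)
  expect_equal(y$dependent_variables[[1]][["components"]],
               ext_dv[["components"]])

  # unresolved external data cannot be internalized
  dv_lazy <- dependent_variable("external", "scalar", "float32",
                                components_url = "file:./nope.bin")
  expect_error(internalize(dv_lazy), "not loaded")
})

test_that("read_only datasets refuse in-place overwrite", {
  td <- withr::local_tempdir()
  x <- fixture_csdm("gmsl_like")
  x$read_only <- TRUE
  p <- file.path(td, "archived.csdf")
  write_csdm(x, p)
  y <- read_csdm(p)
  expect_error(write_csdm(y, p), "read_only")
  expect_silent(write_csdm(y, file.path(td, "copy.csdf")))
})

test_that("non-finite float components fall back to base64 storage", {
  x <- csdm(
    dimensions = list(linear_dimension(3, "1 s")),
    dependent_variables = list(
      dependent_variable("internal", "scalar", "float64",
                         components = list(c(1, NaN, Inf)))))
  expect_message(txt <- csdm_to_json(x), "base64")
  expect_match(txt, "\"encoding\": \"base64\"")
  y <- read_csdm(txt)
  expect_identical(y$dependent_variables[[1]][["components"]][[1]],
                   c(1, NaN, Inf))
})

test_that("sparse vertex arrays can themselves be base64-encoded", {
  x <- fixture_csdm("sparse_2d")
  x$dependent_variables[[1]]$sparse_sampling$encoding <- "base64"
  td <- withr::local_tempdir()
  p <- file.path(td, "sp.csdf")
  write_csdm(x, p)
  txt <- paste(readLines(p), collapse = "\n")
  expect_match(txt, "\"sparse_grid_vertexes\": \"")
  y <- read_csdm(p)
  expect_identical(y$dependent_variables[[1]]$sparse_sampling$sparse_grid_vertexes,
                   x$dependent_variables[[1]]$sparse_sampling$sparse_grid_vertexes)
})
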