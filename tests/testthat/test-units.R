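test_that("unit parsing composes scale and dimensions per the grammar", {
  u <- parse_unit("m/s")
  expect_equal(unname(u$dims[c("length", "time")]), c(1, -1))
  expect_equal(u$scale, 1)

  u <- parse_unit("kg*m^2/s^2")
  expect_equal(unname(u$dims[c("mass", "length", "time")]), c(1, 2, -2))
  expect_equal(u$scale, 1)

  # J expands to kg m^2 s^-2, so J/(mol*K) has energy per amount-temperature
  u <- parse_unit("J/(mol*K)")
  expect_equal(unname(u$dims), c(2, 1, -2, 0, -1, -1, 0))

  # parentheses override left-to-right division
  expect_equal(unname(parse_unit("J/mol*K")$dims),
               c(2, 1, -2, 0, 1, -1, 0))

  # empty string is the dimensionless unit
  u <- parse_unit("")
  expect_equal(unname(u$dims), rep(0, 7))
  expect_equal(u$scale, 1)
})

test_that("compound symbols without operators and unknown symbols fail", {
  expect_error(parse_unit("kWh"), "unknown unit symbol")
  expect_error(parse_unit("N m"), "unexpected token")
  expect_error(parse_unit("furlong"), "unknown unit symbol")
  expect_error(parse_unit("m^"), "exponent")
  expect_error(parse_unit("m^0.5"), "integer")
})

test_that("SI prefixes multiply the base symbol scale", {
  expect_equal(parse_unit("km")$scale, 1e3)
  expect_equal(parse_unit("nm")$scale, 1e-9)
  expect_equal(parse_unit("kg")$scale, 1)      # k * g = 1e3 * 1e-3
  expect_equal(parse_unit("MHz")$scale, 1e6)
  expect_equal(parse_unit("hPa")$scale, 1e2)   # exact 'h' is hour, hPa wins
  # both micro glyphs and the ascii fallback resolve identically
  expect_equal(parse_unit("µs")$scale, parse_unit("μs")$scale)
  expect_equal(parse_unit("us")$scale, 1e-6)
  # exact symbols beat prefix splitting
  expect_equal(unname(parse_unit("min")$dims[3]), 1)
  expect_equal(parse_unit("min")$scale, 60)
  expect_equal(unname(parse_unit("cd")$dims[7]), 1)
})

test_that("scalar quantities parse and format as '<number> <unit>'", {
  q <- parse_scalar_quantity("3.4 m")
  expect_equal(q$value, 3.4)
  expect_equal(q$unit$symbol, "m")
  expect_equal(format_scalar_quantity(q), "3.4 m")

  q <- parse_scalar_quantity("2.3 bar")
  expect_equal(q$value, 2.3)
  expect_equal(q$unit$scale, 1e5)
  expect_equal(unname(q$unit$dims[1:3]), c(-1, 1, -2))

  q <- parse_scalar_quantity("0.08333 yr")
  expect_equal(q$value, 0.08333)
  expect_equal(unname(q$unit$dims[3]), 1)

  expect_equal(format_scalar_quantity(scalar_quantity(0, "mm")), "0.0 mm")
  # the infinite-period sentinel formats for display only
  expect_equal(format_scalar_quantity(scalar_quantity(Inf, "Hz")),
               "∞ Hz")
  expect_error(parse_scalar_quantity("abc m"), "malformed number")
})

test_that("dimensionality comparison groups equivalent units", {
  expect_true(same_dimensionality("Hz", "1/s"))
  expect_true(same_dimensionality("Hz", "Bq"))
  expect_true(same_dimensionality("Bq", "1/s"))
  expect_true(same_dimensionality("m", "m"))
  expect_false(same_dimensionality("m", "s"))
  # angles are dimensionless by convention, comparable to pure numbers
  expect_true(same_dimensionality("°", ""))
  expect_true(same_dimensionality("deg", "rad"))
})

test_that("conversion rescales values and round-trips", {
  expect_equal(convert_quantity(parse_scalar_quantity("80 µs"),
                                "ms")$value, 0.08)
  expect_equal(convert_quantity(parse_scalar_quantity("1 m"), "m")$value, 1)
  expect_equal(convert_quantity(parse_scalar_quantity("2.3 bar"),
                                "Pa")$value, 230000, tolerance = 1e-12)
  q <- parse_scalar_quantity("123.456 km")
  back <- convert_quantity(convert_quantity(q, "mm"), "km")
  expect_equal(back$value, q$value, tolerance = 1e-12)
  expect_error(convert_quantity(parse_scalar_quantity("1 m"), "s"),
               "dimensionality mismatch")
})

test_that("affine temperature units convert by kelvin offset only", {
  expect_equal(convert_quantity(parse_scalar_quantity("0 degC"),
                                "K")$value, 273.15)
  expect_equal(convert_quantity(parse_scalar_quantity("212 degF"),
                                "degC")$value, 100, tolerance = 1e-12)
  expect_error(parse_unit("degC/s"), "affine")
})

test_that("parse-format-parse is idempotent on random unit expressions", {
  set.seed(101)
  for (i in 1:1000) {
    spec <- random_unit_expression(sample(1:4, 1))
    u1 <- parse_unit(spec$expr)
    u2 <- parse_unit(u1$symbol)
    expect_identical(u1$scale, u2$scale)
    expect_identical(u1$dims, u2$dims)
  }
})

test_that("composed dimensions match an independent left-to-right expander", {
  set.seed(202)
  for (i in 1:300) {
    spec <- random_unit_expression(sample(2:4, 1))
    u <- parse_unit(spec$expr)
    expect_equal(unname(u$dims), spec$dims, info = spec$expr)
    expect_equal(u$scale, spec$scale, tolerance = 1e-12, info = spec$expr)
  }
})
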