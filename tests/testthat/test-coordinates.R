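test_that("linear coordinates evaluate increment*(j - Z) + offset", {
  d <- linear_dimension(4096, "0.1 ms", coordinates_offset = "-0.3 ms")
  cc <- linear_coordinates(d)
  expect_equal(length(cc$values), 4096L)
  expect_equal(cc$values[1], -0.3)
  expect_equal(cc$values[4], 0.0)
  expect_equal(cc$values[4096], 409.2)
  expect_equal(cc$unit$symbol, "ms")

  # offsets convert into the increment's unit
  d <- linear_dimension(1024, "80 µs", coordinates_offset = "-41.04 ms")
  cc <- linear_coordinates(d)
  expect_equal(cc$unit$symbol, "µs")
  expect_equal(convert_quantity(scalar_quantity(cc$values[1], cc$unit),
                                "ms")$value, -41.04)

  # single-vertex dimension
  d <- linear_dimension(1, "1 m", coordinates_offset = "5 m")
  expect_equal(linear_coordinates(d)$values, 5)

  expect_error(linear_coordinates(
    linear_dimension(4, "0.1 ms", coordinates_offset = "2 m")),
    "dimensionality")
})

test_that("complex_fft centers the axis so coordinate[Z] equals the
           offset", {
  d <- linear_dimension(8, "100 Hz", coordinates_offset = "0 Hz",
                        complex_fft = TRUE)
  cc <- linear_coordinates(d)
  expect_equal(cc$values, seq(-400, 300, by = 100))
  expect_identical(cc$values[4 + 1], 0)   # Z = 8/2 = 4

  set.seed(55)
  for (i in 1:40) {
    N <- sample(2:512, 1)
    b <- round(rnorm(1), 3)
    d <- linear_dimension(N, "1 Hz",
                          coordinates_offset = sprintf("%g Hz", b),
                          complex_fft = TRUE)
    T_ <- if (N %% 2 == 0) N else N - 1
    Z <- T_ / 2
    expect_identical(linear_coordinates(d)$values[Z + 1], b)
  }
})

test_that("linear coordinates have constant spacing equal to the
           increment", {
  set.seed(66)
  for (i in 1:500) {
    N <- sample(2:10000, 1)
    dx <- rnorm(1)
    while (dx == 0) dx <- rnorm(1)
    b <- rnorm(1)
    d <- linear_dimension(N, scalar_quantity(dx, "s"),
                          coordinates_offset = scalar_quantity(b, "s"))
    v <- linear_coordinates(d)$values
    steps <- diff(v)
    # each endpoint carries at most one ulp of the operand magnitudes
    # |dx * j| + |b| (cancellation can make |v| itself much smaller)
    mag <- abs(dx) * (2:N) + abs(b)
    tol <- 4 * .Machine$double.eps * pmax(mag, abs(dx))
    expect_true(all(abs(steps - dx) <= tol))
  }
})

test_that("monotonic coordinates convert to the first entry's unit", {
  d <- monotonic_dimension(c("1 s", "10 s", "100 s"))
  cc <- monotonic_coordinates(d)
  expect_equal(cc$values, c(1, 10, 100))
  expect_equal(cc$unit$symbol, "s")

  # descending is legal
  d <- monotonic_dimension(c("5 K", "3 K", "1 K"))
  expect_equal(monotonic_coordinates(d)$values, c(5, 3, 1))
  expect_equal(nrow(csdm_validate(csdm(dimensions = list(d)))), 0L)

  # mixed units convert; 0.08 ms duplicates 80 µs and is rejected
  d <- monotonic_dimension(c("0.08 ms", "80 µs", "1 ms"))
  diags <- csdm_validate(csdm(dimensions = list(d)))
  expect_equal(sum(diags$severity == "error"), 1L)
  expect_match(diags$message[1], "unique|duplicate")
})

test_that("labeled coordinates are the label strings themselves", {
  stamps <- sprintf("2019-09-%02dT12:00:00Z", 1:6)
  d <- labeled_dimension(stamps)
  cc <- labeled_coordinates(d)
  expect_identical(cc$values, stamps)
  expect_null(cc$unit)
  expect_identical(labeled_coordinates(labeled_dimension("a"))$values, "a")
  diags <- csdm_validate(csdm(dimensions = list(
    labeled_dimension(c("a", "a")))))
  expect_equal(sum(diags$severity == "error"), 1L)
})

test_that("absolute coordinates add the origin offset after unit
           conversion", {
  cc <- linear_coordinates(linear_dimension(3, "1 Hz"))
  abs_cc <- absolute_coordinates(cc, "400 MHz")
  expect_equal(abs_cc$values, c(4e8, 4e8 + 1, 4e8 + 2))

  # zero origin offset leaves coordinates unchanged
  expect_equal(absolute_coordinates(cc, "0 Hz")$values, cc$values)

  # subtracting the offset restores the input exactly
  back <- absolute_coordinates(abs_cc, "-400 MHz")
  expect_identical(back$values, cc$values)

  cc_mm <- linear_coordinates(linear_dimension(3, "1 mm"))
  expect_error(absolute_coordinates(cc_mm, "1 s"), "dimensionality")
  expect_error(absolute_coordinates(
    labeled_coordinates(labeled_dimension("a")), "1 s"), "labeled")
})

test_that("ratio coordinates divide by (origin - coordinates) offset", {
  cc <- structure(list(values = 100, unit = parse_unit("Hz"),
                       kind = "linear"), class = "csd_coordinates")
  r <- ratio_coordinates(cc, "400 MHz", "0 Hz")
  expect_equal(r$values, 2.5e-7)
  expect_equal(ratio_coordinates(cc, "400 MHz", "0 Hz", ppm = TRUE)$values,
               0.25)
  cc0 <- structure(list(values = 0, unit = parse_unit("Hz"),
                        kind = "linear"), class = "csd_coordinates")
  expect_equal(ratio_coordinates(cc0, "400 MHz", "0 Hz")$values, 0)
  expect_error(ratio_coordinates(cc, "5 Hz", "5 Hz"), "zero denominator")
})
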