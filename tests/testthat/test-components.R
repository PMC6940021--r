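test_that("quantity-type literals imply the component count p", {
  expect_equal(parse_quantity_type("scalar")$p, 1L)
  expect_equal(parse_quantity_type("vector_2")$p, 2L)
  expect_equal(parse_quantity_type("pixel_3")$p, 3L)
  expect_equal(parse_quantity_type("symmetric_matrix_3")$p, 6L)
  qt <- parse_quantity_type("matrix_2_3")
  expect_equal(qt$p, 6L)
  expect_equal(qt$m, 2L)
  expect_equal(qt$n, 3L)
  expect_error(parse_quantity_type("tensor_3"), "unknown quantity_type")
  expect_error(parse_quantity_type("vector_0"), "positive")
  expect_error(parse_quantity_type("vector_x"), "unknown quantity_type")
})

test_that("base64 decodes little-endian IEEE-754 payloads", {
  # 00 00 80 3F is 1.0f little-endian
  comp <- decode_component("AACAPw==", "float32", "base64")
  expect_equal(comp$values, 1)
  expect_equal(comp$samples, 1L)
  expect_equal(encode_component(comp, "base64"), "AACAPw==")

  expect_error(decode_component("AACA Pw==", "float32", "base64"),
               "whitespace")
  expect_equal(decode_component("AACA Pw==", "float32", "base64",
                                strict = FALSE)$values, 1)
  expect_error(decode_component("!!!!", "float32", "base64"), "base64")
  expect_error(decode_component("AAA=", "float32", "base64"),
               "not a multiple")
})

test_that("JSON-number payloads decode with interleaved complex layout", {
  comp <- decode_component(c(-8899.406, -1276.773, -193.923, -67.065),
                           "complex64", "none")
  expect_equal(comp$samples, 2L)
  expect_equal(Re(comp$values[1]), -8899.406, tolerance = 1e-6)
  expect_equal(Im(comp$values[1]), -1276.773, tolerance = 1e-6)
  expect_equal(Im(comp$values[2]), -67.065, tolerance = 1e-6)

  expect_equal(decode_component(numeric(0), "float64", "none")$samples, 0L)
  expect_error(decode_component(c(1, 2, 3), "complex64", "none"), "even")
  expect_error(decode_component(list(1, "a"), "float64", "none"),
               "non-numeric")
  expect_error(decode_component(c(0, 256), "uint8", "none"),
               "out of range")
  expect_error(decode_component(c(0.5), "int16", "none"), "non-integer")
})

test_that("encode/decode are mutually inverse for every numeric type", {
  set.seed(11)
  types <- c("uint8", "uint16", "uint32", "uint64", "int8", "int16",
             "int32", "int64", "float32", "float64", "complex64",
             "complex128")
  for (nt in types) {
    info <- numeric_type_info(nt)
    n <- 1000L
    vals <- if (info$is_complex) {
      v <- complex(real = rnorm(n), imaginary = rnorm(n))
      decode_component(encode_component(v, "raw", nt), nt, "raw")$values
    } else if (info$is_integer) {
      bits <- min(info$bytes_per_numeral * 8, 48)
      lo <- if (info$signed) -2^(bits - 1) else 0
      floor(runif(n, lo, 2^(bits - 1)))
    } else {
      decode_component(encode_component(rnorm(n), "raw", nt), nt,
                       "raw")$values
    }
    for (enc in c("none", "base64", "raw")) {
      back <- decode_component(encode_component(vals, enc, nt), nt, enc)
      expect_identical(back$values, vals,
                       info = paste(nt, enc))
    }
  }
})

test_that("base64 encoding of 3000 bytes costs 4000 characters (75%)", {
  payload <- as.raw(seq_len(3000) %% 256)
  enc <- base64_encode(payload)
  expect_equal(nchar(enc), 4000L)
  expect_identical(base64_decode(enc), payload)
})

test_that("symmetric upper-triangle indexing is a bijection matching the
           packed layout", {
  for (n in 1:6) {
    p <- n * (n + 1) / 2
    # enumerate the upper triangle row by row, as packed in the file
    seen <- integer(0)
    expected <- 0L
    for (r in 0:(n - 1)) for (c in r:(n - 1)) {
      idx <- csdmr:::.sym_index(r, c, n)
      expect_equal(idx, expected)
      seen <- c(seen, idx)
      expected <- expected + 1L
    }
    expect_setequal(seen, 0:(p - 1))
    # mirrored below the diagonal
    for (r in 0:(n - 1)) for (c in 0:(n - 1))
      expect_equal(csdmr:::.sym_index(r, c, n),
                   csdmr:::.sym_index(c, r, n))
  }
  # the worked n = 3 case: entry (1,1) comes from component index 3
  expect_equal(csdmr:::.sym_index(1, 1, 3), 3)
})

test_that("assemble_value reconstructs each quantity-type family", {
  expect_equal(assemble_value("scalar", list(c(7, 8)), 2), 8)
  expect_equal(assemble_value("vector_2", list(1:3, 4:6), 2), c(2, 5))
  expect_equal(assemble_value("pixel_3", list(10, 20, 30), 1),
               c(10, 20, 30))

  # matrix_2_2: entry (r, c) is component c*m + r -> [[U0, U2], [U1, U3]]
  m22 <- assemble_value("matrix_2_2", list(1, 2, 3, 4), 1)
  expect_equal(m22, matrix(c(1, 2, 3, 4), 2, 2))

  # column-major reshape oracle over all m, n <= 4
  set.seed(5)
  for (m in 1:4) for (n in 1:4) {
    p <- m * n
    comps <- lapply(seq_len(p), function(q) rnorm(3))
    i <- sample(1:3, 1)
    got <- assemble_value(sprintf("matrix_%d_%d", m, n), comps, i)
    oracle <- matrix(vapply(comps, `[[`, numeric(1), i), nrow = m,
                     ncol = n)   # column-major fill
    expect_equal(got, oracle)
  }

  sym <- assemble_value("symmetric_matrix_3",
                        as.list(as.numeric(0:5)), 1)
  expect_equal(sym, matrix(c(0, 1, 2,
                             1, 3, 4,
                             2, 4, 5), 3, 3, byrow = TRUE))
  expect_error(assemble_value("vector_2", list(1:3), 1), "components")
  expect_error(assemble_value("scalar", list(1:3), 4), "out of range")
})
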