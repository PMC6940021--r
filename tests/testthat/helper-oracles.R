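# Independent oracles used across the suite.

# Brute-force column-major enumerator: lists every grid vertex with
# dimension 0 varying fastest, by nested looping (recursion over the last
# dimension), independent of the package's stride arithmetic.
brute_force_vertex_list <- function(counts) {
  if (length(counts) == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  inner <- brute_force_vertex_list(counts[-length(counts)])
  last <- counts[length(counts)]
  do.call(rbind, lapply(0:(last - 1L), function(j)
    cbind(inner, j, deparse.level = 0)))
}

# Random unit expression built from registered symbols; the expected scale
# and dimension vector are accumulated independently, term by term, as the
# string is composed left to right.
random_unit_expression <- function(n_terms = 3L) {
  syms <- list(
    m   = list(scale = 1,    dims = c(1, 0, 0, 0, 0, 0, 0)),
    kg  = list(scale = 1,    dims = c(0, 1, 0, 0, 0, 0, 0)),
    s   = list(scale = 1,    dims = c(0, 0, 1, 0, 0, 0, 0)),
    A   = list(scale = 1,    dims = c(0, 0, 0, 1, 0, 0, 0)),
    K   = list(scale = 1,    dims = c(0, 0, 0, 0, 1, 0, 0)),
    mol = list(scale = 1,    dims = c(0, 0, 0, 0, 0, 1, 0)),
    cd  = list(scale = 1,    dims = c(0, 0, 0, 0, 0, 0, 1)),
    Hz  = list(scale = 1,    dims = c(0, 0, -1, 0, 0, 0, 0)),
    N   = list(scale = 1,    dims = c(1, 1, -2, 0, 0, 0, 0)),
    J   = list(scale = 1,    dims = c(2, 1, -2, 0, 0, 0, 0)),
    Pa  = list(scale = 1,    dims = c(-1, 1, -2, 0, 0, 0, 0)),
    bar = list(scale = 1e5,  dims = c(-1, 1, -2, 0, 0, 0, 0)),
    mm  = list(scale = 1e-3, dims = c(1, 0, 0, 0, 0, 0, 0)),
    km  = list(scale = 1e3,  dims = c(1, 0, 0, 0, 0, 0, 0)),
    ms  = list(scale = 1e-3, dims = c(0, 0, 1, 0, 0, 0, 0)),
    MHz = list(scale = 1e6,  dims = c(0, 0, -1, 0, 0, 0, 0)))
  expr <- ""
  scale <- 1
  dims <- rep(0, 7)
  for (t in seq_len(n_terms)) {
    nm <- sample(names(syms), 1L)
    k <- sample(c(-3L:-1L, 1L:3L), 1L)
    term <- if (k == 1L) nm else paste0(nm, "^", k)
    op <- if (t == 1L) "" else sample(c("*", "/"), 1L)
    expr <- paste0(expr, op, term)
    tscale <- syms[[nm]]$scale^k
    tdims <- syms[[nm]]$dims * k
    if (op == "/") {
      scale <- scale / tscale
      dims <- dims - tdims
    } else {
      scale <- scale * tscale
      dims <- dims + tdims
    }
  }
  list(expr = expr, scale = scale, dims = dims)
}

all_fixture_patterns <- c("gmsl_like", "decay_like", "sparse_1d",
                          "sparse_2d", "image_2d", "tensor_3d", "vector_3d",
                          "correlated_2d", "no_dim_0d", "monotonic_2d")

# normalize a csdm object for structural comparison across a file cycle
strip_source <- function(x) {
  attr(x, "source_path") <- NULL
  x
}
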