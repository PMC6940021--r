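# csdmr

An R implementation of the Core Scientific Dataset (CSD) model, version
1.0 — a lightweight, JSON-serialized container for multi-dimensional
scientific datasets, used across NMR and EPR spectroscopy, MRI, mass
spectrometry, astronomy, and microscopy. `csdmr` reads, writes, validates,
and manipulates `.csdf` / `.csdfe` files, for scientists who need a
vendor-neutral interchange and archival format and for developers building
tooling on top of one.

## The model

A dataset is a *p*-component dependent variable {**U**₀, …, **U**₍p−1₎}
sampled at *M* points of a *d*-dimensional orthogonal grid whose axes
(dimensions) are *linear*, *monotonic*, or *labeled*. Along a linear
dimension with count *N*, increment Δx, and coordinates offset *b*, the
coordinates are

    X_j = Δx · (j − Z) + b,   j = 0, …, N − 1,

with Z = 0 normally and Z = T/2 (T = N for even N, N − 1 for odd N) when
the axis carries a complex FFT, so that index Z maps exactly to *b* (the
zero frequency). Absolute coordinates add the origin offset,
X_abs = X + o, and the dimensionless ratio coordinates X / (o − b) give,
e.g., the NMR ppm scale.

Component values are stored flat in **column-major order** (dimension 0
fastest): offset *i* maps to grid indexes j_k = ⌊i / ∏_{ℓ<k} N_ℓ⌋ mod N_k,
and back via i = Σ_k (∏_{ℓ<k} N_ℓ) j_k. Sparsely sampled grids store only
selected fully-sampled cross-sections, located by a flattened array of
sparse-grid vertexes. Payloads are JSON numbers, base64-encoded
little-endian binary (IEEE 754 for floats), or raw external binary files
addressed by a `file:./…` URL. Every physical quantity is a string such as
`"0.1 ms"`, with a case-sensitive unit grammar (`*`, `/`, `^`,
parentheses) and full 7-exponent dimensional algebra.

## Worked example

```r
library(csdmr)

td <- tempdir()
generate_fixtures(td, "decay_like", seed = 42)  # synthetic NMR-like file
x <- read_csdm(file.path(td, "decay_like.csdf"))
print(x)
#> <csdm> version 1.0
#>   dimensions: 1 (32)
#>     [0] linear count=32 increment=0.1 ms
#>   dependent variables: 1
#>     [0] internal scalar complex64

cc <- linear_coordinates(x$dimensions[[1]])
print(cc)
#> <coordinates> linear, n = 32, unit 'ms'
#>   -3.000000e-01, -2.000000e-01, -1.000000e-01,  5.551115e-17, ...

format_scalar_quantity(
  convert_quantity(scalar_quantity(cc$values[1], cc$unit), "µs"))
#> [1] "-300.0 µs"
```

The printed object shows a one-dimensional dataset of 32 complex samples
taken every 0.1 ms starting at −0.3 ms; the coordinate array realizes
X_j = Δx·j + b in the increment's unit, and the quantity machinery
converts it losslessly between µs and ms.

The same operations are available from a shell via the bundled CLI
(`inst/bin/csd`):

```sh
csd validate file.csdf          # exit 0/1/2; diagnostics on stderr
csd info file.csdf [--json]     # shape, quantity types, sparse flags
csd convert in.csdf out.csdf --encoding base64
csd fixtures outdir --seed 42
```

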