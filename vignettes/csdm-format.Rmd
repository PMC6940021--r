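---
title: "The CSD model in csdmr: structure, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CSD model in csdmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdmr)
```

`csdmr` implements version 1.0 of the Core Scientific Dataset (CSD)
model: a JSON container holding a *p*-component dependent variable
sampled at *M* points of a *d*-dimensional orthogonal grid. This
vignette explains the model as the package realizes it, the parameters
that matter, the numerical conventions, and the design choices that the
format definition leaves open.

## The object graph

The root `csdm` object carries a version string ("1.0"), an optional
ISO-8601 UTC timestamp, an optional geographic coordinate, a `read_only`
flag for archived files, free-text tags and description, an ordered list
of dimensions, and an ordered list of dependent variables. All dependent
variables share the one grid the dimensions define; *d* = 0 is legal and
means a single-sample grid (the empty product of counts is 1).

Dimensions come in three subtypes:

* **linear** — uniformly spaced; defined by `count` (N), `increment`
  (Δx, nonzero), `coordinates_offset` (b, default 0), `origin_offset`
  (o, default 0), a `complex_fft` flag, and an optional `period`
  (default infinite, meaning non-periodic; zero is invalid). Coordinates
  are `X[j] = Δx (j − Z) + b`. With `complex_fft` true, `Z = T/2` where
  `T = N` (even) or `N − 1` (odd), which pins index Z exactly to b — the
  zero frequency after a complex FFT — independent of the pre-transform
  axis. Δx, b, o, and the period must share one dimensionality.
* **monotonic** — an explicit list of strictly increasing or strictly
  decreasing quantities, possibly spanning orders of magnitude or mixing
  compatible units (`"0.08 ms"` beside `"80 µs"`); conversion to the
  first entry's unit happens before the monotonicity and uniqueness
  checks.
* **labeled** — unique strings, purely qualitative; no units, no
  spacing semantics. Date-time axes are deliberately kept as labels, not
  parsed times.

A dependent variable is **internal** (payloads inline, JSON numbers or
base64) or **external** (one raw little-endian binary sidecar addressed
by `components_url`). Its `quantity_type` fixes the component count p
and the interpretation at each sample: `scalar` (p = 1), `vector_n`,
`pixel_n` (p = n), `matrix_m_n` (p = mn, column-major, entry (r, c) from
component `c·m + r`), or `symmetric_matrix_n` (p = n(n+1)/2, packed
upper triangle row by row). `numeric_type` names one of twelve storage
types from `uint8` to `complex128`; complex arrays serialize as 2M
interleaved numerals starting with the real part.

## Storage order and sparse sampling

Flat component storage is column-major relative to the ordered
dimensions — dimension 0 varies fastest. `offset_to_indexes()` /
`indexes_to_offset()` realize the two index maps and are checked against
a brute-force nested-loop enumerator in the tests.

Under sparse sampling, only selected cross-sections exist: the
`SparseSampling` object names the sparse dimensions and an ordered,
flattened integer array of sparse-grid vertexes (optionally base64 as an
unsigned integer type). Values along the fully sampled dimensions are
packed column-major within each vertex, vertexes in file order.
`scatter_sparse()` places these cross-sections on the full grid and
returns a logical mask alongside, because the format prescribes no fill
semantics: the default fill is 0 and the mask is how a consumer
distinguishes true zeros from unsampled positions. Two design readings
adopted here: tuple position t of each vertex corresponds to
`dimension_indexes[t]`, and vertex order is exactly file order (never
sorted). Distinct dependent variables may carry independent sparse
layouts.

## Units

No unit-algebra package ships with the R ecosystem this package targets,
and the unit grammar is integral to the format, so `csdmr` implements it
directly. A unit is a positive scale factor to coherent SI plus seven
integer dimension exponents (length, mass, time, current, temperature,
amount, luminous intensity). The grammar is case-sensitive symbols with
optional SI prefixes, explicit `*` and `/`, integer powers via `^`, and
parentheses; implicit multiplication (`"N m"`, `"kWh"`) is an error
naming the offending token. Because exponents in the grammar are
integers, dimension vectors stay exact through arbitrarily long `^` and
`/` chains — no floating drift.

The registry ships the SI base units, the derived symbols with special
names (Hz, Bq, N, Pa, J, W, C, V, F, S, T, Wb, Ω, lm, lx, L), all SI
prefixes from yocto to yotta (with "µ", "μ", and ASCII "u" accepted for
micro, and "deg" for "°"), and the accepted non-SI units the format's
examples require: bar, min, h, d, yr (Julian, 365.25 d), °, rad, sr,
ppm, %. Symbol resolution prefers an exact registry match before prefix
splitting, so `min` is a minute, not milli-inch, while `hPa` still
resolves as hecto-pascal. Angles are dimensionless with a retained
display symbol — the SI convention, and the reason a longitude in
degrees compares dimensionality-equal to a pure number. °C and °F parse
as affine temperature units: they convert to and from kelvin by offset
but refuse `*`/`/`/`^` composition, and the validator flags them with a
warning because they are ambiguous as thermodynamic temperatures. The
shipped registry is a documented subset of the model's full controlled
vocabulary; `quantity_name` strings are carried verbatim and not
validated against a vocabulary.

One wrinkle in the format's prose calls `kg*m^2/s^2` a unit of force;
dimensionally it is energy, and this package follows the dimensional
algebra, never prose labels.

## Serialization conventions

Parsing is delegated to `jsonlite`; emission is a small canonical writer
because the package promises byte-stable output: two-space indentation,
UTF-8 without BOM, a fixed key order per object (`type` first, required
attributes, then optional attributes), and shortest round-trip decimal
formatting for floats (integers as JSON integers). Optional keys at
their default value are omitted, and booleans appear only when true — an
absent `period` key *is* the infinite period. Writing the same object
twice (without refreshing the timestamp) is byte-identical, which the
tests assert for every fixture.

Files with no external dependent variable must use `.csdf`; any external
data forces `.csdfe`, alerting users that a sidecar must travel with the
file. `file:` URLs must be relative (`file:./…`) and resolve inside the
dataset's folder or a subfolder — `..` segments are a security error —
and `https:` fetches require explicit opt-in. External sidecars store
the p components contiguously in component order, each a column-major
sample block; equivalently, the flat file reshapes to
(N₀ × … × N₍d−1₎ × p) with the component index slowest. Loading is lazy:
`read_csdm()` never touches sidecars until `csdm_load_components()` or
`internalize()` asks.

NaN or infinite float values cannot be JSON numbers, so a component
containing them is switched to base64 at write time with a message.
Base64 output uses the standard alphabet, mandatory padding, and no line
breaks; strict reads reject embedded whitespace, lenient reads strip it.
Unknown keys anywhere in the graph are preserved verbatim and re-emitted
after the canonical keys — forward compatibility — and `application`
blocks under reverse-DNS keys pass through untouched; the package never
writes under a reverse-DNS key it does not own. A file whose root is an
array of CSDM objects is rejected: one CSDM per file. Files declaring a
version other than "1.0" are an error in strict mode and a warning in
lenient mode.

Two readings adopted where the definition is loose: the reciprocal
dimension is metadata-only (offsets, period, names — no count or
increment of its own), with a warning (not an error) when its
dimensionality is not the inverse of its parent's; and
`component_labels` shorter than p are an error in strict mode, accepted
in lenient mode.

## Validation

`csdm_validate()` returns an ordered data frame of diagnostics
(severity, path, message) rather than throwing: dimension findings
first, then dependent variables, in index order, deterministically. It
checks required attributes, monotonicity and uniqueness after unit
conversion, the zero-period and zero-increment rules, shared
dimensionality of a dimension's quantities, geographic-coordinate
ranges (latitude in [−90°, 90°], longitude in [−180°, 180°]), component
counts against the quantity type, and sample counts against the grid —
`M = ∏ N_k` fully sampled, or (number of vertexes) × ∏ N over the fully
sampled dimensions under sparse sampling, with complex types counting 2M
flat numerals. Lenient mode drops warning-class findings (reciprocal
dimensionality, affine temperature units) but never required-attribute
violations. Validation never mutates its argument.

## Numerical choices

* Quantity values are held as 64-bit floats; `numeric_type` governs
  storage. JSON-number payloads are snapped to their storage precision
  on import (a float32 array read from JSON equals the same array after
  a binary round trip).
* `int64`/`uint64` decode composes two 32-bit words into a double;
  values beyond 2^53 lose precision. R has no native 64-bit integer;
  this is the documented trade-off.
* Unit conversion multiplies by a single precomputed scale ratio (one
  rounding step), and round-trip conversion is exact to 1e−12 relative.
* Z is computed as an integer (T is even by construction), never a
  half-integer index.
* Monotonicity ties after unit conversion are violations, matching the
  "unique" requirement.

## Fixtures and what the tests do (and do not) show

`fixture_csdm()` / `generate_fixtures()` build ten miniature patterns
covering each serialization feature — linear and monotonic axes, complex
signals with reciprocal metadata, sparse sampling in one and two
dimensions, pixel images, symmetric tensors, external vector data with a
labeled axis, five correlated variables on one grid, and a
0-dimensional dataset. Default sizes are deliberately small (tens of
points per axis): the content is seeded pseudo-random — decaying complex
exponentials where a spectroscopist would expect a signal — because
format fidelity depends on determinism, not realism. Every numeral is a
pure function of (pattern, sizes, seed).

`paper_examples()` reconstructs the metadata skeletons of the canonical
published examples at their full printed sizes (the 1608-point sea-level
record; the 4096-point Bloch decay at 0.1 ms from −0.3 ms; the
saturation-recovery t₂ axis, 1024 points at 80 µs from −41.04 ms, with a
ten-step synthetic monotonic t₁; the 49 × 49 × 6 wind field at 0.5° from
−102.5°/13.5°; the 512 × 512 TEM image at 4 nm; the 1024 × 768 RGB
image; the 148 × 190 × 160 diffusion-tensor MRI at 1 mm with components
Dxx…Dzz). Their data arrays are synthetic stand-ins — the published
binary payloads are not reproducible from a text description — so tests
against them exercise metadata, coordinates, and structure, not data
values. Passing this suite demonstrates faithful implementation of the
format's rules on constructed data; it cannot certify behaviour on
arbitrary real-world files beyond those rules.

## Known limitations

* No compression, checksums, big-endian dialects (rejected, not
  auto-detected), or streaming parse of multi-gigabyte files.
* No CODATA constant registry, logarithmic units (dB), or natural-unit
  systems.
* Sparse *reconstruction* (compressed sensing and kin) is out of scope:
  the package places sampled values faithfully and exposes the mask.
* The CSV export in the CLI is an interchange convenience for d ≤ 2,
  not part of the model.
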