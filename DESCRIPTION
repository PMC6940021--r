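Package: csdmr
Title: Read, Write, and Validate Core Scientific Dataset Model Files
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An implementation of the Core Scientific Dataset (CSD) model
    version 1.0, a lightweight JSON-based container for p-component
    dependent variables sampled on d-dimensional orthogonal grids, as used
    for NMR, MRI, mass spectrometry, microscopy, and imaging datasets.
    Provides parsing and dimensional algebra for physical units, coordinate
    generation for linear, monotonic, and labeled dimensions, base64 and
    raw little-endian component codecs, column-major grid index mapping,
    sparse-sampling reconstruction, strict and lenient validation,
    round-trip '.csdf'/'.csdfe' serialization, deterministic fixture
    generators, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, tools, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
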