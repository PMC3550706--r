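Package: octstrut
Title: Automatic Stent Strut Detection in Intravascular OCT Pullbacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects metal stent struts in intravascular optical coherence
    tomography (IVOCT) pullback runs recorded in polar coordinates. Candidate
    pixels are found from per-A-line intensity profiles (peak plus the slope
    towards the trailing shadow), strut shadows are delineated with directional
    Prewitt compass filters after Gaussian smoothing, candidates are clustered
    with a wrap-aware single-linkage rule guided by the shadow edges, dim
    (non-bright) struts are recovered inside shadow intervals, and false
    positives are removed with three-dimensional pullback information (guide
    wire continuity, stented segment extraction). Includes a synthetic polar
    phantom generator with known ground truth, an evaluation module with
    tolerance-based optimal matching and parameter sensitivity sweeps, and a
    command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
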