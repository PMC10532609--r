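Package: cslrecon
Title: One-Shot Coded Structured Light Pattern Design, Decoding and 3D
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for active 3D reconstruction with a one-shot coded
    structured light (CSL) pattern of binary geometric symbols. Builds a
    projector pattern whose 3x3 symbol neighbourhoods form codewords at
    pairwise Hamming distance of at least 3, so a single classification
    error per codeword can be corrected. Decodes camera images of the
    projected pattern on smooth (fusiform) surfaces via Sauvola adaptive
    binarization, connected-component filtering, rotation- and
    scale-matched template classification, nearest-neighbour subpattern
    assembly with geometric consistency checks, and iterative
    error-correcting codeword matching. Matched symbol centroids are
    triangulated against the projector-camera geometry into sparse point
    clouds, depth maps and morphometric measurements (total length,
    height). A synthetic scene simulator renders the pattern onto
    parametric surfaces with controlled noise, blur and illumination
    gradients, together with exact ground truth, for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
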