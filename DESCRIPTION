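Package: protonrange
Title: Proton Range Verification from Positron-Emitter Activation Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Analytic pipeline for proton-therapy range monitoring via
    activation (dynamic PET) imaging of a water-gel phantom. Models the
    range-energy relation (Bragg-Kleeman or tabulated stopping power),
    depth-dose profiles with range straggling, threshold-gated production
    of the positron emitters 11C, 15O and 13N, and dynamic decay frames.
    Performs voxel-wise spectral analysis by non-negative least squares
    over a logarithmic grid of decaying exponentials to isolate the 13N
    component, locates the Bragg and 13N peaks, sweeps their offset over
    45-250 MeV, and calibrates offset against energy with linear and
    natural cubic-spline interpolation at 0.1 MeV resolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
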