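Package: curvactin
Title: Mechanochemical Modeling of Localization-Enhanced Arp2/3 Actin Nucleation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for studying how spatial localization of the
    nucleation-promoting factor N-WASP enhances Arp2/3-mediated dendritic actin
    nucleation. Generates Shannon-entropy-constrained probability fields at a
    prescribed localization factor and samples them into molecular copy-number
    maps; simulates compartmental reaction-diffusion chemistry with the
    Gibson-Bruck next-reaction method coupled to explicit semiflexible filament
    mechanics (conjugate-gradient energy minimization, Brownian-ratchet
    force-velocity coupling); quantifies nucleation through filament-count time
    series and branch-cluster densities; and provides a nanobar-array
    fluorescence quantification pipeline (background correction, end/center ROI
    densities, curvature-response and Hill fits, single-particle intensities)
    driven entirely by synthetic data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    minpack.lm,
    pracma,
    igraph,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
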