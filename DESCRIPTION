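Package: mcdem
Title: Multi-Contact Discrete Element Simulation of Powder Compaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Particle-scale simulation of uniaxial die compaction of
    pharmaceutical powders with a multi-contact discrete element method
    (MC-DEM). Implements a non-linear hysteretic adhesive elastic-plastic
    normal contact law with a stress-tensor-coupled multi-contact
    correction, Hertz-Mindlin tangential forces with Coulomb friction and
    constant-directional-torque rolling resistance, particle-growth packing
    generation against a fitted volume-weighted log-normal particle size
    distribution, strain-driven compaction and decompression between rigid
    plates in a laterally periodic box, representative-volume-element
    convergence studies, and R-squared-based calibration of the
    multi-contact prefactor against reference compression profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
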