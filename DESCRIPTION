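Package: glst
Title: Linear-Scaling Electrostatics via Gauss-Legendre Spherical Cubature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fast, accuracy-controlled calculation of Coulomb energies and
    forces in non-periodic particle systems. The Coulomb kernel is split
    Ewald-style into a short-range part handled by direct pairwise sums over
    a cell list and a smooth long-range part approximated by a cubature:
    a Gauss-Legendre radial rule fused with an antipodally symmetric
    spherical rule, evaluated through per-cell structure factors so the cost
    scales linearly with the number of atoms. Includes brute-force O(N^2)
    reference oracles, error metrics, a synthetic salt-water benchmark
    system builder, and hardware-independent operation-count sweeps over
    system size, target error threshold and direct-space cutoff.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
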