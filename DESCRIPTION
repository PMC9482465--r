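Package: plumediff
Title: Gas- and Liquid-Phase Electron Diffraction Simulation and Phase-Fraction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates kilovolt electron diffraction of small molecules in the
    independent atom model: atomic and molecular (Debye) scattering from XYZ
    geometries, random-packed liquid droplet configurations for molecular
    liquids, synthesis of noisy two-dimensional detector patterns, radial
    averaging, damped sine-transform inversion of modified molecular scattering
    to real-space pair distributions, and decomposition of measured curves into
    gas-phase and liquid-phase fractional contributions by non-negative least
    squares against theoretical basis curves. Glycerol is shipped as the
    reference system.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, tiff
Encoding: UTF-8
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
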