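Package: trxkin
Title: Kinetic Analysis of Time-Resolved Gas-Phase X-Ray Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and global kinetic analysis of femtosecond pump-probe
    gas-phase x-ray scattering experiments on photochemical reaction networks,
    developed around the deep-UV photodissociation of 1,2-dithiane. Provides
    independent-atom-model (Debye) scattering of molecules and fragment
    mixtures, first-order reaction-network population dynamics with Gaussian
    instrument-response convolution, variable-projection global fitting of
    percent-difference scattering maps into rate constants and
    species-associated scattering patterns, recovery of the optical excitation
    fraction, isotropic/anisotropic detector-image decomposition, ensemble
    averaging over geometry pools for vibrationally hot species, and a seeded
    synthetic-data generator for end-to-end parameter-recovery benchmarks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    lhs,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
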