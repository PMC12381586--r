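Package: haflex
Title: Classifying Hyaluronan Gel Flexibility from NMR Spin-Lattice
    Relaxation and Oscillatory Rheology
Version: 0.1.0
Authors@R:
    person("haflex", "maintainers", email = "haflex@example.org",
           role = c("aut", "cre"))
Description: Tools to decide whether proton spin-lattice relaxation in a
    hyaluronan (HA) hydrogel is governed by nanosecond-scale internal
    molecular motion or by dipolar cross-relaxation (spin diffusion).
    Simulates the competition between the two relaxation contributions for
    restricted motion of a 1H-1H vector on a cone under slow isotropic
    tumbling and extracts the dominance regime map; fits T1 from
    inversion- or saturation-recovery curves with propagated uncertainties
    and tests whether two resonances (sugar ring vs acetyl methyl) share a
    T1; extracts the storage/loss-modulus crossover frequency from
    oscillatory rheology sweeps; and generates synthetic recovery curves,
    two-pool exchange curves and Maxwell-fluid sweeps so the whole
    pipeline runs without external data. A command-line interface chains
    the stages into a single reproducible report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
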