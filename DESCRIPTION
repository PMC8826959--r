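Package: pardiv
Title: Gene-Level Parallelism and Divergence in Evolve-and-Resequence Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical framework for gene-level mutation counts from microbial
    evolve-and-resequence experiments. Predicts per-gene occupancy across
    replicate populations with a zero-free-parameter Poisson sampling model
    (with a mean-matched geometric alternative), tests for a global signal of
    gene-gene covariance via the Tracy-Widom-normalized largest eigenvalue of
    the multiplicity matrix against a fixed-margin randomization null, and
    identifies genes driving divergent evolution between environments with a
    folded Skellam test and a discrete false-discovery-rate procedure. Includes
    a synthetic count-matrix generator matching the framework's sampling
    assumptions and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
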