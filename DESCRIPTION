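Package: clonebench
Title: Simulation and Evaluation Toolkit for Tumor Clone Phylogeny Inference
Version: 0.1.0
Authors@R:
    person("clonebench", "developers", email = "clonebench@example.org",
           role = c("aut", "cre"))
Description: Simulators and scoring tools for benchmarking clonal
    deconvolution methods on multi-sample tumor bulk-sequencing data.
    Generates clone phylogenies with mutations assigned to branches,
    overlays whole-haplotype copy-number gains, losses and LOH, computes
    copy-number-aware expected variant allele frequencies and sequencing
    depths, emits observed read counts under a Poisson/Binomial model,
    and grows three-dimensional lattice tumors under three cell-division
    models with sector sampling and clone calling.  Inferred clone
    genotypes and phylogenies are scored against simulated truth with
    mutation-pair ordering error rates, a multi-label tree vector
    distance, rooted Robinson-Foulds distance, SNV assignment error and
    ancestral-clone detection counts, together with post-processing of
    method outputs (constrained clone-frequency regression, spurious
    ancestor filtering, rare clone discard, degenerate-topology flags).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
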