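Package: gsbridge
Title: Stochastic Simulation of Genomic Selection Breeding Programs with
    Gene-Bank Bridging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time stochastic simulation of doubled-haploid breeding
    programs under genomic selection. Simulates structured inbred founder
    panels, additive trait architectures, meiosis with Poisson crossovers,
    GBLUP genomic prediction with marker-effect backsolving, and cross
    selection by midparent value, the usefulness criterion, or optimal cross
    selection under a Nei-diversity constraint (including a usefulness
    criterion and parental contribution variant). Supports closed elite
    programs and open programs that introduce gene-bank donors through a
    bridging component, with a full metric suite: genetic gain, neutral Nei
    diversity, weighted QTL fixation rates, and pedigree-based donor
    contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
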