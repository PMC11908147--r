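Package: podsim
Title: Forward Simulation of Pseudo-Overdominance in Diploid and
    Autotetraploid Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A forward-in-time Wright-Fisher simulator of constant-size
    diploid and autotetraploid populations accumulating fully recessive
    deleterious mutations on a single chromosome, with tetrasomic
    inheritance through strictly bivalent meiosis (all pairings of the
    four homologs equally likely). Tracks per-generation population and
    parent fitness, median segregating allele frequency, and
    substitution counts; classifies pseudo-overdominance from allele
    frequency trajectories; provides exact closed-form genotype and
    gamete expectations for two-haplotype loci under disomic and
    tetrasomic inheritance; and runs replicated parameter sweeps over
    population size, mutation rate, recombination rate, and selection
    coefficient. Haplotypes can be exported as ms-style matrices or
    minimal VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
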