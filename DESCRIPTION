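Package: opsinshift
Title: Avian SWS1 Opsin Spectral Tuning: UVS/VS Classification and
    Parsimony Reconstruction of Spectral Shifts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring the spectral class (ultraviolet- or
    violet-sensitive, UVS/VS) of the avian short-wavelength-sensitive
    type 1 (SWS1) cone opsin from short genomic fragments. Translates
    DNA fragments spanning spectral tuning sites 86, 90 and 93 (bovine
    rhodopsin numbering), anchors them to a reference window, classifies
    genotypes with a configurable rule table, estimates lambda-max class
    intervals, analyses minimal nucleotide substitution paths between
    codons, and reconstructs the number and placement of UVS/VS shifts
    on a reference phylogeny by generalized Fitch parsimony with exact
    ranges over all most-parsimonious reconstructions. Ships a curated
    survey dataset of tuning-site windows from 40 bird species, a
    reference tree, and a seeded sequence-evolution simulator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
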