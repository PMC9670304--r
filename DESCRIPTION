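Package: ribohybrid
Title: Hybrid Diagnosis from Additive Nuclear Marker Polymorphisms and
    Plastid Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing plant hybrids from Sanger sequences of
    multicopy nuclear markers (ITS, 5S-NTS) and plastid intergenic spacers.
    Direct sequences are classified as pure genotypes or intra-/interspecific
    hybrids by character additivity of IUPAC ambiguity codes against a panel
    of reference ribotypes; parental copies are recovered from clone sets
    with polymerase-error correction and PCR-chimera (recombinant clone)
    detection; the maternal parent of each hybrid is assigned from plastid
    haplotype matching, with explicit equivocal and derived-haplotype
    outcomes; indels are coded as additional presence/absence characters
    (simple indel coding) and matrices exported for external phylogenetic
    software. A seeded simulator generates marker panels, hybrid samples,
    clone sets and plastid haplotypes with full ground truth so the whole
    pipeline can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
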