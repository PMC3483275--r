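Package: mhcclone
Title: MHC Class II Exon 2 Genotyping and Molecular Evolution from Clone
    Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genotyping multigene-family amplicons (MHC class II
    beta exon 2) from plasmid clone libraries. Collapses cloned PCR reads
    into candidate alleles, applies a two-or-more-individuals acceptance
    rule with a sequence-divergence rescue screen, flags pseudogene-like
    alleles, and analyses the validated allele set: nucleotide diversity,
    Tajima's D and Fu and Li's D*/F* neutrality tests, Nei-Gojobori dN/dS
    with Jukes-Cantor correction and codon-bootstrap z-tests partitioned
    by peptide-binding-region site masks, minimum locus-number inference,
    allele-accumulation rarefaction, cross-population allele sharing, and
    neighbour-joining trees with bootstrap consensus. Includes a seeded
    clone-library simulator (duplicated loci, shared ancestral alleles,
    pseudogenes, PCR point errors and chimeras) with full ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
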