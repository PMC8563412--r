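Package: allerscan
Title: Saturation-Mutagenesis PhIP-Seq Epitope Mapping and Antibody Repertoire Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of phage immunoprecipitation sequencing
    (PhIP-seq) experiments built on tiling plus saturation-mutagenesis
    peptide libraries for allergen epitope mapping. Designs the peptide
    library and its encoding oligonucleotides (tiling, single-residue
    saturation, codon-optimized reverse translation with restriction-site
    avoidance and unique 50-nt prefixes), converts immunoprecipitation
    read counts into enrichment Z-scores against a binned, trimmed mock-IP
    null, resolves high-resolution antibody footprints and critical
    residues from mutant enrichments, and summarizes IgE/IgG repertoires
    (breadth, seroprevalence, isotype overlap, dominant shared footprints,
    longitudinal fold changes under oral immunotherapy). Ships a
    fully specified synthetic-data simulator with ground truth so every
    stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
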