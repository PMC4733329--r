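Package: macrodissect
Title: Dissect Macromolecular Structures into Subunits and Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dissects a macromolecular structure (PDB or mmCIF) into eight
    subunit types - SCOP-annotated protein domains, inter-domain linkers,
    N- and C-terminal regions, peptides, undefined chains, and DNA and RNA
    chains - and computes the complete binary subunit interaction network of
    the complex. Contacts are defined at the heavy-atom level (6 Angstrom
    residue-residue cutoff for protein-protein interfaces; 3.5 Angstrom
    base nitrogen/oxygen cutoffs for nucleic-acid-mediated interfaces),
    filtered for sequence adjacency, and classified into 36 interaction
    types. Includes deterministic synthetic-structure generators for
    testing, exporters (JSON, GraphML, TSV, binary-complex PDB), and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
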