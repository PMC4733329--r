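# Component dictionaries: which comp_ids count as amino acids / DNA / RNA
# nucleotides, and which atoms belong to the nucleobase moiety.

AMINO_ACIDS_3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  # common modified residues occupying polymer positions
  "MSE", "SEC", "PYL", "SEP", "TPO", "PTR", "CSO", "HYP", "MLY", "M3L",
  "CME", "KCX", "LLP", "CSD", "OCS", "ASX", "GLX", "UNK"
)

DNA_NUCLEOTIDES <- c("DA", "DC", "DG", "DT", "DU", "DI")
RNA_NUCLEOTIDES <- c("A", "C", "G", "U", "I", "N")

# sugar + phosphate atom names; everything else in a nucleotide is base moiety
SUGAR_PHOSPHATE_ATOMS <- c(
  "P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P",
  "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'",
  "O5*", "C5*", "C4*", "O4*", "C3*", "O3*", "C2*", "O2*", "C1*"
)

# Watson-Crick complements, purine listed first
WC_COMPLEMENT <- list(
  DA = c("DT", "DU"), DG = "DC",
  A  = c("U", "T"),   G = "C"
)

#' Classify a polymer component name
#'
#' Maps a residue/nucleotide component id to one of `amino_acid`,
#' `dna_nucleotide`, `rna_nucleotide` or `other`. DNA components are the
#' standard deoxyribonucleotides plus any component following the
#' two-character `D`-prefix convention (e.g. modified `DOC`); this keeps the
#' classification deterministic without a chemical component dictionary.
#'
#' @param comp_id Character vector of component names (1-3 letters).
#' @return Character vector of unit kinds, same length.
#' @export
#' @examples
#' unit_kind(c("ALA", "DA", "U", "HOH"))
unit_kind <- function(comp_id) {
  comp_id <- toupper(trimws(comp_id))
  kind <- rep("other", length(comp_id))
  kind[comp_id %in% AMINO_ACIDS_3] <- "amino_acid"
  is_dna <- comp_id %in% DNA_NUCLEOTIDES |
    (nchar(comp_id) %in% 2:3 & str_sub(comp_id, 1, 1) == "D" &
       !comp_id %in% AMINO_ACIDS_3)
  kind[is_dna] <- "dna_nucleotide"
  kind[comp_id %in% RNA_NUCLEOTIDES] <- "rna_nucleotide"
  kind
}

is_base_atom <- function(atom_name) {
  !(toupper(atom_name) %in% SUGAR_PHOSPHATE_ATOMS)
}

# element inferred from a PDB atom name when the element column is absent
infer_element <- function(atom_name, comp_kind = NULL) {
  nm <- toupper(trimws(atom_name))
  el <- str_sub(nm, 1, 1)
  # two-letter elements commonly found in polymers
  el[str_sub(nm, 1, 2) == "SE"] <- "SE"
  el[str_sub(nm, 1, 2) == "FE"] <- "FE"
  el[str_sub(nm, 1, 2) == "ZN"] <- "ZN"
  # digit-leading names like 1H, 2HB are hydrogens
  el[str_detect(nm, "^[0-9]+H")] <- "H"
  el
}

is_heavy_element <- function(element) {
  !(toupper(trimws(element)) %in% c("H", "D", ""))
}
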