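#' Contact-detection parameters
#'
#' Bundles the distance cutoffs and filter thresholds that define a binary
#' interaction. The defaults are the standard interface definitions for this
#' kind of analysis: a residue-residue contact pair exists when the smallest
#' heavy-atom distance between the two residues is no more than 6 Angstrom;
#' nucleic-acid-mediated contacts use a 3.5 Angstrom cutoff between base
#' nitrogen/oxygen atoms (and protein heavy atoms on the protein side); a
#' protein-protein interaction requires at least 10 contact pairs; contact
#' pairs between sequence-adjacent subunits of the same chain are discarded
#' unless the residues are more than 10 sequence positions apart.
#'
#' @param pp_distance_cutoff Heavy-atom distance cutoff in Angstrom for
#'   residue-residue contact pairs. Default 6.0.
#' @param nucleic_distance_cutoff Distance cutoff in Angstrom for contacts
#'   involving a nucleic subunit. Default 3.5.
#' @param min_pp_contact_pairs Minimum number of surviving contact pairs for a
#'   protein-protein interaction. Default 10.
#' @param min_nucleic_contact_pairs Minimum number of contact pairs for an
#'   interaction involving a DNA or RNA subunit. Default 1: a single
#'   hydrogen-bond-scale (3.5 Angstrom) contact is individually meaningful.
#' @param adjacency_min_separation Minimum sequence separation (in residues)
#'   for a contact pair between sequence-adjacent subunits of one chain to be
#'   kept. Default 10 (pairs with separation <= 10 are dropped).
#' @param base_atoms_only If `TRUE` (default) only atoms of the nucleobase
#'   moiety are eligible on the nucleic side of residue-nucleotide contacts;
#'   sugar and phosphate atoms are excluded. Set `FALSE` to allow the whole
#'   nucleotide.
#' @return A list of class `contact_params`.
#' @export
#' @examples
#' contact_params()
#' contact_params(min_pp_contact_pairs = 1)
contact_params <- function(pp_distance_cutoff = 6.0,
                           nucleic_distance_cutoff = 3.5,
                           min_pp_contact_pairs = 10L,
                           min_nucleic_contact_pairs = 1L,
                           adjacency_min_separation = 10L,
                           base_atoms_only = TRUE) {
  stopifnot(
    is.finite(pp_distance_cutoff), pp_distance_cutoff > 0,
    is.finite(nucleic_distance_cutoff), nucleic_distance_cutoff > 0,
    min_pp_contact_pairs >= 1, min_nucleic_contact_pairs >= 1,
    adjacency_min_separation > 0
  )
  structure(
    list(
      pp_distance_cutoff = pp_distance_cutoff,
      nucleic_distance_cutoff = nucleic_distance_cutoff,
      min_pp_contact_pairs = as.integer(min_pp_contact_pairs),
      min_nucleic_contact_pairs = as.integer(min_nucleic_contact_pairs),
      adjacency_min_separation = as.integer(adjacency_min_separation),
      base_atoms_only = isTRUE(base_atoms_only)
    ),
    class = "contact_params"
  )
}

#' Subunit-annotation parameters
#'
#' @param peptide_max_len Exclusive upper bound on the length (in resolved
#'   residues) of a peptide: an undomained protein chain shorter than this is
#'   a peptide, otherwise an undefined chain. Default 20, the ASTRAL
#'   short-peptide convention.
#' @return A list of class `annotation_params`.
#' @export
annotation_params <- function(peptide_max_len = 20L) {
  stopifnot(peptide_max_len >= 1)
  structure(
    list(peptide_max_len = as.integer(peptide_max_len)),
    class = "annotation_params"
  )
}

# distance comparisons at a cutoff use this tolerance so that exact-boundary
# fixtures (e.g. 6.00 A) behave identically across platforms
DIST_TOL <- 1e-9
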