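is_protein_kind <- function(kind) kind %in% PROTEIN_SUBUNIT_KINDS
is_nucleic_kind <- function(kind) kind %in% NUCLEIC_SUBUNIT_KINDS

#' Minimum heavy-atom distance between two polymer units
#'
#' The shortest Euclidean distance over all cross pairs of non-hydrogen
#' atoms, one atom from each unit.
#'
#' @param atoms_a,atoms_b Atom tibbles (rows of a `struct_df`) for the two
#'   units; hydrogens are ignored.
#' @return Distance in Angstrom.
#' @export
min_heavy_atom_distance <- function(atoms_a, atoms_b) {
  a <- filter(atoms_a, .data$is_heavy)
  b <- filter(atoms_b, .data$is_heavy)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    abort("unit has no heavy atoms; distance undefined")
  }
  d2 <- cross_dist2(as.matrix(a[, c("x", "y", "z")]),
                    as.matrix(b[, c("x", "y", "z")]))
  sqrt(min(d2))
}

cross_dist2 <- function(m_a, m_b) {
  outer(m_a[, 1], m_b[, 1], "-")^2 +
    outer(m_a[, 2], m_b[, 2], "-")^2 +
    outer(m_a[, 3], m_b[, 3], "-")^2
}

# Shared engine: given the eligible atoms of each side, return one row per
# unit pair whose minimal eligible-atom distance is within cutoff. For the
# nucleic-nucleic definition O-O atom pairs never qualify. Works in blocks
# so memory stays bounded; the result is exactly the all-pairs brute-force
# answer.
empty_contacts <- function() {
  tibble(
    chain_a = character(), seq_index_a = integer(), auth_seq_a = character(),
    comp_a = character(), atom_a = character(),
    chain_b = character(), seq_index_b = integer(), auth_seq_b = character(),
    comp_b = character(), atom_b = character(), min_distance = double()
  )
}

contact_engine <- function(at_a, at_b, cutoff, exclude_oo = FALSE,
                           block = 4e6) {
  empty <- empty_contacts()
  if (nrow(at_a) == 0L || nrow(at_b) == 0L) return(empty)
  m_a <- as.matrix(at_a[, c("x", "y", "z")])
  m_b <- as.matrix(at_b[, c("x", "y", "z")])
  lim2 <- (cutoff + DIST_TOL)^2

  rows_per_block <- max(1L, floor(block / nrow(at_b)))
  hits <- list()
  i <- 1L
  while (i <= nrow(at_a)) {
    j <- min(i + rows_per_block - 1L, nrow(at_a))
    d2 <- cross_dist2(m_a[i:j, , drop = FALSE], m_b)
    ok <- d2 <= lim2
    if (exclude_oo) {
      oo <- outer(at_a$element[i:j] == "O", at_b$element == "O", "&")
      ok <- ok & !oo
    }
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx)) {
      hits[[length(hits) + 1L]] <- tibble(
        ia = idx[, 1] + i - 1L, ib = idx[, 2],
        d = sqrt(d2[idx])
      )
    }
    i <- j + 1L
  }
  if (length(hits) == 0L) return(empty)
  h <- list_rbind(hits)
  h |>
    mutate(
      chain_a = at_a$chain_id[.data$ia], seq_index_a = at_a$seq_index[.data$ia],
      auth_seq_a = at_a$auth_seq_id[.data$ia], comp_a = at_a$comp_id[.data$ia],
      atom_a = at_a$atom_name[.data$ia],
      chain_b = at_b$chain_id[.data$ib], seq_index_b = at_b$seq_index[.data$ib],
      auth_seq_b = at_b$auth_seq_id[.data$ib], comp_b = at_b$comp_id[.data$ib],
      atom_b = at_b$atom_name[.data$ib],
      min_distance = .data$d
    ) |>
    arrange(.data$min_distance, .data$ia, .data$ib) |>
    group_by(.data$chain_a, .data$seq_index_a, .data$chain_b,
             .data$seq_index_b) |>
    dplyr::slice(1L) |>
    ungroup() |>
    select(all_of(names(empty))) |>
    arrange(.data$seq_index_a, .data$seq_index_b)
}

#' Residue-residue contact pairs between two protein subunits
#'
#' A pair of residues, one from each subunit, is a contact pair when the
#' smallest heavy-atom distance between them is no more than
#' `pp_distance_cutoff` (default 6 Angstrom). When the two subunits are
#' sequence-adjacent regions of the same chain, the adjacency exclusion is
#' applied afterwards (see [apply_adjacency_exclusion()]).
#'
#' @param structure A `struct_df`.
#' @param su_a,su_b One-row subunit tibbles of protein kinds.
#' @param params [contact_params()].
#' @return A tibble of contact pairs: residue identifiers for both sides,
#'   `min_distance`, and the atom names achieving it.
#' @export
protein_protein_contacts <- function(structure, su_a, su_b,
                                     params = contact_params()) {
  stopifnot(is_protein_kind(su_a$subunit_kind),
            is_protein_kind(su_b$subunit_kind))
  at_a <- filter(subunit_atoms(structure, su_a), .data$is_heavy)
  at_b <- filter(subunit_atoms(structure, su_b), .data$is_heavy)
  if (nrow(at_a) == 0L || nrow(at_b) == 0L) {
    warn("degenerate subunit with no heavy atoms; no contacts")
  }
  pairs <- contact_engine(at_a, at_b, params$pp_distance_cutoff)
  apply_adjacency_exclusion(pairs, su_a, su_b, params)
}

base_on_atoms <- function(atoms, base_only = TRUE) {
  out <- filter(atoms, .data$element %in% c("N", "O"))
  if (base_only) out <- filter(out, is_base_atom(.data$atom_name))
  out
}

#' Residue-nucleotide contact pairs between a protein and a nucleic subunit
#'
#' A residue-base contact pair exists when an oxygen or nitrogen atom of the
#' nucleobase lies within `nucleic_distance_cutoff` (default 3.5 Angstrom)
#' of any heavy atom of the protein residue. Sugar and phosphate atoms are
#' excluded on the nucleic side unless `params$base_atoms_only` is `FALSE`.
#' The protein subunit is always reported as side `a`.
#'
#' @inheritParams protein_protein_contacts
#' @param su_p Protein-kind subunit row.
#' @param su_n DNA or RNA subunit row.
#' @export
protein_nucleic_contacts <- function(structure, su_p, su_n,
                                     params = contact_params()) {
  stopifnot(is_protein_kind(su_p$subunit_kind),
            is_nucleic_kind(su_n$subunit_kind))
  at_p <- filter(subunit_atoms(structure, su_p), .data$is_heavy)
  at_n <- base_on_atoms(filter(subunit_atoms(structure, su_n), .data$is_heavy),
                        base_only = params$base_atoms_only)
  contact_engine(at_p, at_n, params$nucleic_distance_cutoff)
}

#' Nucleotide-nucleotide contact pairs between two nucleic subunits
#'
#' Two nucleotides form a contact pair when a nitrogen-nitrogen or
#' oxygen-nitrogen atom pair between them is within
#' `nucleic_distance_cutoff` (default 3.5 Angstrom); oxygen-oxygen
#' proximity alone never qualifies.
#'
#' @inheritParams protein_protein_contacts
#' @export
nucleic_nucleic_contacts <- function(structure, su_a, su_b,
                                     params = contact_params()) {
  stopifnot(is_nucleic_kind(su_a$subunit_kind),
            is_nucleic_kind(su_b$subunit_kind))
  at_a <- base_on_atoms(filter(subunit_atoms(structure, su_a), .data$is_heavy),
                        base_only = FALSE)
  at_b <- base_on_atoms(filter(subunit_atoms(structure, su_b), .data$is_heavy),
                        base_only = FALSE)
  contact_engine(at_a, at_b, params$nucleic_distance_cutoff,
                 exclude_oo = TRUE)
}

spans_sequence_adjacent <- function(su_a, su_b) {
  if (su_a$chain_id != su_b$chain_id) return(FALSE)
  sa <- su_a$segments[[1]]
  sb <- su_b$segments[[1]]
  any(outer(sa$end, sb$start, function(e, s) e + 1L == s)) ||
    any(outer(sb$end, sa$start, function(e, s) e + 1L == s))
}

#' Drop covalent-proximity contact pairs between adjacent subunits
#'
#' Contact pairs between two sequence-adjacent subunits of the same chain
#' (e.g. a domain and the linker that follows it) that arise merely from
#' chain connectivity are false positives. When `su_a` and `su_b` abut in
#' sequence, every pair whose residues are within
#' `adjacency_min_separation` (default 10) sequence positions of each other
#' is removed; pairs between non-adjacent subunits pass through unchanged.
#'
#' @param pairs Contact-pair tibble.
#' @inheritParams protein_protein_contacts
#' @export
apply_adjacency_exclusion <- function(pairs, su_a, su_b,
                                      params = contact_params()) {
  if (nrow(pairs) == 0L || !spans_sequence_adjacent(su_a, su_b)) return(pairs)
  filter(pairs,
         abs(.data$seq_index_a - .data$seq_index_b) >
           params$adjacency_min_separation)
}

#' Decide whether two subunits form a binary interaction
#'
#' Dispatches to the contact definition selected by the two subunit kinds
#' (residue-residue, residue-nucleotide, or nucleotide-nucleotide), applies
#' the adjacency exclusion, and keeps the interaction when the surviving
#' contact pairs reach the governing minimum: `min_pp_contact_pairs`
#' (default 10) when both subunits are protein regions,
#' `min_nucleic_contact_pairs` (default 1) when a DNA or RNA subunit is
#' involved.
#'
#' @inheritParams protein_protein_contacts
#' @return A one-row tibble (`label_a`, `label_b`, `kind_a`, `kind_b`,
#'   `interaction_type`, `n_pairs`, `is_intra_chain`, `contacts` list
#'   column) or `NULL` when the subunits do not interact.
#' @export
detect_interaction <- function(structure, su_a, su_b,
                               params = contact_params()) {
  ka <- su_a$subunit_kind
  kb <- su_b$subunit_kind
  pp <- is_protein_kind(ka) && is_protein_kind(kb)
  if (pp) {
    pairs <- protein_protein_contacts(structure, su_a, su_b, params)
  } else if (is_protein_kind(ka) && is_nucleic_kind(kb)) {
    pairs <- protein_nucleic_contacts(structure, su_a, su_b, params)
  } else if (is_nucleic_kind(ka) && is_protein_kind(kb)) {
    pairs <- protein_nucleic_contacts(structure, su_b, su_a, params)
    pairs <- swap_contact_sides(pairs)
  } else if (is_nucleic_kind(ka) && is_nucleic_kind(kb)) {
    pairs <- nucleic_nucleic_contacts(structure, su_a, su_b, params)
  } else {
    abort(paste0("no interaction definition for kinds ", ka, "/", kb))
  }
  min_pairs <- if (pp) params$min_pp_contact_pairs else
    params$min_nucleic_contact_pairs
  if (nrow(pairs) < min_pairs) return(NULL)
  tibble(
    label_a = su_a$label, label_b = su_b$label,
    kind_a = ka, kind_b = kb,
    interaction_type = interaction_type_code(ka, kb),
    n_pairs = nrow(pairs),
    is_intra_chain = su_a$chain_id == su_b$chain_id,
    contacts = list(pairs)
  )
}

swap_contact_sides <- function(pairs) {
  rename(pairs,
         chain_a = "chain_b", seq_index_a = "seq_index_b",
         auth_seq_a = "auth_seq_b", comp_a = "comp_b", atom_a = "atom_b",
         chain_b = "chain_a", seq_index_b = "seq_index_a",
         auth_seq_b = "auth_seq_a", comp_b = "comp_a", atom_b = "atom_a") |>
    select("chain_a", "seq_index_a", "auth_seq_a", "comp_a", "atom_a",
           "chain_b", "seq_index_b", "auth_seq_b", "comp_b", "atom_b",
           "min_distance")
}

#' Export a contact-pair list as TSV
#'
#' One row per contact pair of an interface: chain, author residue number
#' and component of each side, the minimal distance, and the atom pair
#' achieving it.
#'
#' @param pairs Contact-pair tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_contacts <- function(pairs, path) {
  readr::write_tsv(
    select(pairs, "chain_a", "auth_seq_a", "comp_a", "atom_a",
           "chain_b", "auth_seq_b", "comp_b", "atom_b", "min_distance"),
    path
  )
  invisible(path)
}
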