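subunit_positions <- function(su) {
  segs <- su$segments[[1]]
  sort(unique(unlist(Map(seq.int, segs$start, segs$end))))
}

subunit_atoms <- function(structure, su) {
  pos <- subunit_positions(su)
  filter(as_tibble(structure),
         .data$chain_id == su$chain_id, .data$seq_index %in% pos)
}

subunit_unit_count <- function(su) length(subunit_positions(su))

#' Write the coordinates of a binary complex as a PDB file
#'
#' Extracts exactly the atoms of two subunits from a parsed structure and
#' writes them as standard PDB ATOM records, preserving the original author
#' chain ids and residue numbering, with a TER card between chains. The
#' output re-parses to the same two subunits and is what a user downloads to
#' inspect one interaction in isolation.
#'
#' @param structure A `struct_df`.
#' @param subunit_a,subunit_b One-row subunit tibbles (rows of
#'   [annotate_structure()] output or of a network's `nodes`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_binary_complex <- function(structure, subunit_a, subunit_b, path) {
  stopifnot(nrow(subunit_a) == 1L, nrow(subunit_b) == 1L)
  for (su in list(subunit_a, subunit_b)) {
    ch_units <- units_of(structure) |> filter(.data$chain_id == su$chain_id)
    if (nrow(ch_units) == 0L ||
        !all(subunit_positions(su) %in% ch_units$seq_index)) {
      abort(sprintf(
        "subunit %s (chain %s) does not belong to structure %s",
        su$label, su$chain_id, attr(structure, "entry_id") %||% "?"
      ))
    }
  }
  atoms <- bind_rows(
    subunit_atoms(structure, subunit_a),
    subunit_atoms(structure, subunit_b)
  ) |>
    distinct() |>
    arrange(.data$chain_id, .data$seq_index)
  write_pdb_atoms(atoms, path)
  invisible(path)
}

# Format a tidy atom table as PDB ATOM records via bio3d's writer
# (bit-faithful fixed columns), one TER per chain.
write_pdb_atoms <- function(atoms, path) {
  resno <- as.integer(str_match(atoms$auth_seq_id, "^(-?\\d+)")[, 2])
  insert <- str_match(atoms$auth_seq_id, "^-?\\d+(\\D*)$")[, 2]
  insert[is.na(insert) | insert == ""] <- ""
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(atoms)),
    resno = resno,
    resid = atoms$comp_id,
    eleno = seq_len(nrow(atoms)),
    elety = atoms$atom_name,
    chain = atoms$chain_id,
    insert = insert,
    alt = ifelse(atoms$alt_loc == "", NA, atoms$alt_loc),
    o = atoms$occupancy,
    b = rep(0, nrow(atoms)),
    elesy = atoms$element,
    chainter = TRUE,
    verbose = FALSE
  )
  invisible(path)
}

#' Serialize a structure to PDB text
#'
#' @param structure A `struct_df`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  write_pdb_atoms(as_tibble(structure), path)
}
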