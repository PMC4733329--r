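# shared in-code fixtures

# hand-written minimal PDB: 3 alanines, one hydrogen, an altloc pair, water
tiny_pdb_lines <- function() {
  c(
    "HEADER    TEST PROTEIN                            01-JAN-20   1TST",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  HA  ALA A   1      12.000   5.100  -4.900  1.00  0.00           H",
    "ATOM      4  CA BALA A   2      13.000   6.000  -3.000  0.40  0.00           C",
    "ATOM      5  CA AALA A   2      13.100   6.100  -3.100  0.60  0.00           C",
    "ATOM      6  CA  ALA A   3      16.000   6.000  -3.000  1.00  0.00           C",
    "HETATM    7  O   HOH A 101       0.000   0.000   0.000  1.00  0.00           O",
    "TER",
    "END"
  )
}

write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(tiny_pdb_lines(), path)
  path
}

# single protein chain whose only sub-cutoff contacts are planned bridges
# between residue pairs (for adjacency-exclusion tests): baseline CA atoms
# 10 A apart, one dedicated atom pair per planned (i, j, distance)
make_intra_chain_fixture <- function(n, planned, chain_id = "A") {
  base <- purrr::list_rbind(purrr::map(seq_len(n) - 1L, function(i) {
    tibble::tibble(chain_id = chain_id, auth_seq_id = as.character(i + 1L),
                   comp_id = "ALA", atom_name = "CA", element = "C",
                   x = 10 * i, y = 0, z = 0)
  }))
  extra <- purrr::list_rbind(purrr::map(seq_len(nrow(planned)), function(k) {
    m <- c(0, 50 + 40 * k, 0)
    tibble::tibble(
      chain_id = chain_id,
      auth_seq_id = as.character(c(planned$i[k] + 1L, planned$j[k] + 1L)),
      comp_id = "ALA", atom_name = c("CB", "CG"), element = "C",
      x = m[1], y = m[2], z = c(0, planned$distance[k])
    )
  }))
  plan <- dplyr::bind_rows(base, extra) |>
    dplyr::arrange(as.integer(.data$auth_seq_id))
  fixture_structure(plan, entry_id = "INTRA")
}

# random planted domain layout on one chain: returns the structure, the
# assignment table, and the expected subunit tiling
planted_layout_case <- function(seed) {
  set.seed(seed)
  n <- sample(60:140, 1)
  n_dom <- sample(1:3, 1)
  # draw non-overlapping domain intervals with at least 1 free residue gaps
  bounds <- sort(sample(seq_len(n - 1L), 2L * n_dom))
  starts <- bounds[seq(1, by = 2, length.out = n_dom)]
  ends <- bounds[seq(2, by = 2, length.out = n_dom)]
  ok <- ends - starts >= 4 & c(starts[-1], n + 10L) - ends >= 2
  starts <- starts[ok]
  ends <- ends[ok]
  structure <- fixture_structure(make_protein_chain(n, chain_id = "A"),
                                 entry_id = "PLNT")
  if (length(starts) == 0L) {
    return(list(structure = structure, assignments = NULL,
                expected = tibble::tibble(
                  subunit_kind = if (n < 20) "peptide" else "undefined_chain",
                  start_index = 0L, end_index = n - 1L)))
  }
  assignments <- tibble::tibble(
    pdb_id = "PLNT", chain_id = "A",
    start_auth = as.character(starts), end_auth = as.character(ends),
    domain_id = sprintf("dplanted%d", seq_along(starts)),
    scop_family = "a.1.1.1", sunid = "1", source = "scop_curated"
  )
  # expected tiling in 0-based seq coordinates (auth = seq + 1)
  rows <- list()
  pos <- 0L
  for (k in seq_along(starts)) {
    s <- starts[k] - 1L
    e <- ends[k] - 1L
    if (pos < s) {
      kind <- if (k == 1) "n_terminal" else "linker"
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subunit_kind = kind, start_index = pos, end_index = s - 1L)
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      subunit_kind = "domain", start_index = s, end_index = e)
    pos <- e + 1L
  }
  if (pos <= n - 1L) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      subunit_kind = "c_terminal", start_index = pos, end_index = n - 1L)
  }
  list(structure = structure, assignments = assignments,
       expected = purrr::list_rbind(rows))
}

# duplex DNA gripped by one protein domain: planned D-DNA contacts to both
# strands; returns structure + assignments covering the protein chain
gripping_domain_fixture <- function() {
  dup <- make_duplex_dna(8, chain_ids = c("B", "C"))
  dat <- dplyr::filter(as_tibble(dup$structure), .data$atom_name == "N1")
  # place a protein residue's CB exactly 3.0 A from one base N1 per strand
  targets <- dplyr::bind_rows(
    utils::head(dplyr::filter(dat, .data$chain_id == "B"), 1),
    utils::head(dplyr::filter(dat, .data$chain_id == "C"), 1)
  )
  prot <- make_protein_chain(30, chain_id = "A", offset = c(60, 0, 0))
  bridges <- purrr::list_rbind(purrr::map(1:2, function(k) {
    tibble::tibble(chain_id = "A", auth_seq_id = as.character(5 * k),
                   comp_id = "ALA", atom_name = "CG", element = "C",
                   x = targets$x[k] + 3.0, y = targets$y[k],
                   z = targets$z[k])
  }))
  plan <- dplyr::bind_rows(prot, bridges) |>
    dplyr::arrange(as.integer(.data$auth_seq_id))
  s <- fixture_structure(
    list(plan, dplyr::filter(as_tibble(dup$structure), TRUE)),
    entry_id = "GRIP", base_pairs = dup$base_pairs, source_format = "mmcif"
  )
  assignments <- tibble::tibble(
    pdb_id = "GRIP", chain_id = "A", start_auth = "1", end_auth = "30",
    domain_id = "dgrip1", scop_family = "b.1.1.1", sunid = "2",
    source = "scop_curated"
  )
  list(structure = s, assignments = assignments)
}
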