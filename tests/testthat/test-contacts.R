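unit_atoms_at <- function(xyz, name = "CA", element = "C") {
  tibble::tibble(chain_id = "A", seq_index = 0L, auth_seq_id = "1",
                 comp_id = "ALA", unit_kind = "amino_acid",
                 polymer_kind = "protein", atom_name = name,
                 element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 occupancy = 1, alt_loc = "", is_heavy = element != "H")
}

test_that("minimum heavy-atom distance is the exhaustive cross-pair minimum", {
  a <- unit_atoms_at(matrix(c(0, 0, 0), 1))
  b <- unit_atoms_at(matrix(c(3, 4, 0), 1))
  expect_equal(min_heavy_atom_distance(a, b), 5)
  expect_equal(min_heavy_atom_distance(a, a), 0)

  set.seed(42)
  m1 <- matrix(runif(15, 0, 10), ncol = 3)
  m2 <- matrix(runif(21, 0, 10), ncol = 3)
  brute <- min(sqrt(outer(seq_len(5), seq_len(7), Vectorize(function(i, j) {
    sum((m1[i, ] - m2[j, ])^2)
  }))))
  expect_equal(min_heavy_atom_distance(unit_atoms_at(m1), unit_atoms_at(m2)),
               brute)

  h_only <- unit_atoms_at(matrix(c(0, 0, 0), 1), name = "HA", element = "H")
  expect_error(min_heavy_atom_distance(a, h_only), "no heavy atoms")
})

test_that("the 6 A protein-protein boundary is inclusive", {
  dk <- make_docked_pair(3, 3, tibble::tibble(i = 0:2, j = 0:2,
                                              distance = c(5.99, 6.00, 6.01)))
  ct <- protein_protein_contacts(dk$structure,
                                 whole_chain_subunit(dk$structure, "A"),
                                 whole_chain_subunit(dk$structure, "B"))
  expect_equal(nrow(ct), 2L)
  expect_equal(ct$seq_index_a, c(0L, 1L))
  expect_equal(ct$min_distance, c(5.99, 6.00))
})

test_that("a planned 12-pair interface is recovered exactly", {
  plan <- tibble::tibble(
    i = c(0, 0, 1, 2, 3, 4, 5, 6, 7, 8, 9, 9),
    j = c(0, 1, 1, 2, 3, 4, 5, 6, 7, 8, 9, 0),
    distance = seq(2.0, 5.8, length.out = 12)
  )
  dk <- make_docked_pair(10, 10, plan)
  ct <- protein_protein_contacts(dk$structure,
                                 whole_chain_subunit(dk$structure, "A"),
                                 whole_chain_subunit(dk$structure, "B"))
  expect_equal(nrow(ct), 12L)
  expect_equal(ct[, c("seq_index_a", "seq_index_b", "min_distance")],
               dk$expected |>
                 dplyr::rename(min_distance = "distance"),
               ignore_attr = TRUE)

  far <- make_docked_pair(4, 4, tibble::tibble(i = 0, j = 0, distance = 50))
  expect_equal(nrow(protein_protein_contacts(
    far$structure, whole_chain_subunit(far$structure, "A"),
    whole_chain_subunit(far$structure, "B"))), 0L)
})

test_that("the 3.5 A nucleic boundary is inclusive for both definitions", {
  pl <- tibble::tibble(i = 0:2, j = 0:2, distance = c(3.49, 3.50, 3.51))
  nn <- make_docked_pair(3, 3, pl, kind = "nucleic")
  ct_nn <- nucleic_nucleic_contacts(nn$structure,
                                    whole_chain_subunit(nn$structure, "A"),
                                    whole_chain_subunit(nn$structure, "B"))
  expect_equal(ct_nn$min_distance, c(3.49, 3.50))

  pn <- make_docked_pair(3, 3, pl, kind = "protein_nucleic")
  ct_pn <- protein_nucleic_contacts(pn$structure,
                                    whole_chain_subunit(pn$structure, "A"),
                                    whole_chain_subunit(pn$structure, "B"))
  expect_equal(ct_pn$min_distance, c(3.49, 3.50))
})

test_that("only base-moiety N/O atoms count on the nucleic side", {
  # nucleotide whose phosphate OP1 is 3.0 A from the residue but whose base
  # sits 8+ A away: no residue-nucleotide contact under the base-only rule
  prot <- tibble::tibble(chain_id = "A", auth_seq_id = "1", comp_id = "ALA",
                         atom_name = "CA", element = "C", x = 0, y = 0, z = 0)
  nuc <- tibble::tibble(
    chain_id = "B", auth_seq_id = "1", comp_id = "DA",
    atom_name = c("OP1", "N1", "C1'"), element = c("O", "N", "C"),
    x = c(3.0, 9.0, 6.0), y = 0, z = 0
  )
  s <- fixture_structure(prot, nuc, entry_id = "BASE1")
  sa <- whole_chain_subunit(s, "A")
  sn <- whole_chain_subunit(s, "B")
  expect_equal(nrow(protein_nucleic_contacts(s, sa, sn)), 0L)
  # switching off the base-only restriction recovers the phosphate contact
  expect_equal(nrow(protein_nucleic_contacts(
    s, sa, sn, contact_params(base_atoms_only = FALSE))), 1L)
})

test_that("oxygen-oxygen proximity alone never makes a nucleic contact", {
  a <- tibble::tibble(chain_id = "A", auth_seq_id = "1", comp_id = "DG",
                      atom_name = c("O6", "N1"), element = c("O", "N"),
                      x = c(0, 50), y = 0, z = 0)
  b <- tibble::tibble(chain_id = "B", auth_seq_id = "1", comp_id = "DT",
                      atom_name = c("O4", "N3"), element = c("O", "N"),
                      x = c(2.5, 60), y = 0, z = 0)
  s <- fixture_structure(a, b, entry_id = "OO1")
  ct <- nucleic_nucleic_contacts(s, whole_chain_subunit(s, "A"),
                                 whole_chain_subunit(s, "B"))
  expect_equal(nrow(ct), 0L)
  # bring the N within reach: the O-N pair qualifies
  b2 <- b
  b2$x[2] <- 3.0
  s2 <- fixture_structure(a, b2, entry_id = "OO2")
  ct2 <- nucleic_nucleic_contacts(s2, whole_chain_subunit(s2, "A"),
                                  whole_chain_subunit(s2, "B"))
  expect_equal(nrow(ct2), 1L)
  expect_setequal(c(ct2$atom_a, ct2$atom_b), c("O6", "N3"))
})

test_that("Watson-Crick paired strands are in nucleic-nucleic contact", {
  dup <- make_duplex_dna(6)
  ct <- nucleic_nucleic_contacts(dup$structure,
                                 whole_chain_subunit(dup$structure, "B"),
                                 whole_chain_subunit(dup$structure, "C"))
  expect_gte(nrow(ct), 6L)
  expect_true(all(ct$min_distance <= 3.5 + 1e-9))
})

test_that("adjacency exclusion drops short-range pairs between abutting spans", {
  planned <- tibble::tibble(i = c(79L, 79L), j = c(84L, 94L),
                            distance = c(4.0, 4.5))
  s <- make_intra_chain_fixture(100, planned)
  asg <- tibble::tibble(pdb_id = "INTRA", chain_id = "A", start_auth = "1",
                        end_auth = "81", domain_id = "d1",
                        scop_family = "a.1.1.1", sunid = "1",
                        source = "scop_curated")
  spans <- annotate_structure(s, asg)
  dom <- spans[spans$subunit_kind == "domain", ]
  cterm <- spans[spans$subunit_kind == "c_terminal", ]
  # gap 5 dropped, gap 15 kept
  ct <- protein_protein_contacts(s, dom, cterm)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$seq_index_b, 94L)
  # the raw pair set before exclusion has both
  raw <- macrodissect:::contact_engine(
    dplyr::filter(subunit_atoms(s, dom), is_heavy),
    dplyr::filter(subunit_atoms(s, cterm), is_heavy), 6.0)
  expect_equal(nrow(raw), 2L)
  # non-adjacent subunits keep short-gap pairs
  excl <- apply_adjacency_exclusion(raw, dom, whole_chain_subunit(
    fixture_structure(make_protein_chain(5, chain_id = "Z")), "Z"))
  expect_equal(nrow(excl), 2L)
})

test_that("interactions require 10 protein-protein pairs but 1 nucleic pair", {
  mk <- function(n_pairs) {
    plan <- tibble::tibble(i = seq_len(n_pairs) - 1L,
                           j = seq_len(n_pairs) - 1L,
                           distance = 5.0)
    make_docked_pair(12, 12, plan)
  }
  d9 <- mk(9)
  expect_null(detect_interaction(d9$structure,
                                 whole_chain_subunit(d9$structure, "A"),
                                 whole_chain_subunit(d9$structure, "B")))
  d10 <- mk(10)
  int <- detect_interaction(d10$structure,
                            whole_chain_subunit(d10$structure, "A"),
                            whole_chain_subunit(d10$structure, "B"))
  expect_equal(int$n_pairs, 10L)
  expect_equal(int$interaction_type, "U-U")

  nuc <- make_docked_pair(5, 5, tibble::tibble(i = 0, j = 0, distance = 3.2),
                          kind = "protein_nucleic")
  int_n <- detect_interaction(nuc$structure,
                              whole_chain_subunit(nuc$structure, "A"),
                              whole_chain_subunit(nuc$structure, "B"))
  expect_equal(int_n$n_pairs, 1L)
  expect_equal(int_n$interaction_type, "U-DNA")
})

test_that("detection is symmetric in its arguments", {
  plan <- tibble::tibble(i = 0:4, j = c(0, 2, 4, 1, 3),
                         distance = c(3.0, 4.5, 5.0, 5.5, 5.99))
  dk <- make_docked_pair(6, 6, plan)
  pa <- whole_chain_subunit(dk$structure, "A")
  pb <- whole_chain_subunit(dk$structure, "B")
  p <- contact_params(min_pp_contact_pairs = 3)
  ab <- detect_interaction(dk$structure, pa, pb, p)
  ba <- detect_interaction(dk$structure, pb, pa, p)
  expect_equal(ab$interaction_type, ba$interaction_type)
  expect_equal(ab$n_pairs, ba$n_pairs)
  swapped <- ba$contacts[[1]][, c("seq_index_b", "seq_index_a", "min_distance")]
  names(swapped) <- c("seq_index_a", "seq_index_b", "min_distance")
  expect_equal(
    dplyr::arrange(ab$contacts[[1]][, c("seq_index_a", "seq_index_b",
                                        "min_distance")],
                   seq_index_a),
    dplyr::arrange(swapped, seq_index_a),
    ignore_attr = TRUE
  )

  nuc <- make_docked_pair(4, 4, tibble::tibble(i = 1, j = 2, distance = 3.0),
                          kind = "protein_nucleic")
  na_ <- whole_chain_subunit(nuc$structure, "A")
  nb <- whole_chain_subunit(nuc$structure, "B")
  ab2 <- detect_interaction(nuc$structure, na_, nb)
  ba2 <- detect_interaction(nuc$structure, nb, na_)
  expect_equal(ab2$interaction_type, ba2$interaction_type)
  expect_equal(ab2$contacts[[1]]$seq_index_a, ba2$contacts[[1]]$seq_index_b)
})

test_that("cutoffs and minimum-pair thresholds are monotone", {
  set.seed(7)
  plan <- tibble::tibble(i = 0:7, j = sample(0:7), distance = runif(8, 2, 8))
  dk <- make_docked_pair(8, 8, plan)
  pa <- whole_chain_subunit(dk$structure, "A")
  pb <- whole_chain_subunit(dk$structure, "B")
  n_at <- purrr::map_int(c(3, 5, 6, 7, 9), function(cut) {
    nrow(protein_protein_contacts(dk$structure, pa, pb,
                                  contact_params(pp_distance_cutoff = cut)))
  })
  expect_true(all(diff(n_at) >= 0))
  present <- purrr::map_lgl(1:9, function(mp) {
    !is.null(detect_interaction(dk$structure, pa, pb,
                                contact_params(min_pp_contact_pairs = mp)))
  })
  expect_true(all(diff(as.integer(present)) <= 0))
})

test_that("the contact engine matches the brute-force oracle on random complexes", {
  n_pairs_checked <- 0L
  for (seed in 1:10) {
    n_pairs_checked <- n_pairs_checked +
      expect_engine_matches_oracle(make_random_complex(seed))
  }
  expect_gte(n_pairs_checked, 10L)
})
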