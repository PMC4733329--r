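test_that("dir.cla dialect rows parse into assignments", {
  p <- tempfile()
  writeLines(c(
    "# comment line",
    "d1dlwa_ 1dlw A: a.1.1.1 14982",
    "d2aaaa1 2aaa A:2-77 b.2.1.3 55001",
    "d3mska1 3msk A:1-40,A:61-100 c.3.1.1 60110",
    "p4sfxa1 4sfx B:5-90 d.1.1.2 0 superfamily_predicted"
  ), p)
  asg <- read_scop_cla(p)
  expect_equal(nrow(asg), 5L) # multi-segment row contributes two
  whole <- asg[asg$domain_id == "d1dlwa_", ]
  expect_equal(whole$chain_id, "A")
  expect_true(is.na(whole$start_auth))
  bounded <- asg[asg$domain_id == "d2aaaa1", ]
  expect_equal(c(bounded$start_auth, bounded$end_auth), c("2", "77"))
  multi <- asg[asg$domain_id == "d3mska1", ]
  expect_equal(nrow(multi), 2L)
  expect_equal(multi$start_auth, c("1", "61"))
  expect_equal(unique(asg$source[asg$domain_id == "p4sfxa1"]),
               "superfamily_predicted")
})

test_that("commented and malformed rows are skipped", {
  p <- tempfile()
  writeLines(c(
    "d1aaaa_ 1aaa A: a.1.1.1 1",
    "# d2bbbb_ 1bbb B: a.1.1.1 2",
    "d3cccc_ 1ccc C: a.1.1.1 3"
  ), p)
  expect_equal(nrow(read_scop_cla(p)), 2L)
  writeLines(c("d1aaaa_ 1aaa", "d2bbbb_ 1bbb B: a.1.1.1 2"), p)
  expect_warning(asg <- read_scop_cla(p), "malformed")
  expect_equal(nrow(asg), 1L)
})

test_that("domains map onto resolved residues; stale ranges are rejected", {
  s <- fixture_structure(make_protein_chain(100, chain_id = "A"),
                         entry_id = "MAP1")
  asg <- tibble::tibble(
    pdb_id = "MAP1", chain_id = "A",
    start_auth = c("10", "90"), end_auth = c("60", "150"),
    domain_id = c("dok", "dstale"), scop_family = c("a.1.1.1", "b.1.1.1"),
    sunid = c("1", "2"), source = "scop_curated"
  )
  doms <- map_domains(s, "A", asg)
  expect_equal(nrow(doms), 1L)
  expect_equal(doms$n_units, 51L)
  expect_equal(c(doms$start_index, doms$end_index), c(9L, 59L))
  rej <- attr(doms, "rejected")
  expect_equal(rej$domain_id, "dstale")
})

test_that("overlapping assignments resolve deterministically", {
  s <- fixture_structure(make_protein_chain(100, chain_id = "A"),
                         entry_id = "OVL1")
  asg <- tibble::tibble(
    pdb_id = "OVL1", chain_id = "A",
    start_auth = c("1", "30"), end_auth = c("50", "100"),
    domain_id = c("dpred", "dcur"),
    scop_family = c("a.1.1.1", "b.1.1.1"), sunid = c("1", "2"),
    source = c("superfamily_predicted", "scop_curated")
  )
  doms <- map_domains(s, "A", asg)
  # curated wins even though the predicted domain is narrower
  expect_equal(doms$domain_id, "dcur")
  expect_equal(attr(doms, "rejected")$reason, "overlap")
})

test_that("unstructured regions classify as N-terminal, linker, C-terminal", {
  s <- fixture_structure(make_protein_chain(100, chain_id = "A"),
                         entry_id = "UNS1")
  asg <- tibble::tibble(
    pdb_id = "UNS1", chain_id = "A", start_auth = "21", end_auth = "80",
    domain_id = "d1", scop_family = "a.1.1.1", sunid = "1",
    source = "scop_curated"
  )
  spans <- annotate_structure(s, asg)
  expect_equal(spans$subunit_kind, c("n_terminal", "domain", "c_terminal"))
  expect_equal(spans$start_index, c(0L, 20L, 80L))
  expect_equal(spans$end_index, c(19L, 79L, 99L))
  expect_equal(spans$label, c("A1", "A2", "A3"))
})

test_that("two domains flank a single linker and ordinals skip it", {
  s <- fixture_structure(make_protein_chain(100, chain_id = "A"),
                         entry_id = "LNK1")
  asg <- tibble::tibble(
    pdb_id = "LNK1", chain_id = "A",
    start_auth = c("1", "61"), end_auth = c("40", "100"),
    domain_id = c("d1", "d2"), scop_family = "a.1.1.1", sunid = "1",
    source = "scop_curated"
  )
  spans <- annotate_structure(s, asg)
  expect_equal(spans$subunit_kind, c("domain", "linker", "domain"))
  expect_equal(spans$label, c("A1", "A2", "A3"))
  link <- spans[spans$subunit_kind == "linker", ]
  expect_equal(c(link$start_index, link$end_index), c(40L, 59L))
})

test_that("a fully covered chain yields no unstructured spans", {
  s <- fixture_structure(make_protein_chain(50, chain_id = "A"),
                         entry_id = "FUL1")
  asg <- tibble::tibble(pdb_id = "FUL1", chain_id = "A", start_auth = "1",
                        end_auth = "50", domain_id = "d1",
                        scop_family = "a.1.1.1", sunid = "1",
                        source = "scop_curated")
  spans <- annotate_structure(s, asg)
  expect_equal(spans$subunit_kind, "domain")
})

test_that("undomained chains split at the 20-residue peptide bound", {
  s19 <- fixture_structure(make_protein_chain(19, chain_id = "A"))
  s20 <- fixture_structure(make_protein_chain(20, chain_id = "A"))
  s300 <- fixture_structure(make_protein_chain(300, chain_id = "A"))
  expect_equal(annotate_structure(s19)$subunit_kind, "peptide")
  expect_equal(annotate_structure(s20)$subunit_kind, "undefined_chain")
  expect_equal(annotate_structure(s300)$subunit_kind, "undefined_chain")
})

test_that("raising peptide_max_len never turns a peptide into an undefined chain", {
  for (n in c(5L, 19L, 20L, 40L)) {
    s <- fixture_structure(make_protein_chain(n, chain_id = "A"))
    kinds <- purrr::map_chr(c(10L, 20L, 30L, 50L), function(mx) {
      classify_undomained_chain(s, "A", annotation_params(mx))$subunit_kind
    })
    # once peptide, stays peptide as the bound grows
    first_pep <- match("peptide", kinds)
    if (!is.na(first_pep)) {
      expect_true(all(kinds[first_pep:length(kinds)] == "peptide"))
    }
  }
})

test_that("DNA subunits require inter-chain base pairing", {
  dup <- make_duplex_dna(10)
  su <- identify_dna_subunits(dup$structure)
  expect_equal(nrow(su), 2L)
  expect_false(any(su$unpaired))

  # intra-chain hairpin pairs only: flagged unpaired, excluded by default
  hp_atoms <- make_nucleic_chain(c("DA", "DG", "DT", "DC"), chain_id = "H")
  hp <- fixture_structure(hp_atoms, entry_id = "HAIR",
                          base_pairs = tibble::tibble(
                            chain_a = "H", unit_a = "1",
                            chain_b = "H", unit_b = "4"),
                          source_format = "mmcif")
  su_hp <- identify_dna_subunits(hp)
  expect_equal(nrow(su_hp), 1L)
  expect_true(su_hp$unpaired)
  net <- build_network(hp)
  expect_equal(nrow(net$nodes), 0L)
  net_inc <- build_network(hp, include_unpaired_dna = TRUE)
  expect_equal(nrow(net_inc$nodes), 1L)
})

test_that("geometric Watson-Crick fallback pairs plain-PDB duplexes", {
  dup <- make_duplex_dna(10)
  # same coordinates, no base-pair records, PDB provenance
  s <- fixture_structure(as_tibble(dup$structure), entry_id = "GEO1",
                         source_format = "pdb")
  su <- identify_dna_subunits(s)
  expect_equal(nrow(su), 2L)
  expect_false(any(su$unpaired))

  # pull the strands 100 A apart: no geometric pairing remains
  at <- as_tibble(dup$structure)
  at$x[at$chain_id == "C"] <- at$x[at$chain_id == "C"] + 100
  far <- fixture_structure(at, entry_id = "GEO2")
  expect_true(all(identify_dna_subunits(far)$unpaired))
})

test_that("RNA chains are whole-chain subunits; hybrids are excluded and reported", {
  s <- fixture_structure(
    make_nucleic_chain(rep(c("A", "U", "G"), 5), chain_id = "R"),
    make_nucleic_chain(rep(c("G", "C"), 4), chain_id = "S",
                       offset = c(30, 0, 0)),
    make_nucleic_chain(c("A", "U", "DT", "G"), chain_id = "H",
                       offset = c(60, 0, 0)),
    entry_id = "RNA1"
  )
  su <- identify_rna_subunits(s)
  expect_equal(sort(su$chain_id), c("R", "S"))
  expect_equal(su$n_units[su$chain_id == "R"], 15L)
  expect_equal(attr(su, "hybrid_chains"), "H")

  prot <- fixture_structure(make_protein_chain(30, chain_id = "A"))
  expect_equal(nrow(identify_rna_subunits(prot)), 0L)
})

test_that("full annotation tiles every protein chain exactly once", {
  for (seed in 1:12) {
    case <- planted_layout_case(seed)
    spans <- annotate_structure(case$structure, case$assignments)
    got <- spans[, c("subunit_kind", "start_index", "end_index")]
    expect_equal(as.data.frame(got), as.data.frame(case$expected),
                 ignore_attr = TRUE)
    # partition property: positions covered exactly once
    pos <- unlist(purrr::map(seq_len(nrow(spans)),
                             function(i) macrodissect:::subunit_positions(spans[i, ])))
    n <- chains_of(case$structure)$n_units
    expect_equal(sort(pos), 0:(n - 1L))
  }
})

test_that("identical chains get symmetric span sets and labels are deterministic", {
  s <- fixture_structure(
    make_protein_chain(40, chain_id = "A"),
    make_protein_chain(40, chain_id = "B", offset = c(0, 200, 0)),
    entry_id = "SYM1"
  )
  asg <- tibble::tibble(
    pdb_id = "SYM1", chain_id = c("A", "B"), start_auth = "11",
    end_auth = "30", domain_id = c("da", "db"), scop_family = "a.1.1.1",
    sunid = "1", source = "scop_curated"
  )
  spans <- annotate_structure(s, asg)
  a <- spans[spans$chain_id == "A", c("subunit_kind", "start_index", "end_index")]
  b <- spans[spans$chain_id == "B", c("subunit_kind", "start_index", "end_index")]
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
  expect_equal(spans$label, c(paste0("A", 1:3), paste0("B", 1:3)))
  # determinism
  spans2 <- annotate_structure(s, asg)
  expect_equal(as.data.frame(spans), as.data.frame(spans2), ignore_attr = TRUE)
})

test_that("a multi-domain complex with DNA yields all expected kinds", {
  grip <- gripping_domain_fixture()
  spans <- annotate_structure(grip$structure, grip$assignments)
  expect_setequal(unique(spans$subunit_kind), c("domain", "dna"))
  expect_equal(nrow(spans), 3L)
})
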