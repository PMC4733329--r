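# Synthetic structure generators. Geometry is idealized, not physically
# relaxed: every pipeline rule depends only on distances, composition and
# sequence positions, so planned contact maps can be achieved exactly by
# construction.

atom_row <- function(chain_id, auth_seq, comp, name, element, xyz) {
  tibble(chain_id = chain_id, auth_seq_id = as.character(auth_seq),
         comp_id = comp, atom_name = name, element = element,
         x = xyz[1], y = xyz[2], z = xyz[3])
}

#' Generate an idealized protein chain
#'
#' Places `n` amino-acid residues (5 heavy backbone/CB atoms each) on an
#' extended trace (3.8 Angstrom CA spacing) or an alpha-helical trace.
#' Fully deterministic.
#'
#' @param n Number of residues (>= 1).
#' @param geometry `"extended"` or `"helix"`.
#' @param chain_id Chain letter.
#' @param comp Residue name used for every unit.
#' @param start_auth First author residue number.
#' @param offset Numeric length-3 translation applied to the whole chain.
#' @return A chain plan (atom tibble) for [fixture_structure()].
#' @export
#' @examples
#' s <- fixture_structure(make_protein_chain(19))
#' chains_of(s)
make_protein_chain <- function(n, geometry = c("extended", "helix"),
                               chain_id = "A", comp = "ALA",
                               start_auth = 1L, offset = c(0, 0, 0)) {
  if (n < 1) abort("n must be >= 1")
  geometry <- match.arg(geometry)
  rows <- map(seq_len(n), function(i) {
    ca <- if (geometry == "extended") {
      c(3.8 * (i - 1L), 0, 0)
    } else {
      c(2.3 * cos(i * 100 * pi / 180), 2.3 * sin(i * 100 * pi / 180),
        1.5 * (i - 1L))
    }
    ca <- ca + offset
    bind_rows(
      atom_row(chain_id, start_auth + i - 1L, comp, "N", "N",
               ca + c(-1.2, 0.8, 0)),
      atom_row(chain_id, start_auth + i - 1L, comp, "CA", "C", ca),
      atom_row(chain_id, start_auth + i - 1L, comp, "C", "C",
               ca + c(1.0, 0.9, 0)),
      atom_row(chain_id, start_auth + i - 1L, comp, "O", "O",
               ca + c(1.2, 2.0, 0)),
      atom_row(chain_id, start_auth + i - 1L, comp, "CB", "C",
               ca + c(0, -1.4, 0.6))
    )
  })
  list_rbind(rows)
}

# base-moiety template, purine N1 / pyrimidine N3 at the origin facing +x/-x
purine_base <- function(comp) {
  b <- list(
    N1 = c(0, 0, 0), C2 = c(-0.7, 1.2, 0), N3 = c(-2.0, 1.3, 0),
    C4 = c(-2.8, 0.2, 0), C5 = c(-2.2, -1.1, 0), C6 = c(-0.8, -1.2, 0),
    N7 = c(-3.3, -2.0, 0), C8 = c(-4.4, -1.3, 0), N9 = c(-4.2, 0.1, 0)
  )
  b[[if (comp %in% c("DG", "G")) "O6" else "N6"]] <- c(-0.1, -2.4, 0)
  b
}

pyrimidine_base <- function(comp) {
  b <- list(
    N3 = c(0, 0, 0), C2 = c(-0.7, 1.2, 0), O2 = c(-0.1, 2.3, 0),
    N1 = c(-2.1, 1.3, 0), C6 = c(-2.9, 0.2, 0), C5 = c(-2.3, -1.1, 0),
    C4 = c(-0.8, -1.2, 0)
  )
  b[[if (comp %in% c("DC", "C")) "N4" else "O4"]] <- c(-0.1, -2.4, 0)
  b
}

nucleotide_atoms <- function(comp) {
  is_pur <- comp %in% c("DA", "DG", "A", "G")
  base <- if (is_pur) purine_base(comp) else pyrimidine_base(comp)
  # attach sugar/phosphate trailing away from the pairing face
  sgn <- -1
  sugar <- list(
    "C1'" = c(sgn * 5.6, 0.9, 0.3), "O4'" = c(sgn * 6.3, -0.2, 0.5),
    "C3'" = c(sgn * 6.6, 1.9, -0.2), "O3'" = c(sgn * 6.8, 3.1, 0.4),
    "C5'" = c(sgn * 7.9, 0.6, -1.2), "O5'" = c(sgn * 8.6, 0.1, -0.1),
    P = c(sgn * 10.0, -0.5, -0.3), OP1 = c(sgn * 11.0, 0.4, 0.3),
    OP2 = c(sgn * 10.2, -1.8, 0.4)
  )
  if (comp %in% c("A", "C", "G", "U")) {
    sugar[["O2'"]] <- c(sgn * 6.9, 2.2, -1.6)
  }
  c(base, sugar)
}

element_of_name <- function(nm) str_sub(gsub("[^A-Z]", "", toupper(nm)), 1, 1)

rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), nrow = 3)
}

place_nucleotide <- function(chain_id, auth_seq, comp, flip = FALSE,
                             twist = 0, rise = 0, offset = c(0, 0, 0)) {
  tmpl <- nucleotide_atoms(comp)
  pair_gap <- 2.9 # purine N1 - pyrimidine N3 hydrogen-bond distance
  rows <- map(names(tmpl), function(nm) {
    p <- tmpl[[nm]]
    if (flip) p <- c(-p[1] + pair_gap, -p[2], p[3]) # mirror across pairing axis
    p <- as.numeric(rot_z(twist) %*% p) + c(0, 0, rise) + offset
    atom_row(chain_id, auth_seq, comp, nm, element_of_name(nm), p)
  })
  list_rbind(rows)
}

#' Generate an idealized B-form DNA duplex
#'
#' Two complementary antiparallel DNA chains with a 3.38 Angstrom rise and
#' 36 degree twist per base pair; each Watson-Crick pair has its purine N1
#' and pyrimidine N3 exactly 2.9 Angstrom apart. The matching
#' `_ndb_struct_na_base_pair` rows and full mmCIF text are produced
#' alongside, so the duplex round-trips through [read_structure()] and
#' [read_base_pairs()].
#'
#' @param n_bp Number of base pairs (>= 1).
#' @param chain_ids Ids of the two strands.
#' @param seq Optional base sequence of the first strand (characters from
#'   A, C, G, T); defaults to a repeating ACGT pattern.
#' @param offset Translation of the whole duplex.
#' @param entry_id Entry id written to the mmCIF.
#' @return A list: `structure` (a `struct_df` with the base pairs
#'   attached), `base_pairs` (tibble), `mmcif_text` (character vector of
#'   lines).
#' @export
#' @examples
#' dup <- make_duplex_dna(10)
#' nrow(base_pairs_of(dup$structure))
make_duplex_dna <- function(n_bp, chain_ids = c("B", "C"), seq = NULL,
                            offset = c(0, 0, 0), entry_id = "DUPLEX") {
  if (n_bp < 1) abort("n_bp must be >= 1")
  if (is.null(seq)) {
    seq <- rep(c("A", "C", "G", "T"), length.out = n_bp)
  }
  stopifnot(length(seq) == n_bp, all(seq %in% c("A", "C", "G", "T")))
  comp1 <- paste0("D", seq)
  comp_complement <- c(DA = "DT", DC = "DG", DG = "DC", DT = "DA")
  comp2 <- unname(comp_complement[comp1])

  s1 <- list()
  s2 <- list()
  for (i in seq_len(n_bp)) {
    twist <- (i - 1L) * 36 * pi / 180
    rise <- (i - 1L) * 3.38
    pur1 <- comp1[i] %in% c("DA", "DG")
    # the purine of the pair sits at the origin-facing position; its partner
    # is mirrored across the pairing axis
    s1[[i]] <- place_nucleotide(chain_ids[1], i, comp1[i], flip = !pur1,
                                twist = twist, rise = rise, offset = offset)
    s2[[i]] <- place_nucleotide(chain_ids[2], n_bp - i + 1L, comp2[i],
                                flip = pur1, twist = twist, rise = rise,
                                offset = offset)
  }
  # strand 2 atoms in its own 5'->3' residue order
  plan <- bind_rows(list_rbind(s1),
                    arrange(list_rbind(s2), as.integer(.data$auth_seq_id)))
  base_pairs <- tibble(
    chain_a = chain_ids[1], unit_a = as.character(seq_len(n_bp)),
    chain_b = chain_ids[2], unit_b = as.character(n_bp - seq_len(n_bp) + 1L)
  )
  structure <- fixture_structure(plan, entry_id = entry_id,
                                 base_pairs = base_pairs,
                                 source_format = "mmcif")
  list(structure = structure, base_pairs = base_pairs,
       mmcif_text = as_mmcif_text(structure))
}

#' Generate an idealized single nucleic-acid chain
#'
#' Nucleotides on a straight 7 Angstrom-spaced trace; useful for hairpins,
#' hybrid chains and RNA subunit tests.
#'
#' @param comps Character vector of component names (e.g. `c("A","U")` or
#'   `c("DA","DT")`; mixing the two alphabets gives a hybrid chain).
#' @inheritParams make_protein_chain
#' @export
make_nucleic_chain <- function(comps, chain_id = "N", start_auth = 1L,
                               offset = c(0, 0, 0)) {
  rows <- map(seq_along(comps), function(i) {
    place_nucleotide(chain_id, start_auth + i - 1L, comps[i],
                     offset = offset + c(0, 12 * 0, 7 * (i - 1L)))
  })
  list_rbind(rows)
}

#' Assemble chain plans into a structure
#'
#' Builds a `struct_df` (the same tidy atom table [read_structure()]
#' returns) from one or more chain plans produced by the generators in this
#' package.
#'
#' @param ... Chain plans (atom tibbles), or a single list of them.
#' @param entry_id Entry id of the synthetic structure.
#' @param base_pairs Optional base-pair tibble to attach.
#' @param source_format Label recorded as the source format.
#' @return A `struct_df`.
#' @export
fixture_structure <- function(..., entry_id = "FIXT", base_pairs = NULL,
                              source_format = "pdb") {
  plans <- list(...)
  if (length(plans) == 1L && !is.data.frame(plans[[1]])) plans <- plans[[1]]
  plan_cols <- c("chain_id", "auth_seq_id", "comp_id", "atom_name",
                 "element", "x", "y", "z")
  atoms <- list_rbind(map(plans, function(p) {
    as_tibble(p)[, plan_cols]
  }))
  atoms <- atoms |>
    mutate(
      unit_kind = unit_kind(.data$comp_id),
      occupancy = 1, alt_loc = "",
      is_heavy = is_heavy_element(.data$element)
    ) |>
    group_by(.data$chain_id) |>
    mutate(seq_index = match(.data$auth_seq_id, unique(.data$auth_seq_id)) - 1L) |>
    ungroup()
  chain_kinds <- atoms |>
    distinct(.data$chain_id, .data$seq_index, .data$unit_kind) |>
    group_by(.data$chain_id) |>
    summarise(polymer_kind = classify_polymer_kind(unit_kind = .data$unit_kind))
  atoms <- left_join(atoms, chain_kinds, by = "chain_id") |>
    select("chain_id", "seq_index", "auth_seq_id", "comp_id", "unit_kind",
           "polymer_kind", "atom_name", "element", "x", "y", "z",
           "occupancy", "alt_loc", "is_heavy")
  bp <- base_pairs %||% tibble(chain_a = character(), unit_a = character(),
                               chain_b = character(), unit_b = character())
  new_struct_df(atoms, entry_id = entry_id, source_format = source_format,
                base_pairs = bp)
}

#' Build a docked subunit pair with an exactly planned contact map
#'
#' Two chains are laid out on far-apart baselines (every unplanned unit
#' pair is hundreds of Angstrom apart); each planned contact is realised by
#' a dedicated pair of extra atoms placed exactly `distance` apart at an
#' isolated meeting point, so the brute-force contact map of the structure
#' equals the plan to within 1e-6 Angstrom by construction.
#'
#' @param n_a,n_b Units per chain.
#' @param planned Tibble with columns `i`, `j` (0-based unit indices into
#'   chain a / chain b) and `distance` (Angstrom); at most one row per
#'   unit pair.
#' @param kind `"protein"` (both chains protein), `"nucleic"` (both DNA) or
#'   `"protein_nucleic"` (chain a protein, chain b DNA). Meeting atoms are
#'   chosen so that they qualify under the corresponding contact
#'   definition (heavy-heavy, base-N vs heavy, or N-N).
#' @param chain_ids The two chain ids.
#' @return A list: `structure` (`struct_df`) and `expected` (the planned
#'   map as a tibble `seq_index_a`, `seq_index_b`, `distance`).
#' @export
#' @examples
#' dock <- make_docked_pair(5, 5, tibble::tibble(i = 0, j = 0, distance = 5))
#' dock$expected
make_docked_pair <- function(n_a, n_b, planned,
                             kind = c("protein", "nucleic",
                                      "protein_nucleic"),
                             chain_ids = c("A", "B")) {
  kind <- match.arg(kind)
  planned <- as_tibble(planned)
  stopifnot(all(planned$i >= 0), all(planned$i < n_a),
            all(planned$j >= 0), all(planned$j < n_b))
  if (anyDuplicated(planned[, c("i", "j")])) {
    abort("planned map has duplicate unit pairs")
  }
  if (any(planned$distance <= 0)) abort("planned distances must be positive")

  baseline_unit <- function(chain, idx, protein, y0) {
    if (protein) {
      bind_rows(
        atom_row(chain, idx + 1L, "ALA", "N", "N", c(20 * idx - 1.2, y0 + 0.8, 0)),
        atom_row(chain, idx + 1L, "ALA", "CA", "C", c(20 * idx, y0, 0)),
        atom_row(chain, idx + 1L, "ALA", "C", "C", c(20 * idx + 1.0, y0 + 0.9, 0)),
        atom_row(chain, idx + 1L, "ALA", "O", "O", c(20 * idx + 1.2, y0 + 2.0, 0))
      )
    } else {
      comp <- if (idx %% 2 == 0) "DA" else "DT"
      atom_row(chain, idx + 1L, comp, "C1'", "C", c(20 * idx, y0, 0))
    }
  }
  prot_a <- kind %in% c("protein", "protein_nucleic")
  prot_b <- kind == "protein"
  plan_a <- list_rbind(map(seq_len(n_a) - 1L, function(i)
    baseline_unit(chain_ids[1], i, prot_a, 0)))
  plan_b <- list_rbind(map(seq_len(n_b) - 1L, function(j)
    baseline_unit(chain_ids[2], j, prot_b, 600)))

  meet <- list()
  for (k in seq_len(nrow(planned))) {
    m <- c(60 * k, 300, 40)
    d <- planned$distance[k]
    if (prot_a) {
      a_atom <- atom_row(chain_ids[1], planned$i[k] + 1L, "ALA", "CG", "C", m)
    } else {
      comp <- if (planned$i[k] %% 2 == 0) "DA" else "DT"
      nm <- if (comp == "DA") "N1" else "N3"
      a_atom <- atom_row(chain_ids[1], planned$i[k] + 1L, comp, nm, "N", m)
    }
    if (prot_b) {
      b_atom <- atom_row(chain_ids[2], planned$j[k] + 1L, "ALA", "CG", "C",
                         m + c(0, 0, d))
    } else {
      comp <- if (planned$j[k] %% 2 == 0) "DA" else "DT"
      nm <- if (comp == "DA") "N1" else "N3"
      b_atom <- atom_row(chain_ids[2], planned$j[k] + 1L, comp, nm, "N",
                         m + c(0, 0, d))
    }
    meet[[k]] <- bind_rows(a_atom, b_atom)
  }
  extra <- if (length(meet)) list_rbind(meet) else NULL
  plan <- bind_rows(plan_a, plan_b, extra) |>
    arrange(.data$chain_id, as.integer(.data$auth_seq_id))
  structure <- fixture_structure(plan, entry_id = "DOCK")
  expected <- planned |>
    mutate(seq_index_a = as.integer(.data$i), seq_index_b = as.integer(.data$j)) |>
    select("seq_index_a", "seq_index_b", "distance") |>
    arrange(.data$seq_index_a, .data$seq_index_b)
  list(structure = structure, expected = expected)
}

#' Whole-chain subunit row for ad-hoc contact computations
#'
#' @param structure A `struct_df`.
#' @param chain Chain id.
#' @param subunit_kind Kind to assign (defaults to `undefined_chain` for
#'   protein chains, `dna`/`rna` for nucleic chains).
#' @export
whole_chain_subunit <- function(structure, chain, subunit_kind = NULL) {
  un <- units_of(structure) |> filter(.data$chain_id == chain)
  stopifnot(nrow(un) > 0L)
  kind <- subunit_kind %||% switch(un$polymer_kind[1],
    protein = "undefined_chain", dna = "dna", rna = "rna",
    abort("no default subunit kind for this chain")
  )
  su <- new_subunit_row(chain, kind,
                        tibble(start = min(un$seq_index),
                               end = max(un$seq_index)))
  su$label <- paste0(chain, "1")
  su
}

#' Random multi-chain complex for engine stress tests
#'
#' Draws 2-4 chains (protein, DNA or RNA) of random lengths with small
#' random atom clouds per unit, scaled so that a nontrivial number of
#' cross-chain contacts occur. Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param max_units Cap on the total unit count.
#' @return A `struct_df`.
#' @export
make_random_complex <- function(seed, max_units = 120L) {
  set.seed(seed)
  n_chains <- sample(2:4, 1)
  kinds <- sample(c("protein", "dna", "rna"), n_chains, replace = TRUE)
  per_chain <- pmax(3L, as.integer(stats::rmultinom(
    1, size = sample(seq(20L, max_units), 1), prob = rep(1, n_chains))))
  plans <- map(seq_len(n_chains), function(c_i) {
    cid <- LETTERS[c_i]
    n <- per_chain[c_i]
    # jittered random-walk trace keeps chains compact enough to touch
    steps <- matrix(stats::rnorm(3 * n, sd = 3), ncol = 3)
    centers <- apply(steps, 2, cumsum) +
      matrix(stats::runif(3, -8, 8), n, 3, byrow = TRUE)
    rows <- map(seq_len(n), function(i) {
      if (kinds[c_i] == "protein") {
        names_pool <- c("N", "CA", "C", "O", "CB")
        elements <- c("N", "C", "C", "O", "C")
        comp <- "GLY"
      } else {
        names_pool <- c("P", "O5'", "C1'", "N1", "N3", "O2", "N7")
        elements <- c("P", "O", "C", "N", "N", "O", "N")
        comp <- if (kinds[c_i] == "dna") {
          sample(c("DA", "DC", "DG", "DT"), 1)
        } else {
          sample(c("A", "C", "G", "U"), 1)
        }
      }
      n_at <- sample(2:length(names_pool), 1)
      pick <- sort(sample(seq_along(names_pool), n_at))
      list_rbind(map(pick, function(p) {
        atom_row(cid, i, comp, names_pool[p], elements[p],
                 centers[i, ] + stats::runif(3, -1.5, 1.5))
      }))
    })
    list_rbind(rows)
  })
  fixture_structure(plans, entry_id = sprintf("RND%d", seed))
}

#' Serialize a structure as mmCIF text
#'
#' Writes an `_atom_site` loop (label and author identifiers agree) and,
#' when the structure carries base pairs, an `_ndb_struct_na_base_pair`
#' loop.
#'
#' @param structure A `struct_df`.
#' @return Character vector of mmCIF lines.
#' @export
as_mmcif_text <- function(structure) {
  at <- as_tibble(structure)
  quote_name <- function(nm) if_else(str_detect(nm, "'"), paste0('"', nm, '"'), nm)
  resno <- str_match(at$auth_seq_id, "^(-?\\d+)")[, 2]
  ins <- str_match(at$auth_seq_id, "^-?\\d+(\\D*)$")[, 2]
  ins[is.na(ins) | ins == ""] <- "?"
  lines <- c(
    paste0("data_", attr(structure, "entry_id") %||% "FIXT"),
    "#",
    "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id", "auth_asym_id",
      "auth_atom_id", "pdbx_PDB_model_num"
    )),
    sprintf("ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %s %s %s %s 1",
            seq_len(nrow(at)), at$element, quote_name(at$atom_name),
            at$comp_id, at$chain_id, at$seq_index + 1L, ins,
            at$x, at$y, at$z, at$occupancy, resno, at$comp_id,
            at$chain_id, quote_name(at$atom_name)),
    "#"
  )
  bp <- base_pairs_of(structure)
  if (nrow(bp)) {
    lines <- c(lines,
      "loop_",
      paste0("_ndb_struct_na_base_pair.", c(
        "model_number", "i_auth_asym_id", "i_auth_seq_id",
        "j_auth_asym_id", "j_auth_seq_id", "pair_name"
      )),
      sprintf("1 %s %s %s %s %s_%s:%s_%s", bp$chain_a, bp$unit_a,
              bp$chain_b, bp$unit_b, bp$chain_a, bp$unit_a, bp$chain_b,
              bp$unit_b),
      "#"
    )
  }
  lines
}

#' Write a structure as an mmCIF file
#'
#' @inheritParams as_mmcif_text
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_mmcif <- function(structure, path) {
  writeLines(as_mmcif_text(structure), path)
  invisible(path)
}

#' Write domain assignments in the dir.cla dialect
#'
#' Inverse of [read_scop_cla()]: multi-segment assignments of one domain
#' are joined into a comma-separated range; `superfamily_predicted` rows
#' carry a trailing source token.
#'
#' @param assignments Assignment tibble (columns of [read_scop_cla()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scop_fixture <- function(assignments, path) {
  lines <- map_chr(
    split(assignments, factor(assignments$domain_id,
                              levels = unique(assignments$domain_id))),
    function(dom) {
      rng <- paste(map_chr(seq_len(nrow(dom)), function(k) {
        ch <- if (is.na(dom$chain_id[k])) "-" else dom$chain_id[k]
        if (is.na(dom$start_auth[k])) {
          if (ch == "-") "-" else paste0(ch, ":")
        } else {
          paste0(ch, ":", dom$start_auth[k], "-", dom$end_auth[k])
        }
      }), collapse = ",")
      base <- paste(dom$domain_id[1], tolower(dom$pdb_id[1]), rng,
                    dom$scop_family[1],
                    if (is.na(dom$sunid[1])) "0" else dom$sunid[1])
      if (identical(dom$source[1], "superfamily_predicted")) {
        paste(base, "superfamily_predicted")
      } else {
        base
      }
    }
  )
  writeLines(c("# synthetic domain assignments", lines), path)
  invisible(path)
}
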