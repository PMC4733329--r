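PROTEIN_SUBUNIT_KINDS <- c("domain", "linker", "c_terminal", "n_terminal",
                           "peptide", "undefined_chain")
NUCLEIC_SUBUNIT_KINDS <- c("dna", "rna")

empty_nodes <- function() {
  new_subunit_row("x", "domain", tibble(start = 0L, end = 0L))[0, ]
}

set_attrs <- function(x, ...) {
  dots <- list(...)
  for (nm in names(dots)) attr(x, nm) <- dots[[nm]]
  x
}

new_subunit_row <- function(chain_id, subunit_kind, segments,
                            scop_family = NA_character_,
                            scop_source = NA_character_,
                            domain_id = NA_character_,
                            unpaired = FALSE) {
  tibble(
    label = NA_character_,
    chain_id = chain_id,
    subunit_kind = subunit_kind,
    start_index = if (nrow(segments)) min(segments$start) else NA_integer_,
    end_index = if (nrow(segments)) max(segments$end) else NA_integer_,
    n_units = sum(segments$end - segments$start + 1L),
    segments = list(segments),
    domain_id = domain_id,
    scop_family = scop_family,
    scop_source = scop_source,
    unpaired = unpaired
  )
}

#' Read SCOP domain assignments (dir.cla dialect)
#'
#' Parses the tab/whitespace-separated classification-file dialect used by
#' the SCOP parseable files: columns are domain sid, PDB id, chain:range,
#' sccs family string, sunid, and an optional description. Comment lines
#' starting with `#` are skipped; malformed rows are skipped with a warning.
#' A multi-segment range such as `A:1-40,A:61-100` yields one row per
#' segment, all sharing the domain sid. Precomputed SUPERFAMILY predictions
#' may be supplied in the same dialect, either via `source =
#' "superfamily_predicted"` on a second file or as a trailing
#' `superfamily_predicted` token on individual rows.
#'
#' @param path Path to the assignment file.
#' @param source Default provenance for rows that do not carry their own:
#'   `"scop_curated"` or `"superfamily_predicted"`.
#' @return A tibble with one row per domain segment: `pdb_id`, `chain_id`
#'   (`NA` for a whole-structure range), `start_auth`, `end_auth` (`NA` for
#'   whole-chain), `domain_id`, `scop_family`, `sunid`, `source`.
#' @export
read_scop_cla <- function(path, source = c("scop_curated",
                                           "superfamily_predicted")) {
  source <- match.arg(source)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!str_detect(lines, "^\\s*(#|$)")]
  rows <- map(lines, parse_scop_cla_line, default_source = source)
  bad <- map_lgl(rows, is.null)
  if (any(bad)) {
    warn(sprintf("skipped %d malformed assignment row(s)", sum(bad)))
  }
  out <- list_rbind(rows[!bad])
  if (nrow(out) == 0L) {
    out <- tibble(pdb_id = character(), chain_id = character(),
                  start_auth = character(), end_auth = character(),
                  domain_id = character(), scop_family = character(),
                  sunid = character(), source = character())
  }
  out
}

parse_scop_cla_line <- function(line, default_source) {
  f <- str_split(str_trim(line), "\\s+")[[1]]
  if (length(f) < 4L || !nzchar(f[3])) return(NULL)
  src <- default_source
  if (any(f == "superfamily_predicted")) src <- "superfamily_predicted"
  if (any(f == "scop_curated")) src <- "scop_curated"
  segs <- str_split(f[3], ",")[[1]]
  parsed <- map(segs, function(s) {
    if (s == "-") {
      # whole-structure marker: any chain, whole chain
      return(tibble(chain_id = NA_character_, start_auth = NA_character_,
                    end_auth = NA_character_))
    }
    m <- str_match(s, "^([^:]+):(?:(-?\\d+[A-Za-z]?)-(-?\\d+[A-Za-z]?))?$")
    if (is.na(m[1, 1])) return(NULL)
    chain <- m[1, 2]
    if (chain == "-") chain <- NA_character_
    tibble(chain_id = chain, start_auth = m[1, 3], end_auth = m[1, 4])
  })
  if (any(map_lgl(parsed, is.null))) return(NULL)
  segs_tbl <- list_rbind(parsed)
  tibble(
    pdb_id = toupper(f[2]),
    chain_id = segs_tbl$chain_id,
    start_auth = segs_tbl$start_auth,
    end_auth = segs_tbl$end_auth,
    domain_id = f[1],
    scop_family = f[4],
    sunid = if (length(f) >= 5) f[5] else NA_character_,
    source = src
  )
}

#' Map domain assignments onto a protein chain
#'
#' Resolves author-numbered SCOP domain ranges onto the resolved residues of
#' one protein chain, in 0-based sequence coordinates. An assignment is
#' rejected (and reported in the `rejected` attribute) when either boundary
#' residue is absent from the structure - domain definitions routinely go
#' stale as entries are re-deposited. When resolved domains overlap, the
#' deterministic resolution is: curated beats predicted, then the longer
#' domain wins, then the smaller start index; losers are rejected with
#' reason `"overlap"`.
#'
#' @param structure A `struct_df`.
#' @param chain Chain id of a protein chain.
#' @param assignments Assignment tibble from [read_scop_cla()]. Rows are
#'   used when their `chain_id` matches (or is `NA`, a whole-structure
#'   range) and, if the structure's entry id looks like a PDB id, when
#'   `pdb_id` matches.
#' @return A tibble of `domain` subunit rows (multi-segment domains are one
#'   row with several `segments`), with attribute `rejected`.
#' @export
map_domains <- function(structure, chain, assignments) {
  ch_units <- units_of(structure) |> filter(.data$chain_id == chain)
  stopifnot(nrow(ch_units) > 0L)
  if (ch_units$polymer_kind[1] != "protein") {
    abort(paste0("chain ", chain, " is not a protein chain"))
  }
  empty <- new_subunit_row(chain, "domain",
                           tibble(start = integer(), end = integer()))[0, ]
  rejected <- tibble(domain_id = character(), reason = character())
  if (is.null(assignments) || nrow(assignments) == 0L) {
    return(set_attrs(empty, rejected = rejected))
  }

  entry <- toupper(attr(structure, "entry_id") %||% "")
  asg <- assignments |>
    filter(is.na(.data$chain_id) | .data$chain_id == chain)
  if (any(toupper(asg$pdb_id) == entry)) {
    asg <- filter(asg, toupper(.data$pdb_id) == entry)
  }
  if (nrow(asg) == 0L) return(set_attrs(empty, rejected = rejected))

  resolved <- list()
  for (dom in split(asg, paste(asg$domain_id, asg$source))) {
    segs <- vector("list", nrow(dom))
    ok <- TRUE
    for (k in seq_len(nrow(dom))) {
      if (is.na(dom$start_auth[k])) {
        segs[[k]] <- tibble(start = min(ch_units$seq_index),
                            end = max(ch_units$seq_index))
        next
      }
      i0 <- ch_units$seq_index[match(dom$start_auth[k], ch_units$auth_seq_id)]
      i1 <- ch_units$seq_index[match(dom$end_auth[k], ch_units$auth_seq_id)]
      if (is.na(i0) || is.na(i1) || i0 > i1) {
        ok <- FALSE
        break
      }
      segs[[k]] <- tibble(start = i0, end = i1)
    }
    if (!ok) {
      rejected <- bind_rows(rejected, tibble(domain_id = dom$domain_id[1],
                                             reason = "unmappable_range"))
      next
    }
    seg_tbl <- arrange(list_rbind(segs), .data$start)
    resolved[[length(resolved) + 1L]] <- new_subunit_row(
      chain, "domain", seg_tbl,
      scop_family = dom$scop_family[1], scop_source = dom$source[1],
      domain_id = dom$domain_id[1]
    )
  }
  if (length(resolved) == 0L) return(set_attrs(empty, rejected = rejected))
  spans <- list_rbind(resolved)

  # deterministic overlap resolution
  pri <- order(spans$scop_source != "scop_curated", -spans$n_units,
               spans$start_index, spans$domain_id)
  covered <- integer()
  keep <- logical(nrow(spans))
  for (i in pri) {
    pos <- subunit_positions(spans[i, ])
    if (any(pos %in% covered)) {
      rejected <- bind_rows(rejected, tibble(domain_id = spans$domain_id[i],
                                             reason = "overlap"))
    } else {
      keep[i] <- TRUE
      covered <- c(covered, pos)
    }
  }
  out <- arrange(spans[keep, ], .data$start_index)
  set_attrs(out, rejected = rejected)
}

#' Annotate the unstructured regions of a domain-bearing chain
#'
#' Every maximal run of residues not covered by a domain becomes exactly one
#' subunit: a `linker` when domains flank it on both sides, an `n_terminal`
#' when a domain lies only towards the C-side (right), a `c_terminal` when a
#' domain lies only towards the N-side (left). Together with the domains the
#' result tiles the chain with no gaps or overlaps.
#'
#' @inheritParams map_domains
#' @param domain_spans Domain rows from [map_domains()]; must contain at
#'   least one and must not overlap.
#' @return A tibble of unstructured subunit rows (possibly empty).
#' @export
annotate_unstructured <- function(structure, chain, domain_spans) {
  ch_units <- units_of(structure) |> filter(.data$chain_id == chain)
  stopifnot(nrow(ch_units) > 0L, nrow(domain_spans) >= 1L)
  pos_list <- map(seq_len(nrow(domain_spans)),
                  function(i) subunit_positions(domain_spans[i, ]))
  covered <- unlist(pos_list)
  if (anyDuplicated(covered)) abort("overlapping domain spans")
  all_pos <- sort(ch_units$seq_index)
  free <- setdiff(all_pos, covered)
  if (length(free) == 0L) return(domain_spans[0, ])

  runs <- split(free, cumsum(c(1L, diff(free) != 1L)))
  rows <- map(runs, function(run) {
    left <- any(covered < min(run))
    right <- any(covered > max(run))
    kind <- if (left && right) "linker" else if (right) "n_terminal" else "c_terminal"
    new_subunit_row(chain, kind, tibble(start = min(run), end = max(run)))
  })
  list_rbind(rows)
}

#' Classify a protein chain without any domain assignment
#'
#' @inheritParams map_domains
#' @param params [annotation_params()].
#' @return A single whole-chain subunit row: `peptide` when the chain has
#'   fewer resolved residues than `peptide_max_len` (default 20),
#'   `undefined_chain` otherwise.
#' @export
classify_undomained_chain <- function(structure, chain,
                                      params = annotation_params()) {
  ch_units <- units_of(structure) |> filter(.data$chain_id == chain)
  stopifnot(nrow(ch_units) > 0L)
  kind <- if (nrow(ch_units) < params$peptide_max_len) "peptide" else "undefined_chain"
  new_subunit_row(chain, kind,
                  tibble(start = min(ch_units$seq_index),
                         end = max(ch_units$seq_index)))
}

#' Identify DNA subunits
#'
#' Each DNA chain is one candidate subunit; it is retained for the default
#' interaction network only when at least one of its nucleotides is
#' base-paired with a nucleotide of a *different* DNA chain. Pairing is read
#' from the structure's `_ndb_struct_na_base_pair` records when present;
#' otherwise a geometric Watson-Crick test is used (complementary
#' nucleotides whose purine N1 to pyrimidine N3 distance is at most 3.5
#' Angstrom). Chains with no inter-chain pairing (e.g. a lone hairpin or
#' single-stranded DNA) are returned flagged `unpaired = TRUE` so callers
#' can opt in to keeping them.
#'
#' @param structure A `struct_df`.
#' @return A tibble with one whole-chain `dna` subunit row per DNA chain and
#'   an `unpaired` flag.
#' @export
identify_dna_subunits <- function(structure) {
  ch <- chains_of(structure) |> filter(.data$polymer_kind == "dna")
  if (nrow(ch) == 0L) return(new_subunit_row("x", "dna", tibble(start = 0L, end = 0L))[0, ])
  un <- units_of(structure)
  bp <- base_pairs_of(structure)
  dna_chains <- ch$chain_id

  paired <- character()
  if (nrow(bp) > 0L) {
    inter <- bp |> filter(.data$chain_a %in% dna_chains,
                          .data$chain_b %in% dna_chains,
                          .data$chain_a != .data$chain_b)
    paired <- unique(c(inter$chain_a, inter$chain_b))
  } else if (length(dna_chains) > 1L) {
    paired <- geometric_paired_dna_chains(structure, dna_chains)
  }

  rows <- map(dna_chains, function(cid) {
    u <- filter(un, .data$chain_id == cid)
    new_subunit_row(cid, "dna",
                    tibble(start = min(u$seq_index), end = max(u$seq_index)),
                    unpaired = !(cid %in% paired))
  })
  list_rbind(rows)
}

# Watson-Crick geometric fallback: two DNA chains count as paired when a
# complementary nucleotide pair has purine N1 - pyrimidine N3 <= 3.5 A.
geometric_paired_dna_chains <- function(structure, dna_chains,
                                        cutoff = 3.5) {
  at <- as_tibble(structure) |>
    filter(.data$chain_id %in% dna_chains)
  pur <- filter(at, .data$comp_id %in% c("DA", "DG"), .data$atom_name == "N1")
  pyr <- filter(at, .data$comp_id %in% c("DT", "DC", "DU"),
                .data$atom_name == "N3")
  if (nrow(pur) == 0L || nrow(pyr) == 0L) return(character())
  comp_ok <- outer(pur$comp_id, pyr$comp_id, function(a, b) {
    (a == "DA" & b %in% c("DT", "DU")) | (a == "DG" & b == "DC")
  })
  dx <- outer(pur$x, pyr$x, "-")
  dy <- outer(pur$y, pyr$y, "-")
  dz <- outer(pur$z, pyr$z, "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  hit <- comp_ok & d <= cutoff + DIST_TOL &
    outer(pur$chain_id, pyr$chain_id, "!=")
  idx <- which(hit, arr.ind = TRUE)
  unique(c(pur$chain_id[idx[, 1]], pyr$chain_id[idx[, 2]]))
}

#' Identify RNA subunits
#'
#' Each RNA chain is one whole-chain subunit. Hybrid chains (both DNA and
#' RNA bases on one chain) yield nothing and are reported in the
#' `hybrid_chains` attribute; they take part in no interaction.
#'
#' @inheritParams identify_dna_subunits
#' @return A tibble of `rna` subunit rows with attribute `hybrid_chains`.
#' @export
identify_rna_subunits <- function(structure) {
  ch <- chains_of(structure)
  un <- units_of(structure)
  rows <- map(ch$chain_id[ch$polymer_kind == "rna"], function(cid) {
    u <- filter(un, .data$chain_id == cid)
    new_subunit_row(cid, "rna",
                    tibble(start = min(u$seq_index), end = max(u$seq_index)))
  })
  out <- if (length(rows)) list_rbind(rows) else
    new_subunit_row("x", "rna", tibble(start = 0L, end = 0L))[0, ]
  set_attrs(out, hybrid_chains = ch$chain_id[ch$polymer_kind == "hybrid"])
}

#' Dissect a structure into its eight subunit types
#'
#' Runs the full four-stage annotation: SCOP domains are mapped onto each
#' protein chain; the remaining regions become linkers and N-/C-terminal
#' subunits; undomained chains become peptides (< `peptide_max_len`
#' residues) or undefined chains; DNA chains paired with another DNA chain
#' and RNA chains become whole-chain nucleic subunits. Every subunit gets a
#' label `chain letter + ordinal` (e.g. `"A2"`) in sequence order along its
#' chain.
#'
#' @param structure A `struct_df`.
#' @param assignments Optional assignment tibble from [read_scop_cla()].
#' @param params [annotation_params()].
#' @return A tibble of subunit rows (columns `label`, `chain_id`,
#'   `subunit_kind`, `start_index`, `end_index`, `n_units`, `segments`,
#'   `domain_id`, `scop_family`, `scop_source`, `unpaired`), with attributes
#'   `rejected_domains` and `hybrid_chains`.
#' @export
#' @examples
#' s <- fixture_structure(make_protein_chain(30, chain_id = "A"))
#' annotate_structure(s)
annotate_structure <- function(structure, assignments = NULL,
                               params = annotation_params()) {
  ch <- chains_of(structure)
  rejected <- tibble(chain_id = character(), domain_id = character(),
                     reason = character())
  out <- list()
  for (cid in ch$chain_id[ch$polymer_kind == "protein"]) {
    doms <- map_domains(structure, cid, assignments)
    rej <- attr(doms, "rejected")
    if (nrow(rej)) rejected <- bind_rows(rejected, mutate(rej, chain_id = cid))
    spans <- if (nrow(doms) == 0L) {
      classify_undomained_chain(structure, cid, params)
    } else {
      bind_rows(doms, annotate_unstructured(structure, cid, doms))
    }
    out[[length(out) + 1L]] <- spans
  }
  out[[length(out) + 1L]] <- identify_dna_subunits(structure)
  rna <- identify_rna_subunits(structure)
  out[[length(out) + 1L]] <- rna

  spans <- list_rbind(out)
  if (nrow(spans)) {
    spans <- spans |>
      arrange(.data$chain_id, .data$start_index) |>
      group_by(.data$chain_id) |>
      mutate(label = paste0(.data$chain_id, row_number())) |>
      ungroup()
  }
  set_attrs(spans,
            rejected_domains = rejected,
            hybrid_chains = attr(rna, "hybrid_chains"))
}
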