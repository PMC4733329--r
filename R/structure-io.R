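#' Read a macromolecular structure into a tidy atom table
#'
#' Parses a PDB or mmCIF file and returns one row per atom of every polymer
#' chain of the first model. Water and free ligands are excluded; modified
#' residues that occupy polymer positions (e.g. MSE) are kept. Hydrogen and
#' deuterium atoms are retained but flagged `is_heavy = FALSE`. When a
#' residue has alternate locations, the highest-occupancy location is kept
#' (ties broken by the alphabetically first altloc code). For NMR-style
#' multi-model files only model 1 is used. mmCIF chains are identified by
#' their author asym ids so that PDB and mmCIF parses of one entry agree.
#'
#' For mmCIF input any `_ndb_struct_na_base_pair` category is read alongside
#' the coordinates and attached to the result (see [read_base_pairs()]);
#' rows referencing residues absent from the coordinates are dropped with a
#' warning.
#'
#' @param path Path to a PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param format `"auto"` (default; by extension, then content), `"pdb"` or
#'   `"mmcif"`.
#' @return A tibble of class `struct_df` with columns `chain_id`,
#'   `seq_index` (0-based, gap-free within each chain), `auth_seq_id`
#'   (author number plus insertion code), `comp_id`, `unit_kind`,
#'   `polymer_kind`, `atom_name`, `element`, `x`, `y`, `z`, `occupancy`,
#'   `alt_loc`, `is_heavy`, and attributes `entry_id`, `source_format` and
#'   `base_pairs` (a tibble, possibly empty).
#' @seealso [units_of()], [chains_of()], [read_base_pairs()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("structure file not found: ", path))
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) {
      "mmcif"
    } else if (ext %in% c("pdb", "ent")) {
      "pdb"
    } else {
      first <- readLines(path, n = 1L, warn = FALSE)
      if (str_detect(first, "^data_")) "mmcif" else "pdb"
    }
  }

  raw <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb2(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    },
    error = function(e) {
      abort(paste0("failed to parse ", format, " file '", path, "': ",
                   conditionMessage(e)))
    }
  )

  atoms <- as_tibble(raw$atom)
  # bio3d's cif reader leaves CIF quoting on atom names like "C1'"
  atoms$elety <- gsub("^[\"']|[\"']$", "", atoms$elety)
  n_model_atoms <- if (is.matrix(raw$xyz)) ncol(raw$xyz) %/% 3L else length(raw$xyz) %/% 3L
  if (nrow(atoms) > n_model_atoms) atoms <- atoms[seq_len(n_model_atoms), ]

  atoms <- atoms |>
    mutate(
      chain_id = as.character(.data$chain),
      chain_id = if_else(is.na(.data$chain_id), " ", .data$chain_id),
      comp_id = toupper(trimws(as.character(.data$resid))),
      atom_name = trimws(as.character(.data$elety)),
      alt_loc = if_else(is.na(.data$alt), "", as.character(.data$alt)),
      insert = if_else(is.na(.data$insert), "", as.character(.data$insert)),
      auth_seq_id = paste0(.data$resno, .data$insert),
      occupancy = if_else(is.na(.data$o), 1, as.numeric(.data$o)),
      element = toupper(trimws(as.character(.data$elesy)))
    )
  atoms$element <- if_else(
    is.na(atoms$element) | atoms$element == "",
    infer_element(atoms$atom_name), atoms$element
  )
  atoms$unit_kind <- unit_kind(atoms$comp_id)
  atoms <- filter(atoms, .data$unit_kind != "other")
  if (nrow(atoms) == 0L) {
    abort(paste0("no polymer chains found in '", path, "'"))
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite atom coordinates encountered")
  }

  atoms <- resolve_alt_locs(atoms)

  # dense 0-based residue index per chain, in file order
  atoms <- atoms |>
    group_by(.data$chain_id) |>
    mutate(seq_index = match(.data$auth_seq_id, unique(.data$auth_seq_id)) - 1L) |>
    ungroup()

  chain_kinds <- atoms |>
    distinct(.data$chain_id, .data$seq_index, .data$unit_kind) |>
    group_by(.data$chain_id) |>
    summarise(polymer_kind = classify_polymer_kind(unit_kind = .data$unit_kind))
  atoms <- left_join(atoms, chain_kinds, by = "chain_id")

  atoms <- atoms |>
    mutate(is_heavy = is_heavy_element(.data$element)) |>
    select(
      "chain_id", "seq_index", "auth_seq_id", "comp_id", "unit_kind",
      "polymer_kind", "atom_name", "element", "x", "y", "z",
      "occupancy", "alt_loc", "is_heavy"
    )

  entry_id <- structure_entry_id(path, format)
  bp <- tibble(chain_a = character(), unit_a = character(),
               chain_b = character(), unit_b = character())
  if (format == "mmcif") {
    bp <- read_base_pairs(path)
    bp <- validate_base_pairs(bp, atoms)
  }

  new_struct_df(atoms, entry_id = entry_id, source_format = format,
                base_pairs = bp)
}

new_struct_df <- function(atoms, entry_id, source_format, base_pairs) {
  out <- as_tibble(atoms)
  attr(out, "entry_id") <- entry_id
  attr(out, "source_format") <- source_format
  attr(out, "base_pairs") <- base_pairs
  class(out) <- c("struct_df", class(out))
  out
}

structure_entry_id <- function(path, format) {
  first <- tryCatch(readLines(path, n = 5L, warn = FALSE),
                    error = function(e) character())
  if (format == "mmcif") {
    hit <- str_match(first, "^data_(\\S+)")[, 2]
    hit <- hit[!is.na(hit)]
    if (length(hit)) return(hit[[1]])
  } else {
    hdr <- first[str_detect(first, "^HEADER")]
    if (length(hdr)) {
      id <- str_trim(str_sub(hdr[[1]], 63, 66))
      if (nzchar(id)) return(id)
    }
  }
  toupper(tools::file_path_sans_ext(basename(path)))
}

# keep the highest-occupancy alternate location per atom; ties go to the
# alphabetically first altloc code ("" sorts before "A")
resolve_alt_locs <- function(atoms) {
  if (!any(atoms$alt_loc != "")) return(atoms)
  atoms |>
    mutate(.ord = row_number()) |>
    group_by(.data$chain_id, .data$auth_seq_id, .data$atom_name) |>
    arrange(dplyr::desc(.data$occupancy), .data$alt_loc, .by_group = TRUE) |>
    filter(row_number() == 1L | all(.data$alt_loc == "")) |>
    ungroup() |>
    arrange(.data$.ord) |>
    select(-".ord")
}

#' Classify the polymer kind of one chain
#'
#' A chain is `protein` when it has amino-acid units and no nucleotides;
#' `dna` when its nucleotides are all deoxyribonucleotides; `rna` when all
#' ribonucleotides; `hybrid` when both DNA and RNA bases occur on the one
#' chain; `other` otherwise. Depends only on the set of unit kinds present,
#' never on their order.
#'
#' @param units A data frame with a `unit_kind` column (one row per polymer
#'   unit of a single chain), or `NULL` when `unit_kind` is given directly.
#' @param unit_kind Optional character vector of unit kinds.
#' @return One of `"protein"`, `"dna"`, `"rna"`, `"hybrid"`, `"other"`.
#' @export
#' @examples
#' classify_polymer_kind(unit_kind = c("dna_nucleotide", "dna_nucleotide"))
#' classify_polymer_kind(unit_kind = c("dna_nucleotide", "rna_nucleotide"))
classify_polymer_kind <- function(units = NULL, unit_kind = NULL) {
  kinds <- unit_kind %||% units$unit_kind
  stopifnot(length(kinds) >= 1)
  has_aa <- any(kinds == "amino_acid")
  has_dna <- any(kinds == "dna_nucleotide")
  has_rna <- any(kinds == "rna_nucleotide")
  if (has_dna && has_rna) return("hybrid")
  if (has_aa && !has_dna && !has_rna) return("protein")
  if (has_dna && !has_aa) return("dna")
  if (has_rna && !has_aa) return("rna")
  "other"
}

#' Polymer units of a structure
#'
#' @param structure A `struct_df` from [read_structure()] or
#'   [fixture_structure()].
#' @return A tibble with one row per polymer unit: `chain_id`, `seq_index`,
#'   `auth_seq_id`, `comp_id`, `unit_kind`, `polymer_kind`, `n_atoms`,
#'   `n_heavy`.
#' @export
units_of <- function(structure) {
  structure |>
    as_tibble() |>
    group_by(.data$chain_id, .data$seq_index, .data$auth_seq_id,
             .data$comp_id, .data$unit_kind, .data$polymer_kind) |>
    summarise(n_atoms = n(), n_heavy = sum(.data$is_heavy), .groups = "drop") |>
    arrange(.data$chain_id, .data$seq_index)
}

#' Chains of a structure
#'
#' @inheritParams units_of
#' @return A tibble with one row per chain: `chain_id`, `polymer_kind`,
#'   `n_units`.
#' @export
chains_of <- function(structure) {
  units_of(structure) |>
    group_by(.data$chain_id, .data$polymer_kind) |>
    summarise(n_units = n(), .groups = "drop")
}

#' Base pairs recorded in a structure
#'
#' @inheritParams units_of
#' @return The base-pair tibble attached at parse time (empty for plain PDB
#'   input).
#' @export
base_pairs_of <- function(structure) {
  attr(structure, "base_pairs") %||%
    tibble(chain_a = character(), unit_a = character(),
           chain_b = character(), unit_b = character())
}

#' @export
print.struct_df <- function(x, ...) {
  ch <- chains_of(x)
  cat(sprintf(
    "<structure %s> %d chains, %d units, %d atoms (%s source, %d base pairs)\n",
    attr(x, "entry_id") %||% "?", nrow(ch), nrow(units_of(x)), nrow(x),
    attr(x, "source_format") %||% "?", nrow(base_pairs_of(x))
  ))
  print(ch)
  invisible(x)
}
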