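#' Read nucleic-acid base-pair records from an mmCIF file
#'
#' Extracts the `_ndb_struct_na_base_pair` category, which lists the
#' base-paired nucleotide pairs of a structure as annotated by the wwPDB.
#' Chains and residues are identified by author ids so they match the
#' coordinate table of [read_structure()]. A file without the category
#' yields an empty tibble (this is not an error: the category is optional).
#'
#' @param path Path to an mmCIF file, or a character vector of mmCIF lines.
#' @return A tibble with columns `chain_a`, `unit_a`, `chain_b`, `unit_b`
#'   (author chain id and author residue number of each partner).
#' @export
read_base_pairs <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    as.character(path)
  }
  cat_rows <- read_cif_category(lines, "_ndb_struct_na_base_pair")
  empty <- tibble(chain_a = character(), unit_a = character(),
                  chain_b = character(), unit_b = character())
  if (is.null(cat_rows) || nrow(cat_rows) == 0L) return(empty)

  pick <- function(auth, label) {
    if (auth %in% names(cat_rows)) cat_rows[[auth]] else cat_rows[[label]]
  }
  need <- function(auth, label) {
    if (!(auth %in% names(cat_rows)) && !(label %in% names(cat_rows))) {
      warn(paste0("base-pair category lacks both ", auth, " and ", label,
                  "; ignoring category"))
      return(FALSE)
    }
    TRUE
  }
  ok <- need("i_auth_asym_id", "i_label_asym_id") &&
    need("i_auth_seq_id", "i_label_seq_id") &&
    need("j_auth_asym_id", "j_label_asym_id") &&
    need("j_auth_seq_id", "j_label_seq_id")
  if (!ok) return(empty)

  tibble(
    chain_a = pick("i_auth_asym_id", "i_label_asym_id"),
    unit_a  = pick("i_auth_seq_id", "i_label_seq_id"),
    chain_b = pick("j_auth_asym_id", "j_label_asym_id"),
    unit_b  = pick("j_auth_seq_id", "j_label_seq_id")
  )
}

# Minimal mmCIF loop reader for one category. Handles whitespace-delimited
# rows with single/double-quoted tokens; enough for the base-pair category,
# which no installed reader exposes.
read_cif_category <- function(lines, category) {
  tag_re <- paste0("^", category, "\\.")
  tag_idx <- which(str_detect(lines, tag_re))
  if (length(tag_idx) == 0L) return(NULL)

  # locate enclosing loop_
  loop_starts <- which(str_detect(str_trim(lines), "^loop_$"))
  this_loop <- max(loop_starts[loop_starts < tag_idx[1]])
  i <- this_loop + 1L
  tags <- character()
  while (i <= length(lines) && str_detect(str_trim(lines[i]), "^_")) {
    tags <- c(tags, str_trim(lines[i]))
    i <- i + 1L
  }
  fields <- sub(paste0("^", category, "\\."), "", tags)
  values <- character()
  while (i <= length(lines)) {
    ln <- str_trim(lines[i])
    if (ln == "" || str_detect(ln, "^(#|loop_|_|data_)")) break
    values <- c(values, scan(text = lines[i], what = character(),
                             quiet = TRUE, quote = "'\""))
    i <- i + 1L
  }
  if (length(values) == 0L || length(values) %% length(tags) != 0L) {
    if (length(values)) warn(paste0("ragged ", category, " loop; ignored"))
    return(NULL)
  }
  m <- matrix(values, ncol = length(tags), byrow = TRUE)
  out <- as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
  names(out) <- fields
  out
}

# drop base-pair rows whose residues are absent from the parsed coordinates
validate_base_pairs <- function(bp, atoms) {
  if (nrow(bp) == 0L) return(bp)
  key <- unique(paste(atoms$chain_id, atoms$auth_seq_id))
  nt <- atoms$unit_kind %in% c("dna_nucleotide", "rna_nucleotide")
  nt_key <- unique(paste(atoms$chain_id[nt], atoms$auth_seq_id[nt]))
  ok <- paste(bp$chain_a, bp$unit_a) %in% nt_key &
    paste(bp$chain_b, bp$unit_b) %in% nt_key
  if (any(!ok)) {
    warn(sprintf("dropping %d base-pair record(s) referencing absent residues",
                 sum(!ok)))
  }
  bp[ok, ]
}
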