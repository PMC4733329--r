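KIND_LETTER <- c(
  domain = "D", c_terminal = "C", n_terminal = "N", linker = "L",
  undefined_chain = "U", peptide = "P", dna = "DNA", rna = "RNA"
)
KIND_ORDER <- c("D", "C", "N", "L", "U", "P", "DNA", "RNA")

#' The 36 subunit-subunit interaction types
#'
#' Eight subunit kinds - domain (D), C-terminus (C), N-terminus (N),
#' inter-domain linker (L), undefined chain (U), peptide (P), DNA and RNA -
#' give 8 self-pairs plus 28 cross-pairs: 36 unordered interaction types.
#' Codes are canonicalized by the fixed kind ordering D, C, N, L, U, P,
#' DNA, RNA (so a linker-RNA interaction is coded `"L-RNA"`;
#' [normalize_type_code()] accepts either orientation).
#'
#' @return A tibble with columns `code`, `kind_a`, `kind_b` (36 rows).
#' @export
#' @examples
#' nrow(enumerate_interaction_types())
enumerate_interaction_types <- function() {
  idx <- which(upper.tri(diag(8), diag = TRUE), arr.ind = TRUE)
  tibble(
    kind_a = names(KIND_LETTER)[idx[, 1]],
    kind_b = names(KIND_LETTER)[idx[, 2]],
    code = paste0(KIND_ORDER[idx[, 1]], "-", KIND_ORDER[idx[, 2]])
  ) |>
    arrange(match(.data$code, paste0(
      rep(KIND_ORDER, times = 8), "-",
      rep(KIND_ORDER, each = 8)
    ))) |>
    select("code", "kind_a", "kind_b")
}

#' Canonical interaction-type code for a pair of subunit kinds
#'
#' @param kind_a,kind_b Subunit kinds (e.g. `"domain"`, `"rna"`).
#' @return A code such as `"D-D"` or `"D-RNA"`.
#' @export
interaction_type_code <- function(kind_a, kind_b) {
  la <- KIND_LETTER[[kind_a]]
  lb <- KIND_LETTER[[kind_b]]
  ord <- order(match(c(la, lb), KIND_ORDER))
  paste(c(la, lb)[ord], collapse = "-")
}

#' Normalize an interaction-type code
#'
#' Accepts a code in either orientation (`"RNA-L"` or `"L-RNA"`) and
#' returns the canonical form.
#'
#' @param code Character vector of codes.
#' @return Canonical codes; `NA` for unknown kind letters.
#' @export
#' @examples
#' normalize_type_code("RNA-L")
normalize_type_code <- function(code) {
  map_chr(code, function(cd) {
    parts <- str_split(cd, "-")[[1]]
    if (length(parts) != 2L || !all(parts %in% KIND_ORDER)) {
      return(NA_character_)
    }
    paste(parts[order(match(parts, KIND_ORDER))], collapse = "-")
  })
}

#' Build the subunit interaction network of a structure
#'
#' Annotates the structure into subunits (the network's nodes) and tests
#' every unordered pair of subunits for a binary interaction (the edges).
#' Hybrid nucleotide chains never enter the network; DNA chains with no
#' inter-chain base pairing are excluded unless `include_unpaired_dna =
#' TRUE`. Subunits whose contacts stay below the minimum-pair threshold
#' remain as disconnected nodes.
#'
#' @param structure A `struct_df`.
#' @param assignments Optional SCOP assignments ([read_scop_cla()]).
#' @param params [contact_params()].
#' @param annotation [annotation_params()].
#' @param include_unpaired_dna Keep DNA chains that pair with no other DNA
#'   chain? Default `FALSE`.
#' @return An `interaction_network`: list with `entry_id`, `nodes`
#'   (subunit tibble), `edges` (one row per binary interaction, contact
#'   pairs in a list column) and `params`.
#' @export
#' @examples
#' s <- fixture_structure(
#'   make_protein_chain(30, chain_id = "A"),
#'   make_protein_chain(15, chain_id = "B", offset = c(4, 0, 0))
#' )
#' net <- build_network(s)
#' glance(net)
build_network <- function(structure, assignments = NULL,
                          params = contact_params(),
                          annotation = annotation_params(),
                          include_unpaired_dna = FALSE) {
  nodes <- annotate_structure(structure, assignments, annotation)
  if (!include_unpaired_dna && nrow(nodes)) {
    nodes <- filter(nodes, !.data$unpaired)
  }
  edges <- empty_edges()
  if (nrow(nodes) >= 2L) {
    idx <- combn(nrow(nodes), 2L)
    found <- map(seq_len(ncol(idx)), function(k) {
      detect_interaction(structure, nodes[idx[1, k], ], nodes[idx[2, k], ],
                         params)
    })
    found <- found[!map_lgl(found, is.null)]
    if (length(found)) edges <- list_rbind(found)
  }
  base::structure(
    list(
      entry_id = attr(structure, "entry_id") %||% "UNKNOWN",
      nodes = nodes,
      edges = edges,
      params = list(contact = unclass(params),
                    annotation = unclass(annotation),
                    include_unpaired_dna = include_unpaired_dna)
    ),
    class = "interaction_network"
  )
}

empty_edges <- function() {
  tibble(
    label_a = character(), label_b = character(),
    kind_a = character(), kind_b = character(),
    interaction_type = character(), n_pairs = integer(),
    is_intra_chain = logical(), contacts = list()
  )
}

#' Per-type interaction counts of a network
#'
#' @param network An `interaction_network`.
#' @return A 36-row tibble (`code`, `kind_a`, `kind_b`, `n`) whose counts
#'   sum to the number of edges.
#' @export
network_summary <- function(network) {
  types <- enumerate_interaction_types()
  counts <- count(network$edges, code = .data$interaction_type)
  types |>
    left_join(counts, by = "code") |>
    mutate(n = if_else(is.na(.data$n), 0L, .data$n))
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction network %s> %d subunits, %d interactions\n",
              x$entry_id, nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    sm <- filter(network_summary(x), .data$n > 0)
    cat("  ", paste0(sm$code, ":", sm$n, collapse = "  "), "\n")
  }
  invisible(x)
}

#' @describeIn build_network One row per binary interaction (without the
#'   contact list column).
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.interaction_network <- function(x, ...) {
  select(x$edges, -"contacts")
}

#' @describeIn build_network One-row network summary.
#' @exportS3Method generics::glance
glance.interaction_network <- function(x, ...) {
  tibble(
    entry_id = x$entry_id,
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_types = dplyr::n_distinct(x$edges$interaction_type),
    n_intra_chain = sum(x$edges$is_intra_chain),
    n_contact_pairs = sum(x$edges$n_pairs)
  )
}

#' Plot a subunit interaction network
#'
#' Nodes on a circle, coloured by subunit kind; edge width scales with the
#' number of contact pairs.
#'
#' @param object An `interaction_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.interaction_network <- function(object, ...) {
  nodes <- object$nodes
  if (nrow(nodes) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  theta <- seq(0, 2 * pi, length.out = nrow(nodes) + 1L)[seq_len(nrow(nodes))]
  lay <- mutate(nodes, xx = cos(theta), yy = sin(theta))
  p <- ggplot2::ggplot()
  if (nrow(object$edges)) {
    seg <- object$edges |>
      left_join(select(lay, "label", ax = "xx", ay = "yy"),
                by = c(label_a = "label")) |>
      left_join(select(lay, "label", bx = "xx", by_ = "yy"),
                by = c(label_b = "label"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$ax, y = .data$ay, xend = .data$bx,
                   yend = .data$by_, linewidth = .data$n_pairs),
      colour = "grey60"
    ) +
      ggplot2::scale_linewidth(range = c(0.3, 2), guide = "none")
  }
  p +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(.data$xx, .data$yy,
                                     colour = .data$subunit_kind), size = 5) +
    ggplot2::geom_text(data = lay,
                       ggplot2::aes(.data$xx * 1.15, .data$yy * 1.15,
                                    label = .data$label), size = 3) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::labs(colour = "subunit kind", title = object$entry_id) +
    ggplot2::theme_void()
}
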