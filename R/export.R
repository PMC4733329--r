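#' Export an interaction network
#'
#' Writes the network as JSON (lossless: [read_network_json()] reconstructs
#' nodes, edges, contact pairs and parameters), GraphML (nodes with kind and
#' label, edges with type code and pair count), or a TSV edge list.
#'
#' @param network An `interaction_network`.
#' @param format `"json"`, `"graphml"` or `"tsv"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, format = c("json", "graphml", "tsv"),
                           path) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(paste0(
                       "unknown export format '", format[1],
                       "' (use json, graphml or tsv)")))
  switch(format,
    json = export_network_json(network, path),
    graphml = export_network_graphml(network, path),
    tsv = export_network_tsv(network, path)
  )
  invisible(path)
}

export_network_json <- function(network, path) {
  nodes <- network$nodes
  payload <- list(
    entry_id = network$entry_id,
    params = network$params,
    nodes = map(seq_len(nrow(nodes)), function(i) {
      r <- nodes[i, ]
      list(
        label = r$label, chain_id = r$chain_id,
        subunit_kind = r$subunit_kind,
        start_index = r$start_index, end_index = r$end_index,
        n_units = r$n_units,
        segments = as.list(r$segments[[1]]),
        domain_id = r$domain_id, scop_family = r$scop_family,
        scop_source = r$scop_source, unpaired = r$unpaired
      )
    }),
    edges = map(seq_len(nrow(network$edges)), function(i) {
      e <- network$edges[i, ]
      list(
        label_a = e$label_a, label_b = e$label_b,
        kind_a = e$kind_a, kind_b = e$kind_b,
        interaction_type = e$interaction_type,
        n_pairs = e$n_pairs, is_intra_chain = e$is_intra_chain,
        contacts = as.list(e$contacts[[1]])
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
}

#' Read a JSON network export back
#'
#' @param path Path written by [export_network()] with `format = "json"`.
#' @return An `interaction_network`.
#' @export
read_network_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- list_rbind(map(p$nodes, function(nd) {
    tibble(
      label = nd$label, chain_id = nd$chain_id,
      subunit_kind = nd$subunit_kind,
      start_index = as.integer(nd$start_index),
      end_index = as.integer(nd$end_index),
      n_units = as.integer(nd$n_units),
      segments = list(tibble(start = as.integer(unlist(nd$segments$start)),
                             end = as.integer(unlist(nd$segments$end)))),
      domain_id = nd$domain_id %||% NA_character_,
      scop_family = nd$scop_family %||% NA_character_,
      scop_source = nd$scop_source %||% NA_character_,
      unpaired = isTRUE(nd$unpaired)
    )
  }))
  edges <- map(p$edges, function(e) {
    ct <- e$contacts
    tibble(
      label_a = e$label_a, label_b = e$label_b,
      kind_a = e$kind_a, kind_b = e$kind_b,
      interaction_type = e$interaction_type,
      n_pairs = as.integer(e$n_pairs),
      is_intra_chain = isTRUE(e$is_intra_chain),
      contacts = list(tibble(
        chain_a = as.character(unlist(ct$chain_a)),
        seq_index_a = as.integer(unlist(ct$seq_index_a)),
        auth_seq_a = as.character(unlist(ct$auth_seq_a)),
        comp_a = as.character(unlist(ct$comp_a)),
        atom_a = as.character(unlist(ct$atom_a)),
        chain_b = as.character(unlist(ct$chain_b)),
        seq_index_b = as.integer(unlist(ct$seq_index_b)),
        auth_seq_b = as.character(unlist(ct$auth_seq_b)),
        comp_b = as.character(unlist(ct$comp_b)),
        atom_b = as.character(unlist(ct$atom_b)),
        min_distance = as.numeric(unlist(ct$min_distance))
      ))
    )
  })
  edges <- if (length(edges)) list_rbind(edges) else empty_edges()
  pr <- p$params
  base::structure(
    list(
      entry_id = p$entry_id,
      nodes = if (is.null(nodes)) empty_nodes() else nodes,
      edges = edges,
      params = list(
        contact = pr$contact, annotation = pr$annotation,
        include_unpaired_dna = isTRUE(pr$include_unpaired_dna)
      )
    ),
    class = "interaction_network"
  )
}

export_network_graphml <- function(network, path) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  keydefs <- list(
    c(id = "kind", `for` = "node", attr.name = "subunit_kind",
      attr.type = "string"),
    c(id = "chain", `for` = "node", attr.name = "chain_id",
      attr.type = "string"),
    c(id = "type", `for` = "edge", attr.name = "interaction_type",
      attr.type = "string"),
    c(id = "npairs", `for` = "edge", attr.name = "n_pairs",
      attr.type = "int")
  )
  for (kd in keydefs) {
    k <- xml2::xml_add_child(doc, "key")
    for (nm in names(kd)) xml2::xml_set_attr(k, nm, kd[[nm]])
  }
  g <- xml2::xml_add_child(doc, "graph", id = network$entry_id,
                           edgedefault = "undirected")
  for (i in seq_len(nrow(network$nodes))) {
    r <- network$nodes[i, ]
    nd <- xml2::xml_add_child(g, "node", id = r$label)
    xml2::xml_add_child(nd, "data", key = "kind", r$subunit_kind)
    xml2::xml_add_child(nd, "data", key = "chain", r$chain_id)
  }
  for (i in seq_len(nrow(network$edges))) {
    e <- network$edges[i, ]
    ed <- xml2::xml_add_child(g, "edge", source = e$label_a,
                              target = e$label_b)
    xml2::xml_add_child(ed, "data", key = "type", e$interaction_type)
    xml2::xml_add_child(ed, "data", key = "npairs",
                        as.character(e$n_pairs))
  }
  xml2::write_xml(doc, path)
}

export_network_tsv <- function(network, path) {
  readr::write_tsv(tidy(network), path)
}

#' Export a subunit table as TSV
#'
#' Label, chain, kind, sequence bounds and SCOP family of every subunit.
#'
#' @param nodes Subunit tibble ([annotate_structure()] or a network's
#'   `nodes`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_subunits <- function(nodes, path) {
  readr::write_tsv(select(nodes, -"segments"), path)
  invisible(path)
}
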