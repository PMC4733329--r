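# Independent brute-force contact oracle: exhaustive minimum over every
# atom cross pair of every unit pair, written against the contact
# definitions directly (no spatial blocking, no grouping machinery).

oracle_sugar_phosphate <- c(
  "P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P",
  "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'"
)

oracle_eligible <- function(atoms, side, definition) {
  keep <- atoms$is_heavy
  if (definition == "pn" && side == "b") {
    keep <- keep & atoms$element %in% c("N", "O") &
      !(atoms$atom_name %in% oracle_sugar_phosphate)
  }
  if (definition == "nn") {
    keep <- keep & atoms$element %in% c("N", "O")
  }
  atoms[keep, ]
}

# returns tibble(seq_index_a, seq_index_b, min_distance)
oracle_contacts <- function(structure, chain_a, chain_b, definition,
                            cutoff) {
  at <- as.data.frame(structure)
  a_el <- oracle_eligible(at[at$chain_id == chain_a, ], "a", definition)
  b_el <- oracle_eligible(at[at$chain_id == chain_b, ], "b", definition)
  a_units <- split(a_el, a_el$seq_index)
  b_units <- split(b_el, b_el$seq_index)
  res <- list()
  for (ia in names(a_units)) {
    ua <- a_units[[ia]]
    for (ib in names(b_units)) {
      ub <- b_units[[ib]]
      best <- Inf
      for (p in seq_len(nrow(ua))) {
        for (q in seq_len(nrow(ub))) {
          if (definition == "nn" &&
              ua$element[p] == "O" && ub$element[q] == "O") next
          d <- sqrt((ua$x[p] - ub$x[q])^2 + (ua$y[p] - ub$y[q])^2 +
                      (ua$z[p] - ub$z[q])^2)
          if (d < best) best <- d
        }
      }
      if (best <= cutoff + 1e-9) {
        res[[length(res) + 1L]] <- data.frame(
          seq_index_a = as.integer(ia), seq_index_b = as.integer(ib),
          min_distance = best
        )
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(seq_index_a = integer(), seq_index_b = integer(),
               min_distance = double())
  out[order(out$seq_index_a, out$seq_index_b), , drop = FALSE]
}

# engine results reduced to the oracle's columns for comparison
engine_as_oracle <- function(pairs) {
  out <- as.data.frame(pairs[, c("seq_index_a", "seq_index_b",
                                 "min_distance")])
  out <- out[order(out$seq_index_a, out$seq_index_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

contacts_for_definition <- function(structure, ca, cb, definition,
                                    params = contact_params()) {
  sa <- whole_chain_subunit(structure, ca)
  sb <- whole_chain_subunit(structure, cb)
  switch(definition,
    pp = protein_protein_contacts(structure, sa, sb, params),
    pn = protein_nucleic_contacts(structure, sa, sb, params),
    nn = nucleic_nucleic_contacts(structure, sa, sb, params)
  )
}

definition_for_kinds <- function(ka, kb) {
  if (ka == "protein" && kb == "protein") return("pp")
  if (ka == "protein" && kb != "protein") return("pn")
  if (ka != "protein" && kb != "protein") return("nn")
  NA_character_
}

# compare engine and oracle on every orientable chain pair of a structure;
# returns number of chain pairs checked, stops on first mismatch
expect_engine_matches_oracle <- function(structure) {
  ch <- chains_of(structure)
  ch <- ch[ch$polymer_kind %in% c("protein", "dna", "rna"), ]
  n_checked <- 0L
  if (nrow(ch) >= 2) {
    cmb <- combn(nrow(ch), 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      # orient protein first for the pn definition
      if (ch$polymer_kind[i] != "protein" && ch$polymer_kind[j] == "protein") {
        tmp <- i; i <- j; j <- tmp
      }
      def <- definition_for_kinds(ch$polymer_kind[i], ch$polymer_kind[j])
      cutoff <- if (def == "pp") 6.0 else 3.5
      eng <- engine_as_oracle(
        contacts_for_definition(structure, ch$chain_id[i], ch$chain_id[j], def))
      ora <- oracle_contacts(structure, ch$chain_id[i], ch$chain_id[j], def,
                             cutoff)
      rownames(ora) <- NULL
      expect_equal(eng, ora, tolerance = 1e-12)
      n_checked <- n_checked + 1L
    }
  }
  n_checked
}
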