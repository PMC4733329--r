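# macrodissect

Dissect a macromolecular structure into its interacting subunits and
compute the complete binary interaction network of the complex.

Most structures in the PDB are complexes, and the biologically meaningful
units of interaction inside them are rarely whole chains: protein chains
decompose into SCOP-annotated **domains** separated by **inter-domain
linkers** and flanked by **N-** and **C-terminal** regions; short chains
act as **peptides** and unannotated long chains as **undefined chains**;
nucleic acids contribute **DNA** and **RNA** chain subunits. `macrodissect`
assigns every polymer region of a PDB or mmCIF file to exactly one of these
eight subunit types and then decides, for every unordered pair of subunits,
whether they form a binary interaction — giving one of 36 interaction types
(8 self-pairs + 28 cross-pairs, coded `D-D`, `D-RNA`, `L-RNA`, ...).

## Interface definitions

Contacts are computed at the heavy-atom level:

* **Residue–residue** (protein–protein): residues *i*, *j* of two protein
  subunits form a contact pair when
  min<sub>a∈i, b∈j</sub> ‖x<sub>a</sub> − x<sub>b</sub>‖ ≤ 6 Å over heavy
  atoms. An interaction requires ≥ 10 surviving contact pairs
  (configurable).
* **Residue–nucleotide** (protein–DNA/RNA): a contact pair exists when an
  N or O atom of the *nucleobase* (sugar and phosphate excluded) lies
  within 3.5 Å of a heavy atom of the residue. One pair suffices by
  default.
* **Nucleotide–nucleotide** (DNA/RNA–DNA/RNA): a qualifying N–N or O–N
  atom pair within 3.5 Å; O–O proximity alone never counts.
* **Adjacency exclusion**: contact pairs between sequence-adjacent
  subunits of the same chain are discarded unless the residues are more
  than 10 sequence positions apart, suppressing covalent-proximity false
  positives. Exclusion is applied before the minimum-pair count.

Distances exactly at a cutoff qualify; comparisons use a 10⁻⁹ Å tolerance
so boundary cases are platform-stable.

Subunit annotation follows the four-stage rule set: curated SCOP domain
definitions (`dir.cla` parseable dialect) are mapped first, optionally
complemented by precomputed SUPERFAMILY predictions supplied in the same
dialect; every remaining maximal unannotated region becomes a linker
(domains on both sides) or terminal region (domain on one side); fully
unannotated chains are peptides below 20 resolved residues, undefined
chains otherwise; a DNA chain is a subunit when at least one of its
nucleotides is base-paired (per `_ndb_struct_na_base_pair`, or a geometric
Watson–Crick test when those records are absent) with a nucleotide of
another DNA chain; each RNA chain is one subunit; hybrid DNA/RNA chains
are excluded.

## Worked example

The package ships deterministic generators, so a complete example needs no
downloads — here a protein domain grips both strands of an 8-bp B-form
duplex:

```r
library(macrodissect)

dup <- make_duplex_dna(8, chain_ids = c("B", "C"))
at  <- dplyr::filter(tibble::as_tibble(dup$structure), atom_name == "N1")
targets <- dplyr::bind_rows(head(dplyr::filter(at, chain_id == "B"), 1),
                            head(dplyr::filter(at, chain_id == "C"), 1))
prot <- make_protein_chain(30, chain_id = "A", offset = c(60, 0, 0))
bridges <- purrr::list_rbind(purrr::map(1:2, function(k)
  tibble::tibble(chain_id = "A", auth_seq_id = as.character(5 * k),
                 comp_id = "ALA", atom_name = "CG", element = "C",
                 x = targets$x[k] + 3.0, y = targets$y[k], z = targets$z[k])))
s <- fixture_structure(list(dplyr::bind_rows(prot, bridges),
                            tibble::as_tibble(dup$structure)),
                       entry_id = "GRIP", base_pairs = dup$base_pairs,
                       source_format = "mmcif")
asg <- tibble::tibble(pdb_id = "GRIP", chain_id = "A", start_auth = "1",
                      end_auth = "30", domain_id = "d_grip_a1",
                      scop_family = "b.1.1.1", sunid = "2",
                      source = "scop_curated")
net <- build_network(s, asg)
net
#> <interaction network GRIP> 3 subunits, 3 interactions
#>    D-DNA:2  DNA-DNA:1
tidy(net)
#> # A tibble: 3 × 7
#>   label_a label_b kind_a kind_b interaction_type n_pairs is_intra_chain
#>   <chr>   <chr>   <chr>  <chr>  <chr>              <int> <lgl>
#> 1 A1      B1      domain dna    D-DNA                  3 FALSE
#> 2 A1      C1      domain dna    D-DNA                  2 FALSE
#> 3 B1      C1      dna    dna    DNA-DNA               22 FALSE
```

The whole protein chain is one domain subunit `A1`; its engineered CG
atoms sit 3.0 Å from base nitrogens of each strand, giving two `D-DNA`
interactions, and the duplex's Watson–Crick pairing gives the `DNA-DNA`
edge with 22 nucleotide contact pairs. `ggplot2::autoplot(net)` draws the
network; `export_network(net, "json" | "graphml" | "tsv", path)` and
`write_binary_complex()` export it; `read_network_json()` restores a JSON
export losslessly.

From a shell, the same pipeline runs as

```sh
Rscript inst/cli/macrodissect dissect --input complex.cif --scop domains.cla --out results/
Rscript inst/cli/macrodissect extract --input complex.cif --scop domains.cla A1 B1 --out results/
Rscript inst/cli/macrodissect types
```

with flags for every threshold (`--pp-cutoff`, `--nuc-cutoff`,
`--min-pairs`, `--min-nuc-pairs`, `--adjacency-gap`, `--peptide-max`,
`--include-unpaired-dna`).

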