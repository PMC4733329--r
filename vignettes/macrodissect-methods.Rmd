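---
title: "Dissecting macromolecular complexes into subunit interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting macromolecular complexes into subunit interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrodissect)
```

## The model

A deposited structure is treated as a set of polymer chains; each chain is
partitioned into *subunits*, the units between which interactions are
defined. Eight subunit kinds exist:

| kind | code | definition |
|---|---|---|
| domain | D | region matching a SCOP family assignment |
| C-terminal region | C | unannotated region with a domain only on its N-side |
| N-terminal region | N | unannotated region with a domain only on its C-side |
| inter-domain linker | L | unannotated region flanked by domains on both sides |
| undefined chain | U | protein chain with no domain, ≥ 20 resolved residues |
| peptide | P | protein chain with no domain, < 20 resolved residues |
| DNA chain | DNA | DNA chain base-paired with another DNA chain |
| RNA chain | RNA | any RNA chain |

Unordered pairs of kinds give 36 interaction types. A pair of subunits is
an interaction when its contact pairs, under the definition selected by
the two kinds, survive the adjacency filter and reach the governing
minimum count. The three contact definitions, their default cutoffs, and
the filters are described in the README; this vignette concentrates on the
choices behind them.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `pp_distance_cutoff` | 6.0 | Å | residue–residue heavy-atom cutoff; the widely adopted residue-contact threshold |
| `nucleic_distance_cutoff` | 3.5 | Å | hydrogen-bond-scale cutoff for contacts involving nucleotides |
| `min_pp_contact_pairs` | 10 | pairs | smallest interface accepted as a protein–protein interaction |
| `min_nucleic_contact_pairs` | 1 | pairs | a single 3.5 Å base contact is individually meaningful, so nucleic-mediated interactions default to 1 |
| `adjacency_min_separation` | 10 | residues | contacts between sequence-adjacent subunits of one chain must span more than this many positions |
| `peptide_max_len` | 20 | residues | exclusive peptide bound (ASTRAL short-chain convention) |
| `base_atoms_only` | `TRUE` | — | restrict the nucleic side of residue–nucleotide contacts to the nucleobase moiety |

The minimum-pair rule is stated for protein–protein interfaces only; for
nucleic-mediated interfaces no analogous published minimum exists, so the
package defaults to 1 qualifying pair and exposes it as a parameter. The
"nucleic base" is taken literally: sugar and phosphate atoms are excluded
on the nucleic side (a residue hydrogen-bonded only to a phosphate oxygen
is not a base contact); `base_atoms_only = FALSE` restores
whole-nucleotide behaviour.

Chain length for the peptide rule counts *resolved* polymer units, not
the author-numbering extent: it is derivable from the coordinates alone
and therefore deterministic across depositions.

## Numerical choices

* Distances are compared to cutoffs with a 10⁻⁹ Å tolerance, so fixtures
  placed exactly at 6.00 Å or 3.50 Å qualify on every platform.
* Alternate locations: the highest-occupancy altloc is kept, ties going to
  the alphabetically first code. Multi-model (NMR) files use model 1.
* mmCIF chains are identified by author asym ids so PDB and mmCIF parses
  of one entry agree; internally every rule operates on 0-based, gap-free
  sequence indices, with author numbering retained for reporting.
* Nucleotide typing is dictionary-free: standard deoxyribonucleotides
  (DA/DC/DG/DT/DU/DI) plus the two-character `D`-prefix convention are
  DNA; single-letter A/C/G/U(/I/N) are RNA. Modified amino acids occupying
  polymer positions (MSE, SEP, ...) count as amino acids.
* Overlapping domain assignments resolve deterministically: curated beats
  predicted, then the longer domain, then the smaller start index; losers
  are reported as rejected rather than silently dropped. Assignments whose
  boundary residues are missing from the coordinates (stale definitions)
  are likewise rejected and reported.
* Multi-segment domains are one subunit with several segments: ordinals
  follow the first segment, and contacts pool across segments.
* Sequence adjacency means the two subunits' segment intervals abut with
  no intervening span; the exclusion applies to every intra-chain abutting
  pair (domain–linker, domain–terminus, ...), and it runs *before* the
  minimum-pair count, since excluded pairs are considered false positives
  outright.

## Design decisions taken where the rules are open

**Unpaired DNA chains.** The DNA-subunit rule keeps only chains
base-paired with *another* DNA chain; applied literally it silently drops
single-stranded DNA, so e.g. a single-strand-binding protein would lose
its DNA partner entirely. The package therefore retains such chains
*flagged* (`unpaired = TRUE`) and excludes them from the default network,
with `include_unpaired_dna = TRUE` to opt in.

**Base pairing without records.** The `_ndb_struct_na_base_pair` category
exists only in mmCIF. For plain PDB input — and for mmCIF files lacking
the category — pairing falls back to a geometric Watson–Crick test: two
DNA chains are paired when a complementary nucleotide pair has its purine
N1 and pyrimidine N3 within 3.5 Å. The category, when present, is
authoritative.

**The pairing rule's wording.** The source rule reads "at least one base
pair complementarily paired with a base pair of another chain"; a base
pair cannot pair with a base pair under the cited data item, so it is
interpreted as "at least one *nucleotide* base-paired with a nucleotide of
another DNA chain".

**Termini in sequence coordinates.** Whether terminal/linker rules use
author numbering or resolved positions is unstated; resolved 0-based
indices are used because author numbering may contain gaps and insertion
codes that make interval arithmetic ill-defined.

**Type-code orientation.** Codes are canonicalized by the fixed kind
ordering D, C, N, L, U, P, DNA, RNA; both orientations occur in practice
(`D-RNA` and `RNA-L` style), so `normalize_type_code()` accepts either and
equality is orientation-insensitive.

**Symmetry copies.** The pipeline operates on the asymmetric unit as
deposited: no biological-assembly expansion, and symmetric interactions
between crystallographic copies are all reported.

## The contact engine and its oracle

The engine computes, per subunit pair, the minimum eligible-atom distance
for every unit pair, blockwise so memory stays bounded, and is required to
return *exactly* the exhaustive all-pairs answer — there is no
approximation to tune. The test suite and the acceptance script verify
this pair-for-pair against an independently written brute-force oracle
(plain nested loops over units and atoms) on 100 random multi-chain
complexes of up to ~120 units each; that size keeps the full suite within
a few minutes on one CPU while exercising all three contact definitions
and both chain-kind orientations.

## What the synthetic generators emulate — and what they do not

The generators produce: idealized extended/helical protein traces with
5 heavy atoms per residue; B-form DNA duplexes (3.38 Å rise, 36° twist)
whose Watson–Crick N1–N3 distances are exactly 2.9 Å, with matching
base-pair records and mmCIF text; docked pairs whose contact map is
planned and achieved exactly by construction (each planned pair gets a
dedicated atom pair at an isolated meeting point, all unplanned unit
pairs hundreds of Å apart); and seeded random complexes for stress tests.

These fixtures are geometric, not physical: no side-chain rotamers, no
relaxed conformations, no crystallographic disorder, no modified-residue
zoo, no alternate conformer ambiguity beyond what the parser tests
construct. Since every pipeline rule depends only on distances,
composition and sequence positions, passing on fixtures demonstrates the
rules are implemented exactly; it does not validate scientific
conclusions about any real complex, nor cover the full heterogeneity of
deposited files (exotic chemical components, gigantic assemblies,
malformed records).

## Known limitations

* SUPERFAMILY domain *prediction* is out of scope: predictions are
  consumed as precomputed assignment files only.
* No biological-assembly expansion and no small-molecule ligands: an
  interface mediated by a symmetry mate or a cofactor is invisible.
* Hybrid DNA/RNA chains are annotated and reported but excluded from
  interaction detection.
* Nucleotide typing by naming convention can misclassify nonstandard
  components absent from the built-in lists; they fall to `other` and are
  dropped with the heteroatoms.
* GraphML output is structurally valid (checked by parsing) but is not
  validated against the official XML schema, which would require the
  schema files.
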