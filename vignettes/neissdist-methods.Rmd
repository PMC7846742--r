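---
title: "Screening protein complexes for C-terminus-to-amine proximity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening protein complexes for C-terminus-to-amine proximity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neissdist)
```

## The method

Covalent probes built on calcium-triggered autoproteolysis place a reactive
aspartic anhydride at the C-terminus of a binder protein. Conjugation then
requires a nucleophilic amine on the docked target within reach of that
C-terminus. This package screens deposited structures for exactly that
geometry, and keeps the accounting honest about what a crystal structure
can and cannot tell you.

The unit of analysis is the **chain instance**: one polypeptide chain copy
inside one biological assembly, i.e. an (assembly, chain, operator-product)
triple. Assemblies are generated by expanding the deposited
`pdbx_struct_assembly_gen` operator expressions — including cartesian
products such as `(1-60)(61)` — and applying the 4×4 transforms to the
chains they name. Legacy PDB files carry no operator records here; they are
analysed as their asymmetric unit with a notice, since the mmCIF route is
the authoritative one for assemblies.

Per chain instance and coordinate model:

- the **C-terminal residue** is the last *resolved* standard amino acid —
  deliberately not the sequence terminus, because unresolved tails cannot
  position an anhydride;
- **targets** are the first resolved standard residue (its backbone
  nitrogen is the free α-amine) and every lysine (side-chain Nε, PDB atom
  NZ).

Distances run from Ct backbone atoms {C, CA, N} to the target atom set, and
one **primary distance** is selected per (Ct, target) pair by a fixed
priority order, falling back through backbone atoms when side chains or
termini are unresolved:

| rank | lysine | N-terminus | N-terminal lysine |
|------|--------|------------|-------------------|
| 1–3  | C–Nε, CA–Nε, N–Nε | C–αN, CA–αN, N–αN | source vs shorter of αN/Nε |
| 4–6  | C–CA, CA–CA, N–CA | C–CA, CA–CA, N–CA | C–CA, CA–CA, N–CA |
| 7–9  | C–N, CA–N, N–N | — | — |

The priority order encodes chemical preference (the carbonyl carbon is
where the anhydride forms; Nε is the attacking nucleophile), so the primary
distance is *not* the minimum over atom pairs — the test suite asserts this
on a constructed counter-example, and checks the selector exhaustively
against a literal first-available-in-list reference over every atom
availability pattern.

Records are classified **intramolecular** (same instance), **homomeric**
(different instances, identical polymer sequence) or **heteromeric**
(different sequences). Primary distances below 1.6 Å are flagged as
existing covalent linkages (e.g. ubiquitin conjugates) and excluded from
shortlists. Per structure, one minimum is kept per category — taken across
assemblies and models — plus the single overall-shortest record.

## Parameters and defaults

| parameter | default | why |
|-----------|---------|-----|
| `max_file_bytes` | 10,485,760 | skip viruses and similarly huge assemblies before parsing; strict `<` |
| `max_models` | 10 | NMR ensembles contribute their first 10 models, in file order |
| `covalent_cutoff` | 1.6 Å | below typical C–N bond-adjacent distances; strict `<`, so 1.60 Å is kept |
| `histogram_range` | [0, 50) Å | half-open; a minimum at exactly 50 Å is excluded |
| `bin_width` / `fine_step` | 1 Å / 0.1 Å | reporting resolution of minima histograms and cumulative interrogation |
| screen cutoffs | 10 Å / 10 Å | the headline shortlist query uses < 10 Å for the target amine; the self-reaction "close" is not independently quantified, so the same 10 Å is used symmetrically and both are configurable |

Headline store queries (`count_structures_below()`, `minima_histogram()`,
`export_shortlist()`) restrict to records whose primary pair is exactly
C–Nε; for an N-terminal lysine this means Nε was selected over the α-amine.
The restriction is applied to records first and minima are taken afterwards,
which keeps histogram bins and cumulative counts mutually consistent (an
identity the tests assert).

## Numerical and design choices

- **Altlocs**: the highest-occupancy conformer wins; exact ties go to the
  lexicographically first altloc id.
- **Standard residues**: the canonical 20 three-letter codes.
  Selenomethionine is treated as non-standard unless `map_mse = TRUE`, a
  strict reading of "standard amino acid".
- **αN vs backbone N**: the first residue's backbone nitrogen *is* its
  α-amine; it appears once, as αN, never as a second fallback column.
- **Exact ties** αN/Nε at an N-terminal lysine resolve to αN (listed first
  in the priority phrasing); documented and tested.
- **Same-residue pairs**: a chain ending in lysine measures its own Ct
  against itself at backbone-bond range. These records are computed,
  flagged `same_residue`, and excluded from shortlists and (optionally)
  minima; including them silently would dominate intramolecular minima.
- **Reporting precision**: distances are carried at full floating precision
  and rounded only in reports, to 0.1 Å, with halves away from zero (a
  14.47 Å distance prints as 14 Å at integer precision).
- **Multi-model reduction**: distances are computed per model and minimised
  across models inside the per-structure aggregation, consistent with the
  shortest-distance intent of the screen.
- **Cross-assembly**: chains are never paired across assemblies, but minima
  may compare across them.
- **Determinism**: all orderings and tie-breaks are explicit; scanning the
  same bytes twice gives identical tables.
- **File-size gate**: applied to the input file as the proxy for assembly
  size, with a secondary post-expansion atom-count cap (500,000 atoms)
  guarding pathological operator products. Whether the original protocol
  measured the entry file or the generated assembly is ambiguous; both
  guards are provided.
- **Store backend**: a directory of three TSV tables with dplyr queries.
  A plain-text store is transparent, versionable and dependency-free, and
  at desk scale the aggregate queries are trivially fast; the query surface
  (counts below cutoff, shortest-category tallies, histograms, shortlist
  export) is what matters, not the engine behind it.

## What the synthetic fixtures do and do not show

The `make_*_fixture()` generators emit valid mmCIF text with idealized
template backbones in which the *key* quantity — the Ct carbonyl carbon to
lysine Nε distance, an operator-generated homomeric contact, a per-model
distance ladder — is placed exactly, on the 3-decimal grid that survives a
write/parse round trip bit-exactly. Optional jitter (seeded, 0.05 Å s.d.)
perturbs every non-key atom to keep tests honest about ordering assumptions.

This validates the machinery: parsing, operator expansion, priority
selection, classification, aggregation, queries. It does not emulate real
data's pathologies — alternate conformations beyond simple altloc pairs,
insertion codes, chain breaks, microheterogeneity, or physically refined
side-chain rotamers — so passing fixtures says nothing about, e.g., whether
a particular deposited lysine's Nε position is reliable. One integration
test therefore screens the deposited decarboxylase/antizyme complex (PDB
4zgy) end to end; it requires fetching that entry from the PDB.

Problem sizes throughout the suite are desk-scale by design: toy chains of
3–4 residues, populations of five or six structures, a 12-model ensemble.
These are sufficient because every assertion is against constructed truth
or an exact counting identity, not against sampling noise.

## Mass bookkeeping

`average_mass()` sums average residue masses (ExPASy table) plus one water
(18.0153 Da), optionally dropping a leading methionine; a monoisotopic
table sits behind a flag. `cleavage_masses()` splits a precursor into the
anhydride-bearing N-fragment (`precursor − c_fragment`) and its hydrolyzed
form (one water heavier); `conjugate_mass()` adds binder fragment and
target and subtracts one water for the new amide/ester bond. The identity
`conjugate = precursor − c_fragment + target` — in which all waters
cancel — is asserted in the tests, and the published component masses
reproduce the published conjugate mass within the 0.1 Da print precision.

## Known limitations

- Steric accessibility of the reactive site and occlusion of the binding
  interface by the fused module are *not* computed; reports carry explicit
  manual-inspection notes, matching the visual-inspection step of the
  original protocol.
- No amine pKa prediction, docking, or scoring of any kind; the screen is
  purely geometric.
- Legacy PDB assembly records (REMARK 350) are not expanded.
- Snapshot-scale statistics (how many structures in the whole PDB pass a
  cutoff) depend on the database snapshot and bulk compute; this package
  implements and verifies the queries that produce them, not the numbers
  themselves.
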