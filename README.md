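# neissdist

Structure screening for C-terminal anhydride chemistry: find protein
complexes in which one chain's C-terminus sits close to a reactive amine on
a partner chain.

## The problem

A binder protein fused to a calcium-triggered self-processing module can be
turned into a covalent probe: on Ca²⁺ addition the module autocleaves at an
Asp–Pro bond and leaves a short-lived aspartic anhydride at the binder's new
C-terminus. If the docked target protein presents a nucleophilic amine — a
lysine ε-amine (atom Nε/NZ) or the chain's α-amine — within reach, the
anhydride is attacked and the complex is ligated covalently. Whether a given
complex is a good candidate is, to first order, a geometry question, and
this package answers it from deposited structures.

For every polypeptide chain in every biological assembly of a structure,
the package:

1. defines the **C-terminal residue** Ct as the last *resolved* standard
   amino acid of the chain, and **targets** as the first resolved standard
   residue (α-amine) plus every lysine;
2. measures backbone atoms C, CA, N of Ct against target atoms Nε (lysines),
   αN (first residue) and the CA/N fallbacks, and selects a single
   **primary distance** per pair by a fixed priority order
   (C–Nε > CA–Nε > N–Nε > C–CA > CA–CA > N–CA > C–N > CA–N > N–N for
   lysines; αN replaces Nε for N-termini; an N-terminal lysine uses
   whichever of αN/Nε is shorter);
3. classifies each record as intramolecular, intermolecular **homomeric**
   (identical sequences) or **heteromeric** (different sequences), flags
   primary distances < 1.6 Å as existing covalent linkages, and reduces
   each structure to per-category minima (across assemblies and models, at
   most 10 models per structure, input files < 10 MB);
4. persists records and minima in a queryable store: structure counts below
   a cutoff, shortest-category tallies, 1 Å minima histograms on [0, 50),
   and a ranked candidate shortlist.

A single-complex `screen_complex()` report implements the design criteria
directly: rank the target's amines by distance to the binder Ct and check
that the binder itself has no amine near its own C-terminus (self-reaction,
an "own-goal"). Mass bookkeeping for the cleavage products (anhydride vs
hydrolyzed) and the final conjugate supports intact-MS validation.

## Worked example

```r
library(neissdist)

f <- tempfile(fileext = ".cif")
writeLines(make_toy_complex(distance = 3.5), f)   # known geometry
screen_complex(f, binder_chain = "A", target_chain = "B")
#> <neiss_screen> toyhet assembly 1, binder A (Ct E3) -> target B
#>   nearest target amine : K2 lysine at 3.5 A (C-NZ)
#>   binder self amine    : A1 at 9.7 A
#>   target within 10 A   : TRUE
#>   self-clash  < 10 A   : TRUE
```

The nearest target amine is the constructed lysine at exactly 3.5 Å from
the binder's C-terminal carbonyl carbon, measured through the C–NZ primary
pair; the binder's only other amine is its own α-amine 9.7 Å away, so at a
10 Å criterion the complex would also be flagged for self-reaction risk.
With a real entry, `screen_complex(fetch_structure("4zgy"), ...)` produces
the same report for the decarboxylase/antizyme pair.

Scanning into a store and querying:

```r
recs <- scan_structure(f)
store <- neiss_store("dist-store")
store_persist(store, recs, aggregate_minima(recs))
count_structures_below(store, "intermolecular_heteromeric", 10)
#> [1] 1
export_shortlist(store, cutoff = 10)
```

Mass accounting from the published component masses (Da):

```r
cp <- cleavage_masses(42024.7, 26415.1)  # binder-module fusion, module
cp$n_fragment_hydrolyzed                 # 15627.6
conjugate_mass(cp$n_fragment_hydrolyzed, 52929.9)
#> [1] 68539.5
```

A command-line wrapper with `scan`, `screen`, `query`, `hist`, `shortlist`,
`mass` and `fixtures` subcommands is installed at `inst/cli/neissdist`.

## Package layout

- `R/structure-io.R` — mmCIF/PDB parsing, size gate, assembly fetch
- `R/assembly.R` — operator-expression expansion into chain instances
- `R/terminus.R` — Ct/target definitions and the primary-pair priority order
- `R/scan.R` — full per-structure scan, classification, minima
- `R/store.R` — TSV-backed distance store and aggregate queries
- `R/screen.R` — single-complex report (`tidy()`, `glance()`, `autoplot()`)
- `R/mass.R` — sequence masses, cleavage and conjugate bookkeeping
- `R/fixtures.R` — synthetic mmCIF generators with exact geometry

See `vignettes/neissdist-methods.Rmd` for the method description, parameter
rationale and limitations.
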