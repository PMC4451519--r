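# sbgnpd

Compound-graph modelling and complexity management of SBGN Process
Description (SBGN-PD) maps, for systems biologists and tool builders who
need to cut large pathway maps down to readable sub-maps **without breaking
the notation**.

An SBGN-PD map is a compound graph: entity pool nodes (EPNs — macromolecules,
simple chemicals, complexes, ...) and process nodes connected by consumption,
production and modulation-family arcs, with complexes containing members and
compartments containing entities, to arbitrary depth. Generic graph
filtering of such a map produces dangling arcs, processes missing
substrates, and complexes missing the members that define them. `sbgnpd`
instead implements closure-based *Show Selected* / *Hide Selected*
operations that always yield valid, complete sub-maps.

## The core operations

For a selection *G* in map *M*, the focusing closure `expand_nodes(M, G)`
executes one straight-line pass:

    G ← G ∪ descendants(G)
    G ← G ∪ ancestors(G)
    G ← G ∪ descendants(G ∩ complexes)
    P ← processes(G);  N ← G \ P
    Q ← processNeighbors(N)
    G ← G ∪ nbhd(P) ∪ Q ∪ nbhd(Q)
    G ← G ∪ ancestors(G)
    G ← G ∪ descendants(G ∩ complexes)

`show_selected()` displays exactly this closure; `hide_selected()` expands
the selection first, then expands the complement of that closure inside the
current visible universe, and shows only the second closure — naively
expanding the raw complement would typically hide nothing. Five invariants
(selection shown; selected EPNs keep their processes; triggered processes
keep all substrates/products/effectors; parent chains shown; complexes
complete) are checked by `check_invariants()`. The closure is single-pass by
design and therefore *not* idempotent; see the methods vignette
(`vignettes/complexity-management.Rmd`) for why.

Around the core: lossless SBGN-ML reading/writing (`read_sbgnml`,
`write_sbgnml`), a structural validator (`validate_structure`), a seeded
random-map generator and figure-scenario fixtures (`generate_map`,
`fixture`), a nesting-preserving compound layout with SVG export
(`compound_layout`, `export_svg`), and a CLI (`pd_cli`, installed script
`inst/cli/sbgnpd`).

## Worked example

```r
library(sbgnpd)

m <- fixture("fig2_like")      # myosin complex nested in actin-myosin, in a compartment
m
#> <pd_map 'fig2_like'> 17 glyphs, 11 arcs, nesting depth 4
#>   glyphs: compartment=1, complex=2, macromolecule=3, process=3, simple chemical=8
#>   arcs:   catalysis=2, consumption=5, production=4

sel <- c("cx_myosin", "pr_bind")   # the myosin complex + the process consuming it
st <- show_selected(m, sel)
st
#> <visibility_state> 14 nodes shown, 3 hidden, 8 arcs shown

check_invariants(m, sel, st)
#> <invariant_report> all 5 invariants hold
#>   [1] ok   selected nodes are shown
#>   [2] ok   processes of selected non-process nodes are shown
#>   [3] ok   triggered processes keep all substrates, products, effectors
#>   [4] ok   parent complexes/compartments of shown nodes are shown
#>   [5] ok   shown complexes keep all members

setdiff(glyph_ids(m), st$shown_nodes)
#> [1] "ep_x1"    "ep_x2"    "pr_other"
```

The closure pulled in the complex's members, its parent complex and
compartment, every participant of the selected process and of the process
its enclosing complex feeds — and nothing else: the unrelated
phosphorylation of a bystander (`pr_other` and its pools) stays hidden, even
though one shown pool catalyzes it. `induced_submap(m, st)` materializes the
result as a standalone map that validates and writes back to SBGN-ML.

From the shell:

```sh
Rscript inst/cli/sbgnpd show-selected map.sbgn -s "NBN" --out sub.sbgn --svg sub.svg
```

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch — seeded
random map generation, structural validation, Show/Hide Selected with the
five-invariant check, induced sub-maps, SBGN-ML round trips, compound layout
with containment checks, and the figure-scenario fixtures — and writes its
result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
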