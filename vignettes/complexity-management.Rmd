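---
title: "Complexity management of SBGN-PD maps: model, algorithms, guarantees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity management of SBGN-PD maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbgnpd)
```

## The problem

Process description maps in the Systems Biology Graphical Notation (SBGN-PD)
depict how pools of molecular entities — macromolecules, simple chemicals,
complexes — are transformed by process nodes, inside cellular compartments,
with complexes nesting members to arbitrary depth. Realistic maps are large,
and the standard remedy, filtering the drawing down to a selected subset,
breaks the notation when done generically: arcs end at nodes that are no
longer there, processes lose substrates, complexes lose the members that
define their identity.

`sbgnpd` models a PD map as a *compound graph* — a node set with both an arc
relation and a containment forest (complex membership, compartment location)
— and implements domain-aware focusing ("Show Selected") and ignoring
("Hide Selected") operations whose output is always a valid, complete
sub-map.

## The five sub-map invariants

A sub-map produced from a node group is considered valid when, writing `S`
for the shown set:

1. every node in the group is in `S`;
2. for every non-process node in the group, every process it participates in
   is in `S` (PD semantics live in the processes, so an entity without its
   processes is meaningless);
3. for every triggered process in `S`, all of its substrates, products and
   effectors are in `S` (hiding a participant would silently denote a
   different reaction);
4. for every node in `S`, its parent chain (complexes, compartments) is in
   `S` — membership and cellular location are identity-bearing;
5. every complex in `S` is in `S` together with all of its members,
   transitively.

`check_invariants()` evaluates exactly these five conditions and names the
offending glyphs per invariant.

## The expansion closure

`expand_nodes()` computes the minimal enlargement of a selection satisfying
the invariants as a fixed straight-line program: descendants, ancestors,
complex members; then the group is split into processes and non-processes,
the process neighbors of the non-processes are collected, and the
neighborhoods of both process sets are unioned in; finally ancestors and
complex members are unioned once more (new participants may live in unseen
containers or be complexes themselves).

Three decisions here were genuinely open and are worth recording:

* **"parents" and "children" are transitive.** Invariant 4 must hold
  recursively for chains like complex-in-complex-in-compartment, so
  `ancestors()`/`descendants()` return full transitive closures, not one
  level.
* **Single pass, not a fixpoint.** The straight-line program is executed
  exactly once. Iterating it to a fixpoint would let every EPN added as a
  process participant pull in *its* other processes, flooding the whole
  connected component and defeating the point of focusing. Consequently the
  closure is inflationary and monotone but deliberately **not idempotent**;
  `expand_pass_count()` exposes an instrumentation counter so tests can
  assert that exactly one pass ran.
* **Invariant-3 trigger set.** Full participant sets are guaranteed only for
  the processes the single pass treats that way: processes inside the
  selection's containment closure, plus processes adjacent to its
  non-process members. Processes that enter the result later (e.g. as a
  parent's neighbor's participant) are shown but not themselves expanded —
  the checker replays the first six lines of the closure to reconstruct this
  trigger set rather than guessing from the final state.

## Hiding

Expanding the complement of a selection is the obvious — and wrong — way to
hide: the complement contains the selection's processes, whose neighborhoods
pull the selection straight back in, so often *nothing* is hidden. In the
linear phosphorylation chain of `fixture("fig4_like")`, expanding the
complement of the native-state selection returns the entire map.

`hide_selected()` therefore expands the *selection* first, takes the
complement of that closure, and expands the complement; only this second
closure is shown. The two closures may overlap (typically on a shared
compartment or a shared intermediate state) — intended, since those elements
are needed by what remains visible. Two consequences are part of the
contract:

* **Chaining.** The operation takes the current visible universe
  (`all_elems`) and evaluates both closures on the sub-map induced by it, so
  successive hides compose; feeding a previous state's `shown_nodes` back in
  is the supported idiom.
* **Empty results are legal.** Hiding everything (or a selection whose
  complement-closure is empty) yields an empty state with a warning flag
  rather than an error — the GUI analog is a blank canvas.

For invariant checking of a hide result, the node group "to be shown" is the
complement seed (visible nodes minus the expanded selection); the property
suite passes that seed as `initial_selection`.

## Vocabulary decisions

* Process nodes are exactly {process, omitted process, uncertain process,
  association, dissociation}. **Phenotype is not a process node**: it enters
  sub-maps only through adjacency (a conservative reading of the PD
  reference card).
* **Logic operators** (and/or/not) are "not-process" for the selectors but
  participate in adjacency, so an operator adjacent to a process is pulled
  in like an effector EPN. Whether selecting an operator should drag in all
  of its upstream inputs is not specified anywhere we could anchor; the
  adjacency-only behavior is documented, not asserted as canonical.
* **Equivalence arcs and tags** are carried through I/O but invisible to all
  closure algorithms; **source-and-sink** glyphs are ordinary EPNs.
* Arcs are derived state: an arc is drawn iff both endpoints are shown. Arcs
  are never independently selectable.

## SBGN-ML I/O

Reading targets the 0.2-era SBGN-ML dialect and only the process description
language. Complex membership is taken from XML nesting (which wins over a
conflicting `compartmentRef`), compartment membership from `compartmentRef`;
ports are resolved to their owning glyph at parse time and are cosmetic
thereafter — all algorithms operate on glyph ids. State variables and units
of information become decorations of their owner, never map nodes; a
`<state value="P" variable="T185"/>` is folded into the decoration label as
`"P@T185"` and re-emitted as a label (lossless for files this package
writes; a documented simplification for foreign files). Unknown XML
*attributes* on glyph and arc elements are preserved verbatim; unknown child
elements are dropped. Writing is deterministic (sorted, compartments first)
and serializes coordinates with `%.17g`, so a parse-write-parse round trip
reproduces bounding boxes bit-exactly and equal maps produce identical
bytes.

`write_sbgnml()` refuses maps that fail `validate_structure()` — the checks
(acyclic containment, legal arc roles, processes with at least one substrate
and one product, non-empty complexes) encode the well-formedness the closure
algorithms assume.

## The synthetic world

`generate_map()` draws seeded random maps that are structurally valid by
construction: every process gets 1–2 substrates and 1–2 products (disjoint),
an effector with probability `effector_prob` (default 0.3); an EPN is a
complex with probability `complex_prob` (default 0.2) with 1–3 members,
recursively, within `max_nest_depth` (compartment membership counts as one
nesting level); entities and processes sit in a compartment with probability
0.7 when compartments exist and the depth budget allows. Defaults were
chosen once to resemble mid-sized curated pathway maps (tens to a few
hundred glyphs, shallow nesting, sparse regulation) and are not tuned to any
test outcome. Positions are uniform random on a canvas growing with node
count — the "random layout" starting state the layout stage cleans up.

What the generator does **not** emulate: biological reaction-type
distributions, stoichiometry, logic gates, tags/submaps, arcs attaching to
complex members (the hand-built fixtures cover that case). A green property
suite therefore establishes correctness of the graph algorithms on a broad
class of well-formed compound graphs, not fidelity to any particular curated
pathway corpus.

Named fixtures encode the walkthrough scenarios as topology-only contracts:
`fig1_like` (four processes, two shared-EPN instances, one complex — the
generic-vs-domain-aware filtering contrast), `fig2_like` (two-level complex
nesting in a compartment — the focusing walkthrough), `fig4_like` (a linear
modification chain — the hiding walkthrough), `minimal_process`. Labels and
coordinates are cosmetic; captions' counts, nesting and adjacency are the
contract. The same maps ship as plain-text `.sbgn` files under
`inst/extdata/` and are regenerated programmatically.

## Layout

The layout contract is containment, not aesthetics: after
`compound_layout()`, every child box lies strictly inside its parent box by
the `compartment_padding` margin, top-level boxes do not overlap, and
coordinates are deterministic under the config seed. The algorithm is a
recursive bottom-up two-phase scheme: each container's children are embedded
with a seeded Fruchterman–Reingold-style spring model over the arcs
projected onto that sibling level, sibling box overlaps are removed by a
deterministic pairwise push-apart (with a guaranteed-terminating row
fallback after 30 sweeps), and the container is fitted around its children
plus padding; top-level connected components are placed on a shelf, left to
right. Overlap between non-siblings is tolerated; edge routing and the
polish of production compound layouts are out of scope. Port coordinates are
not updated (they are cosmetic).

Numerical notes: containment is checked with a 1e-6 map-unit tolerance;
`compartment_padding = 0` is clamped to a tiny positive margin internally so
"strictly inside" remains meaningful; the spring model caps displacement by
a cooling schedule and floors distances at 1e-3 to avoid singularities.

## Known limitations

* Invariant 3's trigger set follows the single-pass algorithm, not the
  broadest reading of the prose invariant; processes shown only as
  containment/neighbor side effects keep whatever participants the pass
  gave them.
* No BioPAX, CellDesigner or GraphML input; no submap/tag expansion
  semantics; no stoichiometry labels.
* SVG export approximates PD glyph shapes and anchors arcs at bounding-box
  centers; it is a faithful structural rendering, not a reference-quality
  drawing.
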