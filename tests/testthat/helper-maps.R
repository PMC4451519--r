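# Shared builders for the test suite. All fixtures are built in code; no
# files are read except the packaged .sbgn copies under inst/extdata.

# A linear modification chain e1 -[P1]-> e2 -[P2]-> e3: the canonical
# demonstration that the expansion closure is deliberately not idempotent.
chain_map <- function() {
  pd_map_new("chain") |>
    add_glyph("e1", "macromolecule", label = "X") |>
    add_glyph("p1", "process") |>
    add_glyph("e2", "macromolecule", label = "X-P") |>
    add_glyph("p2", "process") |>
    add_glyph("e3", "macromolecule", label = "X-PP") |>
    add_arc("consumption", "e1", "p1") |>
    add_arc("production", "p1", "e2") |>
    add_arc("consumption", "e2", "p2") |>
    add_arc("production", "p2", "e3")
}

# Deterministic grid of generator configs with varied size/nesting/wiring.
# Sizes range from ~10 to ~300 glyphs; nesting depth never exceeds 4.
gen_config_grid <- function(n, base_seed = 1000L) {
  epns <- c(6L, 12L, 25L, 50L, 90L, 120L)
  procs <- c(3L, 6L, 12L, 25L, 45L, 60L)
  comps <- c(0L, 1L, 2L, 3L)
  cxp <- c(0, 0.15, 0.3, 0.45)
  depth <- c(1L, 2L, 3L, 4L)
  lapply(seq_len(n), function(i) {
    map_gen_config(
      n_compartments = comps[(i %% length(comps)) + 1L],
      n_processes = procs[(i %% length(procs)) + 1L],
      n_epns = epns[(i %% length(epns)) + 1L],
      complex_prob = cxp[(i %% length(cxp)) + 1L],
      max_nest_depth = depth[(i %% length(depth)) + 1L],
      effector_prob = 0.3,
      seed = base_seed + i)
  })
}

# k random glyph ids, deterministic under seed, without touching global RNG.
random_selection <- function(map, k, seed) {
  withr::with_seed(seed, sample(glyph_ids(map), min(k, n_glyphs(map))))
}
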