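test_that("expanding the empty group yields the empty group", {
  m <- fixture("fig2_like")
  expect_identical(expand_nodes(m, character(0)), character(0))
})

test_that("focusing walkthrough: complex + consuming process", {
  m <- fixture("fig2_like")
  got <- expand_nodes(m, c("cx_myosin", "pr_bind"))
  # children of the selected complex, its parent chain, all participants of
  # the selected process and of the process its enclosing complex feeds,
  # plus every member of each complex so reached; nothing else.
  expect_setequal(got, c(
    "cx_myosin", "pr_bind",                       # selection
    "m_myosin", "m_mlc",                          # members of the selection
    "cx_actmyo", "cp_cyto",                       # parent chain
    "m_actin",                                    # member of pulled complex
    "ep_atp", "ep_adp", "ep_myop", "ep_mlck",     # pr_bind participants
    "pr_contract",                                # neighbor process of cx_actmyo
    "ep_ca", "ep_amact"                           # its participants
  ))
  # the unrelated process chain stays out even though ep_myop catalyzes it
  expect_false(any(c("pr_other", "ep_x1", "ep_x2") %in% got))
  expect_identical(got, oracle_expand(m, c("cx_myosin", "pr_bind")))
})

test_that("show_selected emits a closed, invariant-clean state", {
  m <- fixture("fig2_like")
  sel <- c("cx_myosin", "pr_bind")
  st <- show_selected(m, sel)
  expect_setequal(st$shown_nodes, expand_nodes(m, sel))
  # arcs are derived: shown iff both endpoints shown, so never dangling
  a <- m$arcs
  both_in <- a$source %in% st$shown_nodes & a$target %in% st$shown_nodes
  expect_setequal(st$shown_arcs, a$id[both_in])
  expect_true(attr(check_invariants(m, sel, st), "all_pass"))
  expect_error(show_selected(m, character(0)), "select at least one")
  # closure of everything is everything
  all_st <- show_selected(m, glyph_ids(m))
  expect_setequal(all_st$shown_nodes, glyph_ids(m))
  expect_setequal(all_st$shown_arcs, arc_ids(m))
})

test_that("hiding walkthrough: complement closure, not naive complement", {
  m <- fixture("fig4_like")
  sel <- c("ep_rsk0", "ep_k1")
  # the naive hide — expanding only the raw complement — shows everything
  naive <- expand_nodes(m, setdiff(glyph_ids(m), sel))
  expect_setequal(naive, glyph_ids(m))
  # the proper complement closure: second modification step + shared
  # compartment + the shared intermediate state
  shown <- expand_remaining_nodes(m, sel)
  expect_setequal(shown, c("cp_cyto", "pr_p2", "ep_rsk1", "ep_rsk2", "ep_k2"))
  st <- hide_selected(m, sel)
  expect_setequal(st$shown_nodes, shown)
  expect_setequal(st$hidden_nodes, c("ep_rsk0", "ep_k1", "pr_p1"))
  expect_false(st$empty_warning)
  # result strictly differs from the naive computation
  expect_true(length(setdiff(naive, shown)) > 0)
  # overlap with the expanded selection (shared compartment, shared state)
  expect_true(all(c("cp_cyto", "ep_rsk1") %in%
                    intersect(shown, expand_nodes(m, sel))))
})

test_that("hide of nothing keeps all; hide of everything warns empty", {
  m <- fixture("fig2_like")
  st0 <- hide_selected(m, character(0))
  expect_setequal(st0$shown_nodes, glyph_ids(m))
  st1 <- hide_selected(m, glyph_ids(m))
  expect_identical(st1$shown_nodes, character(0))
  expect_identical(st1$shown_arcs, character(0))
  expect_true(st1$empty_warning)
  expect_identical(expand_remaining_nodes(m, glyph_ids(m)), character(0))
})

test_that("chained hides compose through the visible universe", {
  m <- fixture("fig2_like")
  st1 <- hide_selected(m, "pr_other")
  expect_false("pr_other" %in% st1$shown_nodes)
  st2 <- hide_selected(m, "pr_contract", all_elems = st1$shown_nodes)
  expect_false("pr_contract" %in% st2$shown_nodes)
  expect_true(all(st2$shown_nodes %in% st1$shown_nodes))
  # the second state is invariant-clean on the first state's sub-map
  sub <- induced_submap(m, st1)
  seed <- setdiff(st1$shown_nodes, expand_nodes(sub, "pr_contract"))
  expect_true(attr(check_invariants(sub, seed,
                                    hide_selected(sub, "pr_contract")),
                   "all_pass"))
  # selecting outside the visible universe is an error
  expect_error(hide_selected(m, "pr_other", all_elems = st1$shown_nodes),
               "outside the visible universe")
})

test_that("check_invariants pinpoints manufactured violations", {
  m <- fixture("fig2_like")
  sel <- c("cx_myosin", "pr_bind")
  full <- visibility_state(m, glyph_ids(m))
  expect_true(attr(check_invariants(m, sel, full), "all_pass"))
  # delete one member of a shown complex -> invariant 5 names it
  st <- visibility_state(m, setdiff(glyph_ids(m), "m_mlc"))
  rep5 <- check_invariants(m, sel, st)
  expect_false(rep5$pass[5])
  expect_identical(rep5$offending[[5]], "m_mlc")
  # also invariant 3: a triggered process lost a participant? m_mlc is not a
  # participant, so only 5 fails here
  expect_true(rep5$pass[3])
  # hide a substrate of the selected process -> invariant 3 names it
  st3 <- visibility_state(m, setdiff(glyph_ids(m), "ep_atp"))
  rep3 <- check_invariants(m, sel, st3)
  expect_false(rep3$pass[3])
  expect_identical(rep3$offending[[3]], "ep_atp")
  # hide an ancestor -> invariant 4
  st4 <- visibility_state(m, setdiff(glyph_ids(m), "cp_cyto"))
  expect_false(check_invariants(m, sel, st4)$pass[4])
  # hide a selected node -> invariant 1
  st1 <- visibility_state(m, setdiff(glyph_ids(m), "cx_myosin"))
  expect_false(check_invariants(m, sel, st1)$pass[1])
  # hide the process of a selected EPN -> invariant 2
  st2 <- visibility_state(m, setdiff(glyph_ids(m), "pr_contract"))
  rep2 <- check_invariants(m, "cx_actmyo", st2)
  expect_false(rep2$pass[2])
  expect_identical(rep2$offending[[2]], "pr_contract")
})

test_that("expansion is inflationary and monotone but not idempotent", {
  m <- chain_map()
  once <- expand_nodes(m, "e1")
  expect_setequal(once, c("e1", "p1", "e2"))
  twice <- expand_nodes(m, once)
  # second pass pulls the other process of the newly added participant
  expect_setequal(twice, glyph_ids(m))
  expect_true(length(twice) > length(once))
  expect_true(all(once %in% twice))
  # single-pass instrumentation: one call, one pass
  expand_pass_count(reset = TRUE)
  expand_nodes(m, "e1")
  expect_identical(expand_pass_count(), 1L)
})

test_that("induced submap is valid, writable, and faithful", {
  m <- fixture("fig2_like")
  st <- show_selected(m, c("cx_myosin", "pr_bind"))
  sub <- induced_submap(m, st)
  expect_setequal(glyph_ids(sub), st$shown_nodes)
  expect_setequal(arc_ids(sub), st$shown_arcs)
  expect_true(attr(validate_structure(sub), "all_pass"))
  expect_true(pd_map_equal(sub, parse_sbgnml(write_sbgnml(sub))))
  # full state copies the map; empty state empties it
  expect_true(pd_map_equal(induced_submap(m, visibility_state(m, glyph_ids(m))),
                           m))
  expect_equal(n_glyphs(induced_submap(m, visibility_state(m, character(0)))),
               0L)
  # a non-ancestor-closed state is refused
  broken <- visibility_state(m, "m_myosin")
  expect_error(induced_submap(m, broken), "ancestor-closed")
})
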