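test_that("config validation rejects unsatisfiable settings", {
  expect_error(map_gen_config(n_epns = 1), "n_epns")
  expect_error(map_gen_config(n_processes = 0), "n_processes")
  expect_error(map_gen_config(complex_prob = 1.5), "probabilities")
  expect_error(map_gen_config(max_nest_depth = 0), "max_nest_depth")
})

test_that("the minimal config produces the 3-node, 2-arc process motif", {
  m <- generate_map(map_gen_config(n_compartments = 0, n_processes = 1,
                                   n_epns = 2, complex_prob = 0,
                                   effector_prob = 0, seed = 7))
  expect_equal(n_glyphs(m), 3L)
  expect_equal(n_arcs(m), 2L)
  expect_equal(sum(is_process_class(m$glyphs$class)), 1L)
})

test_that("identical configs give byte-identical SBGN-ML", {
  cfg <- map_gen_config(n_processes = 8, n_epns = 15, complex_prob = 0.3,
                        seed = 99)
  expect_identical(write_sbgnml(generate_map(cfg)),
                   write_sbgnml(generate_map(cfg)))
  # and a different seed gives a different map
  cfg2 <- map_gen_config(n_processes = 8, n_epns = 15, complex_prob = 0.3,
                         seed = 100)
  expect_false(identical(write_sbgnml(generate_map(cfg)),
                         write_sbgnml(generate_map(cfg2))))
})

test_that("generated maps respect their config and pass validation", {
  for (cfg in gen_config_grid(20, base_seed = 700L)) {
    m <- generate_map(cfg)
    expect_true(attr(validate_structure(m), "all_pass"))
    expect_lte(nesting_depth(m), cfg$max_nest_depth)
    expect_equal(sum(m$glyphs$class == "compartment"), cfg$n_compartments)
    expect_equal(sum(is_process_class(m$glyphs$class)), cfg$n_processes)
    # every process has at least one substrate and one product
    procs <- m$glyphs$id[is_process_class(m$glyphs$class)]
    expect_true(all(procs %in% m$arcs$target[m$arcs$class == "consumption"]))
    expect_true(all(procs %in% m$arcs$source[m$arcs$class == "production"]))
  }
})

test_that("fixtures honour their topology contracts", {
  expect_error(fixture("fig3_like"), "available")

  mp <- fixture("minimal_process")
  expect_equal(n_glyphs(mp), 3L)
  expect_equal(n_arcs(mp), 2L)

  f1 <- fixture("fig1_like")
  expect_equal(sum(is_process_class(f1$glyphs$class)), 4L)
  expect_equal(sum(f1$glyphs$class == "complex"), 1L)
  # the two shared EPNs each participate in more than one process
  for (shared in c("ep_nbn", "ep_nbn_p")) {
    expect_gte(length(neighborhood(f1, shared, "process")), 2L)
  }

  f2 <- fixture("fig2_like")
  expect_true(any(vapply(glyph_ids(f2), function(id) {
    anc <- ancestors(f2, id)
    f2$glyphs$class[match(id, f2$glyphs$id)] == "complex" &&
      any(f2$glyphs$class[match(anc, f2$glyphs$id)] == "complex") &&
      any(f2$glyphs$class[match(anc, f2$glyphs$id)] == "compartment")
  }, NA)))
  expect_gte(sum(is_process_class(f2$glyphs$class)), 2L)

  f4 <- fixture("fig4_like")
  expect_true(attr(validate_structure(f4), "all_pass"))
  # closures of the hidden chain and its complement overlap on the compartment
  g <- expand_nodes(f4, c("ep_rsk0", "ep_k1"))
  r <- expand_remaining_nodes(f4, c("ep_rsk0", "ep_k1"))
  expect_true(length(intersect(g, r)) > 0)
})

test_that("validate_structure reports constructed defects without throwing", {
  # reversed production arc: EPN -> process under a production class
  rev <- pd_map(
    glyphs = data.frame(id = c("a", "p", "b"),
                        class = c("macromolecule", "process", "macromolecule"),
                        stringsAsFactors = FALSE),
    arcs = data.frame(id = c("a1", "a2"),
                      class = c("consumption", "production"),
                      source = c("a", "b"), target = c("p", "p"),
                      stringsAsFactors = FALSE))
  rep <- validate_structure(rev)
  expect_false(attr(rep, "all_pass"))
  expect_true("a2" %in% rep$offending[[which(rep$check ==
                                               "arc endpoint roles legal")]])
  # the process also lacks a production arc
  expect_false(rep$pass[rep$check == "processes have consumption and production"])

  # empty complex
  ec <- pd_map(glyphs = data.frame(id = "cx", class = "complex",
                                   stringsAsFactors = FALSE))
  expect_false(attr(validate_structure(ec), "all_pass"))

  # parent cycle between two complexes
  cyc <- pd_map(glyphs = data.frame(id = c("c1", "c2"),
                                    class = c("complex", "complex"),
                                    parent = c("c2", "c1"),
                                    stringsAsFactors = FALSE))
  repc <- validate_structure(cyc)
  expect_false(repc$pass[repc$check == "containment forest acyclic"])
})
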