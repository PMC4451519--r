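minimal_doc <- '<?xml version="1.0" encoding="UTF-8"?>
<sbgn xmlns="http://sbgn.org/libsbgn/0.2">
  <map language="process description" id="m1">
    <glyph class="macromolecule" id="g1">
      <label text="ERK"/>
      <bbox x="10" y="20" w="80" h="40"/>
    </glyph>
  </map>
</sbgn>'

test_that("a minimal document parses to one node, zero edges", {
  m <- parse_sbgnml(minimal_doc)
  expect_equal(n_glyphs(m), 1L)
  expect_equal(n_arcs(m), 0L)
  expect_identical(m$glyphs$label, "ERK")
  expect_identical(m$glyphs$x, 10)
})

test_that("XML nesting inside a complex sets parent links", {
  doc <- '<sbgn xmlns="http://sbgn.org/libsbgn/0.2">
    <map language="process description" id="m1">
      <glyph class="complex" id="cx"><bbox x="0" y="0" w="100" h="100"/>
        <glyph class="macromolecule" id="a"><bbox x="5" y="5" w="40" h="20"/></glyph>
        <glyph class="macromolecule" id="b"><bbox x="5" y="40" w="40" h="20"/></glyph>
      </glyph>
    </map>
  </sbgn>'
  m <- parse_sbgnml(doc)
  expect_equal(n_glyphs(m), 3L)
  expect_identical(parent_of(m, c("a", "b")), c("cx", "cx"))
})

test_that("complex nesting beats compartmentRef; compartmentRef otherwise", {
  doc <- '<sbgn xmlns="http://sbgn.org/libsbgn/0.2">
    <map language="process description" id="m1">
      <glyph class="compartment" id="cyt"><bbox x="0" y="0" w="500" h="500"/></glyph>
      <glyph class="complex" id="cx" compartmentRef="cyt"><bbox x="0" y="0" w="100" h="100"/>
        <glyph class="macromolecule" id="a" compartmentRef="cyt"><bbox x="5" y="5" w="40" h="20"/></glyph>
      </glyph>
      <glyph class="macromolecule" id="free" compartmentRef="cyt"><bbox x="200" y="5" w="40" h="20"/></glyph>
    </map>
  </sbgn>'
  m <- parse_sbgnml(doc)
  expect_identical(parent_of(m, "cx"), "cyt")
  expect_identical(parent_of(m, "a"), "cx")     # nesting wins
  expect_identical(parent_of(m, "free"), "cyt")
})

test_that("ports resolve to their owning glyph; aux glyphs attach to owners", {
  doc <- '<sbgn xmlns="http://sbgn.org/libsbgn/0.2">
    <map language="process description" id="m1">
      <glyph class="macromolecule" id="a">
        <bbox x="0" y="0" w="40" h="20"/>
        <glyph class="state variable" id="sv1">
          <state value="P" variable="T185"/>
          <bbox x="0" y="0" w="20" h="10"/>
        </glyph>
      </glyph>
      <glyph class="process" id="p">
        <bbox x="100" y="0" w="20" h="20"/>
        <port id="p.1" x="90" y="10"/>
        <port id="p.2" x="130" y="10"/>
      </glyph>
      <glyph class="macromolecule" id="b"><bbox x="200" y="0" w="40" h="20"/></glyph>
      <arc class="consumption" id="a1" source="a" target="p.1"/>
      <arc class="production" id="a2" source="p.2" target="b"/>
    </map>
  </sbgn>'
  m <- parse_sbgnml(doc)
  # state variable is a decoration, not a map node
  expect_equal(n_glyphs(m), 3L)
  expect_equal(length(m$aux[["a"]]), 1L)
  expect_identical(m$aux[["a"]][[1]]$label, "P@T185")
  # port endpoints resolved to the owning process
  expect_identical(m$arcs$target[m$arcs$id == "a1"], "p")
  expect_identical(m$arcs$source[m$arcs$id == "a2"], "p")
  # round trip keeps ports, aux and port-addressed arc refs
  m2 <- parse_sbgnml(write_sbgnml(m))
  expect_true(pd_map_equal(m, m2))
  expect_equal(nrow(m2$ports), 2L)
  expect_identical(m2$arcs$target_ref[m2$arcs$id == "a1"], "p.1")
})

test_that("parse errors are specific", {
  expect_error(parse_sbgnml("<sbgn><map language='process description'><glyph"),
               "parse error")
  expect_error(parse_sbgnml(sub("macromolecule", "nanomachine", minimal_doc)),
               "unknown glyph class 'nanomachine' \\(id g1\\)")
  expect_error(parse_sbgnml(sub('language="process description"',
                                'language="activity flow"', minimal_doc)),
               "unsupported SBGN language")
  bad_arc <- sub("</map>",
                 '<arc class="consumption" id="x" source="g1" target="ghost"/></map>',
                 minimal_doc)
  expect_error(parse_sbgnml(bad_arc), "dangling reference")
  expect_error(read_sbgnml(file.path(tempdir(), "no-such-file.sbgn")),
               "not found")
})

test_that("unknown attributes survive a round trip as opaque extensions", {
  doc <- sub('<glyph class="macromolecule" id="g1">',
             '<glyph class="macromolecule" id="g1" orientation="horizontal">',
             minimal_doc)
  m <- parse_sbgnml(doc)
  out <- write_sbgnml(m)
  expect_match(out, 'orientation="horizontal"')
  expect_true(pd_map_equal(m, parse_sbgnml(out)))
})

test_that("an empty map writes to an empty map element and reparses", {
  out <- write_sbgnml(pd_map_new("empty"))
  m <- parse_sbgnml(out)
  expect_equal(n_glyphs(m), 0L)
  expect_equal(n_arcs(m), 0L)
})

test_that("writer refuses a structurally invalid map with a report", {
  bad <- pd_map_new() |>
    add_glyph("a", "macromolecule") |>
    add_glyph("p", "process") |>
    add_arc("consumption", "a", "p")   # process lacks a production arc
  expect_error(write_sbgnml(bad), "fails structural validation")
  expect_silent(write_sbgnml(bad, validate = FALSE))
})

test_that("one compartment + process + two EPNs yields 4 glyph, 2+ arc elements", {
  m <- pd_map_new() |>
    add_glyph("c", "compartment") |>
    add_glyph("s", "macromolecule", parent = "c") |>
    add_glyph("p", "process", parent = "c") |>
    add_glyph("t", "macromolecule", parent = "c") |>
    add_arc("consumption", "s", "p") |>
    add_arc("production", "p", "t")
  doc <- xml2::read_xml(write_sbgnml(m))
  xml2::xml_ns_strip(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//glyph")), 4L)
  expect_gte(length(xml2::xml_find_all(doc, "//arc")), 2L)
})

test_that("round trip is lossless on fixtures and generated maps", {
  for (nm in c("minimal_process", "fig1_like", "fig2_like", "fig4_like")) {
    m <- fixture(nm)
    expect_true(pd_map_equal(m, parse_sbgnml(write_sbgnml(m))), label = nm)
  }
  for (cfg in gen_config_grid(10, base_seed = 600L)) {
    m <- generate_map(cfg)
    m2 <- parse_sbgnml(write_sbgnml(m))
    expect_true(pd_map_equal(m, m2, bbox_tol = 1e-9))
    # parsing drops nothing
    expect_equal(n_glyphs(m2), n_glyphs(m))
    expect_equal(n_arcs(m2), n_arcs(m))
  }
})

test_that("packaged .sbgn fixture files equal their programmatic builders", {
  for (nm in c("minimal_process", "fig1_like", "fig2_like", "fig4_like")) {
    path <- system.file("extdata", paste0(nm, ".sbgn"), package = "sbgnpd")
    expect_true(nzchar(path), label = nm)
    expect_true(pd_map_equal(read_sbgnml(path), fixture(nm)), label = nm)
  }
})
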