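#' Structural well-formedness validation
#'
#' Checks the PD well-formedness assumptions every algorithm in this package
#' relies on, reporting rather than throwing: unique glyph ids; an acyclic
#' containment (parent) forest with legal parent classes and no compartment
#' nested inside a complex; arc endpoint roles legal per class (consumption
#' EPN to process, production process to EPN, modulation-family arcs EPN or
#' logic operator to process, logic arcs EPN/logic to logic operator); every
#' process with at least one consumption and one production arc; and
#' non-empty complexes.
#'
#' @param map a `pd_map`.
#' @return object of class `structure_report`: data frame with columns
#'   `check`, `pass`, `offending` (list column of glyph/arc ids); attribute
#'   `all_pass`.
#' @examples
#' validate_structure(fixture("minimal_process"))
#' @export
validate_structure <- function(map) {
  g <- map$glyphs
  a <- map$arcs
  cls_of <- function(ids) g$class[match(ids, g$id)]

  off_dup <- unique(g$id[duplicated(g$id)])

  # containment forest acyclic
  idx <- match(g$parent, g$id)
  off_cycle <- character(0)
  n <- nrow(g)
  for (i in seq_len(n)) {
    j <- idx[i]
    steps <- 0L
    while (!is.na(j)) {
      steps <- steps + 1L
      if (steps > n) { off_cycle <- c(off_cycle, g$id[i]); break }
      j <- idx[j]
    }
  }
  off_cycle <- unique(off_cycle)

  pcls <- cls_of(g$parent)
  off_parent <- g$id[!is.na(g$parent) &
                       (is.na(pcls) | !pcls %in% c("complex", "compartment"))]
  off_comp <- g$id[g$class == "compartment" & !is.na(g$parent) &
                     !is.na(pcls) & pcls == "complex"]

  scls <- cls_of(a$source)
  tcls <- cls_of(a$target)
  ok_role <- rep(TRUE, nrow(a))
  cons <- a$class == "consumption"
  ok_role[cons] <- is_epn_class(scls[cons]) & is_process_class(tcls[cons])
  prod <- a$class == "production"
  ok_role[prod] <- is_process_class(scls[prod]) & is_epn_class(tcls[prod])
  eff <- is_effector_class(a$class)
  ok_role[eff] <- (is_epn_class(scls[eff]) | is_logic_class(scls[eff])) &
    is_process_class(tcls[eff])
  lg <- a$class == "logic arc"
  ok_role[lg] <- (is_epn_class(scls[lg]) | is_logic_class(scls[lg])) &
    is_logic_class(tcls[lg])
  off_role <- a$id[!ok_role]

  procs <- g$id[is_process_class(g$class)]
  has_cons <- procs %in% a$target[a$class == "consumption"]
  has_prod <- procs %in% a$source[a$class == "production"]
  off_proc <- procs[!(has_cons & has_prod)]

  complexes <- g$id[g$class == "complex"]
  off_empty <- complexes[!complexes %in% g$parent]

  offending <- list(off_dup, off_cycle, off_parent, off_comp, off_role,
                    off_proc, off_empty)
  report <- data.frame(
    check = c("unique ids", "containment forest acyclic",
              "parents are complexes or compartments",
              "compartments not nested in complexes",
              "arc endpoint roles legal",
              "processes have consumption and production",
              "complexes non-empty"),
    pass = lengths(offending) == 0L,
    stringsAsFactors = FALSE
  )
  report$offending <- I(lapply(offending, function(x) sort(unique(x))))
  structure(report, class = c("structure_report", "data.frame"),
            all_pass = all(report$pass))
}

#' @export
print.structure_report <- function(x, ...) {
  cat(sprintf("<structure_report> %s\n",
              if (attr(x, "all_pass")) "map is structurally valid"
              else "STRUCTURAL PROBLEMS"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-4s %s", if (x$pass[i]) "ok" else "FAIL", x$check[i]))
    if (!x$pass[i]) cat(" — ", paste(x$offending[[i]], collapse = ", "))
    cat("\n")
  }
  invisible(x)
}

#' Configuration for the random map generator
#'
#' Collects and validates the knobs of [generate_map()]. Identical configs
#' (including `seed`) yield identical maps and byte-identical SBGN-ML.
#'
#' @param n_compartments number of compartments (may be 0; compartments may
#'   end up empty).
#' @param n_processes number of process nodes, at least 1.
#' @param n_epns number of top-level entity pool nodes, at least 2 (a process
#'   needs a substrate and a product).
#' @param complex_prob probability that an EPN is a complex (with 1-3
#'   members, recursively, down to `max_nest_depth`).
#' @param max_nest_depth maximum depth of the containment forest, counting
#'   compartment membership as one level (1 = flat map with empty
#'   compartments; complexes need at least 2).
#' @param effector_prob probability that a process gets a modulation-family
#'   arc.
#' @param seed RNG seed.
#' @return object of class `map_gen_config`.
#' @export
map_gen_config <- function(n_compartments = 2, n_processes = 10, n_epns = 20,
                           complex_prob = 0.2, max_nest_depth = 3,
                           effector_prob = 0.3, seed = 1) {
  if (n_compartments < 0 || n_processes < 1) {
    stop("config error: need n_compartments >= 0 and n_processes >= 1")
  }
  if (n_epns < 2) {
    stop("config error: n_epns must be >= 2 so a process can have a ",
         "substrate and a product")
  }
  if (complex_prob < 0 || complex_prob > 1 ||
      effector_prob < 0 || effector_prob > 1) {
    stop("config error: probabilities must lie in [0, 1]")
  }
  if (max_nest_depth < 1) stop("config error: max_nest_depth must be >= 1")
  structure(list(n_compartments = as.integer(n_compartments),
                 n_processes = as.integer(n_processes),
                 n_epns = as.integer(n_epns),
                 complex_prob = complex_prob,
                 max_nest_depth = as.integer(max_nest_depth),
                 effector_prob = effector_prob,
                 seed = as.integer(seed)),
            class = "map_gen_config")
}

LEAF_EPN_CLASSES <- c("macromolecule", "simple chemical",
                      "nucleic acid feature", "unspecified entity")

#' Generate a random structurally valid PD map
#'
#' Draws a seeded random SBGN-PD map: compartments, top-level EPNs (each a
#' complex with probability `complex_prob`, nesting recursively up to
#' `max_nest_depth`), and processes wired with 1-2 consumption and 1-2
#' production arcs to disjoint top-level EPNs plus optional effector arcs.
#' Bounding boxes are placed uniformly at random on a canvas that grows with
#' node count (the "laid out randomly" starting state the layout module is
#' meant to clean up). Every output passes [validate_structure()].
#'
#' @param config a [map_gen_config()].
#' @return a `pd_map`.
#' @examples
#' m <- generate_map(map_gen_config(n_processes = 3, n_epns = 6, seed = 42))
#' attr(validate_structure(m), "all_pass")
#' @export
generate_map <- function(config) {
  stopifnot(inherits(config, "map_gen_config"))
  with_local_seed(config$seed, {
    canvas <- 100 * sqrt(config$n_epns + config$n_processes +
                           config$n_compartments + 1)
    acc <- new.env(parent = emptyenv())
    acc$glyphs <- list()
    acc$arcs <- list()
    acc$n <- 0L
    put_glyph <- function(id, class, label, parent) {
      p <- round(stats::runif(2, 0, canvas), 3)
      sz <- default_bbox_size(class)
      acc$glyphs[[length(acc$glyphs) + 1L]] <- data.frame(
        id = id, class = class, label = label, parent = parent,
        x = p[1], y = p[2], w = sz[1], h = sz[2], stringsAsFactors = FALSE)
      id
    }
    put_arc <- function(class, source, target) {
      acc$arcs[[length(acc$arcs) + 1L]] <- data.frame(
        id = sprintf("arc%d", length(acc$arcs) + 1L), class = class,
        source = source, target = target, stringsAsFactors = FALSE)
    }
    new_id <- function(prefix) {
      acc$n <- acc$n + 1L
      sprintf("%s%d", prefix, acc$n)
    }

    comp_ids <- vapply(seq_len(config$n_compartments), function(i) {
      put_glyph(sprintf("comp%d", i), "compartment",
                sprintf("compartment %d", i), NA_character_)
    }, "")
    # membership in a compartment occupies one nesting level, so a depth-1
    # budget forces a flat map with empty compartments
    pick_compartment <- function() {
      if (!length(comp_ids) || config$max_nest_depth < 2L ||
          stats::runif(1) > 0.7) {
        return(NA_character_)
      }
      sample(comp_ids, 1)
    }

    # one EPN, recursively a complex subtree with prob complex_prob
    build_epn <- function(parent, depth) {
      if (depth < config$max_nest_depth &&
          stats::runif(1) < config$complex_prob) {
        id <- new_id("cx")
        put_glyph(id, "complex", id, parent)
        for (k in seq_len(sample(1:3, 1))) build_epn(id, depth + 1L)
        id
      } else {
        id <- new_id("epn")
        put_glyph(id, sample(LEAF_EPN_CLASSES, 1), id, parent)
      }
    }

    top_epns <- vapply(seq_len(config$n_epns), function(i) {
      parent <- pick_compartment()
      build_epn(parent, if (is.na(parent)) 1L else 2L)
    }, "")

    proc_classes <- c("process", "omitted process", "uncertain process")
    for (i in seq_len(config$n_processes)) {
      pid <- sprintf("proc%d", i)
      put_glyph(pid, sample(proc_classes, 1, prob = c(0.8, 0.1, 0.1)),
                pid, pick_compartment())
      n_sub <- min(sample(1:2, 1), length(top_epns) - 1L)
      subs <- sample(top_epns, n_sub)
      prods <- sample(setdiff(top_epns, subs),
                      min(sample(1:2, 1), length(top_epns) - n_sub))
      for (s in subs) put_arc("consumption", s, pid)
      for (pr in prods) put_arc("production", pid, pr)
      if (stats::runif(1) < config$effector_prob) {
        pool <- setdiff(top_epns, c(subs, prods))
        if (length(pool)) {
          put_arc(sample(c("catalysis", "stimulation", "inhibition"), 1),
                  sample(pool, 1), pid)
        }
      }
    }
    pd_map(do.call(rbind, acc$glyphs), do.call(rbind, acc$arcs),
           map_id = sprintf("gen-seed%d", config$seed))
  })
}

#' Deterministic fixture maps
#'
#' Hand-built maps mirroring the canonical focusing/hiding scenarios, used
#' throughout the test suite. Topology (counts, nesting, adjacency) is the
#' contract; labels and coordinates are cosmetic.
#'
#' * `minimal_process` — one process consuming one EPN, producing another:
#'   3 nodes, 2 arcs.
#' * `fig1_like` — a DNA-damage-response-style map with exactly 4 processes,
#'   two shared EPNs (the NBN analogs, each involved in two processes) and one
#'   complex (the MRN analog); the scenario where generic filtering of the
#'   shared-EPN selection leaves an invalid map while the domain-aware
#'   closure does not.
#' * `fig2_like` — two-level complex nesting (myosin inside a myosin complex
#'   inside an actin-myosin complex) within a muscle-cytosol compartment,
#'   3 processes; the focusing walkthrough.
#' * `fig4_like` — a linear phosphorylation chain (native kinase, two
#'   modified states) in one compartment; the hiding walkthrough where
#'   expanding the raw complement would hide nothing.
#'
#' @param name one of `"fig1_like"`, `"fig2_like"`, `"fig4_like"`,
#'   `"minimal_process"`.
#' @return a `pd_map`.
#' @export
fixture <- function(name) {
  known <- c("fig1_like", "fig2_like", "fig4_like", "minimal_process")
  if (length(name) != 1 || !name %in% known) {
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  }
  switch(name,
    minimal_process = fixture_minimal(),
    fig1_like = fixture_fig1(),
    fig2_like = fixture_fig2(),
    fig4_like = fixture_fig4()
  )
}

fixture_minimal <- function() {
  pd_map_new("minimal_process") |>
    add_glyph("ep_a", "macromolecule", label = "A", x = 20, y = 40) |>
    add_glyph("pr_p", "process", x = 140, y = 50) |>
    add_glyph("ep_b", "macromolecule", label = "B", x = 220, y = 40) |>
    add_arc("consumption", "ep_a", "pr_p", id = "a1") |>
    add_arc("production", "pr_p", "ep_b", id = "a2")
}

fixture_fig1 <- function() {
  m <- pd_map_new("fig1_like") |>
    add_glyph("cp_nuc", "compartment", label = "nucleoplasm",
              x = 0, y = 0, w = 900, h = 600) |>
    add_glyph("cx_mrn", "complex", label = "MRN", parent = "cp_nuc",
              x = 40, y = 60) |>
    add_glyph("m_mre11", "macromolecule", label = "MRE11", parent = "cx_mrn",
              x = 50, y = 70) |>
    add_glyph("m_rad50", "macromolecule", label = "RAD50", parent = "cx_mrn",
              x = 50, y = 100) |>
    add_glyph("m_nbn_c", "macromolecule", label = "NBN", parent = "cx_mrn",
              x = 50, y = 130)
  for (g in list(
    c("ep_nbn", "NBN"), c("ep_nbn_p", "NBN-P"),
    c("ep_atm", "ATM"), c("ep_atm_p", "ATM-P"),
    c("ep_ra", "repairA"), c("ep_ra_p", "repairA-P"),
    c("ep_rb", "repairB"), c("ep_rb_p", "repairB-P"))) {
    m <- add_glyph(m, g[1], "macromolecule", label = g[2], parent = "cp_nuc",
                   x = 200, y = 60)
  }
  for (p in c("pr1", "pr2", "pr3", "pr4")) {
    m <- add_glyph(m, p, "process", parent = "cp_nuc", x = 400, y = 60)
  }
  m |>
    add_arc("consumption", "ep_nbn", "pr1") |>
    add_arc("production", "pr1", "ep_nbn_p") |>
    add_arc("catalysis", "ep_atm", "pr1") |>
    add_arc("consumption", "ep_atm", "pr2") |>
    add_arc("production", "pr2", "ep_atm_p") |>
    add_arc("stimulation", "cx_mrn", "pr2") |>
    add_arc("consumption", "ep_ra", "pr3") |>
    add_arc("production", "pr3", "ep_ra_p") |>
    add_arc("catalysis", "ep_nbn_p", "pr3") |>
    add_arc("consumption", "ep_rb", "pr4") |>
    add_arc("production", "pr4", "ep_rb_p") |>
    add_arc("catalysis", "ep_nbn", "pr4")
}

fixture_fig2 <- function() {
  m <- pd_map_new("fig2_like") |>
    add_glyph("cp_cyto", "compartment", label = "muscle cytosol",
              x = 0, y = 0, w = 1000, h = 700) |>
    add_glyph("cx_actmyo", "complex", label = "actin-myosin",
              parent = "cp_cyto", x = 40, y = 60, w = 220, h = 160) |>
    add_glyph("cx_myosin", "complex", label = "myosin complex",
              parent = "cx_actmyo", x = 60, y = 80, w = 120, h = 90) |>
    add_glyph("m_myosin", "macromolecule", label = "myosin",
              parent = "cx_myosin", x = 70, y = 90) |>
    add_glyph("m_mlc", "macromolecule", label = "myosin light chain",
              parent = "cx_myosin", x = 70, y = 130) |>
    add_glyph("m_actin", "macromolecule", label = "actin",
              parent = "cx_actmyo", x = 60, y = 180)
  for (g in list(
    c("ep_atp", "ATP"), c("ep_adp", "ADP"), c("ep_myop", "myosin-P"),
    c("ep_mlck", "MLCK"), c("ep_ca", "Ca2+"),
    c("ep_amact", "active actomyosin"),
    c("ep_x1", "bystanderA"), c("ep_x2", "bystanderA-P"))) {
    m <- add_glyph(m, g[1], "simple chemical", label = g[2],
                   parent = "cp_cyto", x = 400, y = 100)
  }
  for (p in c("pr_bind", "pr_contract", "pr_other")) {
    m <- add_glyph(m, p, "process", parent = "cp_cyto", x = 600, y = 100)
  }
  m |>
    add_arc("consumption", "cx_myosin", "pr_bind") |>
    add_arc("consumption", "ep_atp", "pr_bind") |>
    add_arc("production", "pr_bind", "ep_myop") |>
    add_arc("production", "pr_bind", "ep_adp") |>
    add_arc("catalysis", "ep_mlck", "pr_bind") |>
    add_arc("consumption", "cx_actmyo", "pr_contract") |>
    add_arc("consumption", "ep_ca", "pr_contract") |>
    add_arc("production", "pr_contract", "ep_amact") |>
    add_arc("consumption", "ep_x1", "pr_other") |>
    add_arc("production", "pr_other", "ep_x2") |>
    add_arc("catalysis", "ep_myop", "pr_other")
}

fixture_fig4 <- function() {
  m <- pd_map_new("fig4_like") |>
    add_glyph("cp_cyto", "compartment", label = "cytosol",
              x = 0, y = 0, w = 900, h = 400)
  for (g in list(
    c("ep_rsk0", "RSK"), c("ep_rsk1", "RSK-P"), c("ep_rsk2", "RSK-PP"),
    c("ep_k1", "kinase1"), c("ep_k2", "kinase2"))) {
    m <- add_glyph(m, g[1], "macromolecule", label = g[2],
                   parent = "cp_cyto", x = 100, y = 100)
  }
  m <- m |>
    add_glyph("pr_p1", "process", parent = "cp_cyto", x = 250, y = 120) |>
    add_glyph("pr_p2", "process", parent = "cp_cyto", x = 550, y = 120)
  m |>
    add_arc("consumption", "ep_rsk0", "pr_p1") |>
    add_arc("production", "pr_p1", "ep_rsk1") |>
    add_arc("catalysis", "ep_k1", "pr_p1") |>
    add_arc("consumption", "ep_rsk1", "pr_p2") |>
    add_arc("production", "pr_p2", "ep_rsk2") |>
    add_arc("catalysis", "ep_k2", "pr_p2")
}
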