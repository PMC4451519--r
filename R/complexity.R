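#' Expand a node group to the minimal valid sub-map
#'
#' The focusing closure: given a user-selected node group, compute the minimal
#' superset whose induced sub-map is a valid, complete PD map — every selected
#' EPN keeps all the processes it is involved with, every triggered process
#' keeps all its substrates, products and effectors, every node keeps its
#' containing complex/compartment chain, and every complex keeps all its
#' members.
#'
#' The algorithm is a fixed straight-line sequence executed exactly once, in
#' order:
#' 1. union in all descendants of the group;
#' 2. union in all ancestors;
#' 3. union in the members (descendants) of every complex now in the group;
#' 4.-5. split the group into processes and non-processes;
#' 6. collect the process neighbors of the non-processes;
#' 7. union in the neighborhoods of the in-group processes, the neighbor
#'    processes themselves, and the neighborhoods of those neighbor processes;
#' 8. union in ancestors again (participants may live in unseen containers);
#' 9. union in complex members again (participants may be complexes).
#'
#' It is deliberately *not* iterated to a fixpoint: EPNs that enter the set as
#' process participants would, on a second pass, pull in all *their* other
#' processes, and repeating that floods the whole connected component —
#' defeating the point of a minimal focus. Consequently `expand_nodes` is
#' inflationary and monotone but not idempotent.
#'
#' @param map a `pd_map`.
#' @param group character vector of selected glyph ids; empty in, empty out.
#' @return the expanded node group (sorted glyph ids, a superset of `group`).
#' @examples
#' m <- fixture("fig2_like")
#' expand_nodes(m, c("cx_myosin", "pr_bind"))
#' @export
expand_nodes <- function(map, group) {
  group <- check_group(map, group)
  if (!length(group)) return(character(0))
  .pd_state$expand_passes <- .pd_state$expand_passes + 1L

  ng <- group
  ng <- union(ng, descendants(map, ng))                                    # 1
  ng <- union(ng, ancestors(map, ng))                                      # 2
  ng <- union(ng, descendants(map, select_by_class(map, ng, "complex")))   # 3
  processes <- select_by_class(map, ng, "process")                         # 4
  non_processes <- select_by_class(map, ng, "not-process")                 # 5
  neighbor_processes <- neighborhood(map, non_processes, "process")        # 6
  ng <- union(ng, neighborhood(map, processes))                            # 7
  ng <- union(ng, neighbor_processes)
  ng <- union(ng, neighborhood(map, neighbor_processes))
  ng <- union(ng, ancestors(map, ng))                                      # 8
  ng <- union(ng, descendants(map, select_by_class(map, ng, "complex")))   # 9
  sort(ng)                                                                 # 10
}

#' Instrumentation counter for expansion passes
#'
#' Each call to [expand_nodes()] on a non-empty group executes its
#' straight-line body exactly once and increments this counter by one. Used to
#' assert single-pass semantics (no hidden fixpoint iteration).
#'
#' @param reset if `TRUE`, zero the counter and return the old value.
#' @return integer count of passes since load/reset.
#' @export
expand_pass_count <- function(reset = FALSE) {
  n <- .pd_state$expand_passes
  if (reset) .pd_state$expand_passes <- 0L
  n
}

#' Visibility state of a map
#'
#' The product of the Show/Hide Selected operations: which glyphs and arcs are
#' currently displayed. Arcs are derived state — an arc is shown iff both its
#' endpoint glyphs are shown — so a valid state can never contain a dangling
#' arc.
#'
#' @param map a `pd_map`.
#' @param shown_nodes character vector of visible glyph ids.
#' @param empty_warning flag set when a hide operation legitimately emptied
#'   the map.
#' @return object of class `visibility_state`: list with `shown_nodes`,
#'   `shown_arcs`, `hidden_nodes`, `empty_warning`.
#' @export
visibility_state <- function(map, shown_nodes, empty_warning = FALSE) {
  shown_nodes <- sort(check_group(map, shown_nodes))
  a <- map$arcs
  shown_arcs <- sort(a$id[a$source %in% shown_nodes &
                            a$target %in% shown_nodes])
  structure(
    list(shown_nodes = shown_nodes, shown_arcs = shown_arcs,
         hidden_nodes = sort(setdiff(map$glyphs$id, shown_nodes)),
         empty_warning = isTRUE(empty_warning)),
    class = "visibility_state"
  )
}

#' @export
print.visibility_state <- function(x, ...) {
  cat(sprintf("<visibility_state> %d nodes shown, %d hidden, %d arcs shown%s\n",
              length(x$shown_nodes), length(x$hidden_nodes),
              length(x$shown_arcs),
              if (x$empty_warning) " [empty-map warning]" else ""))
  invisible(x)
}

#' Focus on a node group ("Show Selected")
#'
#' Expands the selection with [expand_nodes()] and shows exactly the closure:
#' the result is always a valid, complete sub-map (all five sub-map invariants
#' hold, see [check_invariants()]).
#'
#' @inheritParams expand_nodes
#' @return a [visibility_state()].
#' @export
show_selected <- function(map, group) {
  group <- check_group(map, group)
  if (!length(group)) {
    stop("empty selection: select at least one node to focus on")
  }
  visibility_state(map, expand_nodes(map, group))
}

#' Expand the complement of a node group
#'
#' The core of the hide operation. Expanding the raw complement of a selection
#' is wrong: the complement contains processes adjacent to the selected nodes,
#' and expanding it would pull the selection straight back in — often hiding
#' nothing at all. Instead the selection is expanded *first*; the complement
#' of that closure is then expanded, and that second closure is what gets
#' shown. The two closures may still overlap (typically on shared containers
#' such as a compartment) — that is intended.
#'
#' @inheritParams expand_nodes
#' @param all_elems the current visible universe (glyph ids); defaults to the
#'   whole map. Expansion is evaluated on the sub-map induced by this
#'   universe, so successive hides compose.
#' @return node group to keep visible (sorted glyph ids).
#' @export
expand_remaining_nodes <- function(map, group, all_elems = glyph_ids(map)) {
  all_elems <- check_group(map, all_elems)
  group <- check_group(map, group)
  extra <- setdiff(group, all_elems)
  if (length(extra)) {
    stop("selection outside the visible universe: ",
         paste(extra, collapse = ", "))
  }
  sub <- restrict_map(map, all_elems)
  ng <- expand_nodes(sub, group)
  remaining <- setdiff(all_elems, ng)
  expand_nodes(sub, remaining)
}

#' Ignore a node group ("Hide Selected")
#'
#' Hides a selection by showing [expand_remaining_nodes()] of it: everything
#' outside the complement-closure is hidden, and no dangling references can
#' arise. Hiding nothing keeps everything; hiding everything yields an empty
#' state with `empty_warning` set (the analog of a blank canvas, not an
#' error). Chained hiding is supported by passing the previous state's
#' `shown_nodes` as `all_elems`.
#'
#' @inheritParams expand_remaining_nodes
#' @return a [visibility_state()] over `map`; nodes outside `all_elems` are
#'   hidden too.
#' @export
hide_selected <- function(map, group, all_elems = glyph_ids(map)) {
  shown <- expand_remaining_nodes(map, group, all_elems)
  visibility_state(map, shown, empty_warning = length(shown) == 0L)
}

#' Check the five sub-map validity invariants
#'
#' Evaluates a visibility state against the five invariants a complexity-
#' management operation must keep intact for the shown sub-map \eqn{S}:
#' 1. every node specified in the selection is shown;
#' 2. for every selected non-process node, every process it is involved with
#'    is shown;
#' 3. for every shown *triggered* process, all of its substrates, products and
#'    effectors are shown — the trigger set contains exactly the processes the
#'    expansion algorithm grants full participant sets: processes in the
#'    selection's containment closure plus processes adjacent to its
#'    non-process members;
#' 4. for every shown node, its parent complex/compartment chain is shown;
#' 5. every shown complex is shown with all of its members, transitively.
#'
#' @param map a `pd_map`.
#' @param initial_selection the node group the operation started from.
#' @param state a [visibility_state()].
#' @return object of class `invariant_report`: data frame with columns
#'   `invariant` (1-5), `pass`, `offending` (list column of glyph ids) and
#'   `description`; attribute `all_pass`.
#' @export
check_invariants <- function(map, initial_selection, state) {
  sel <- check_group(map, initial_selection)
  s <- check_group(map, state$shown_nodes)
  a <- map$arcs

  # 1: selection shown
  off1 <- setdiff(sel, s)

  # 2: processes of selected non-process nodes shown
  sel_nonproc <- select_by_class(map, sel, "not-process")
  off2 <- setdiff(neighborhood(map, sel_nonproc, "process"), s)

  # 3: triggered processes complete. Trigger set replays expansion lines 1-6.
  trig <- character(0)
  if (length(sel)) {
    ng <- sel
    ng <- union(ng, descendants(map, ng))
    ng <- union(ng, ancestors(map, ng))
    ng <- union(ng, descendants(map, select_by_class(map, ng, "complex")))
    trig <- union(select_by_class(map, ng, "process"),
                  neighborhood(map, select_by_class(map, ng, "not-process"),
                               "process"))
  }
  trig <- intersect(trig, s)
  participants <- unique(c(
    a$source[a$class == "consumption" & a$target %in% trig],
    a$target[a$class == "production" & a$source %in% trig],
    a$source[is_effector_class(a$class) & a$target %in% trig]
  ))
  off3 <- setdiff(participants, s)

  # 4: ancestor closure
  off4 <- setdiff(ancestors(map, s), s)

  # 5: complex completeness
  shown_complexes <- select_by_class(map, s, "complex")
  off5 <- setdiff(descendants(map, shown_complexes), s)

  offending <- list(off1, off2, off3, off4, off5)
  report <- data.frame(
    invariant = 1:5,
    pass = lengths(offending) == 0L,
    description = c(
      "selected nodes are shown",
      "processes of selected non-process nodes are shown",
      "triggered processes keep all substrates, products, effectors",
      "parent complexes/compartments of shown nodes are shown",
      "shown complexes keep all members"
    ),
    stringsAsFactors = FALSE
  )
  report$offending <- I(lapply(offending, sort))
  structure(report, class = c("invariant_report", "data.frame"),
            all_pass = all(report$pass))
}

#' @export
print.invariant_report <- function(x, ...) {
  cat(sprintf("<invariant_report> %s\n",
              if (attr(x, "all_pass")) "all 5 invariants hold"
              else "INVARIANT VIOLATIONS"))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%d] %-4s %s", x$invariant[i],
                if (x$pass[i]) "ok" else "FAIL", x$description[i]))
    if (!x$pass[i]) {
      cat(" — offending: ", paste(x$offending[[i]], collapse = ", "))
    }
    cat("\n")
  }
  invisible(x)
}

#' Extract the shown sub-map
#'
#' Materializes a visibility state as a standalone `pd_map` restricted to the
#' shown glyphs and arcs. Requires the state to be ancestor-closed (as every
#' state produced by [show_selected()]/[hide_selected()] is), so no parent
#' link can point at a hidden node; the result passes structural validation
#' and can be written back to SBGN-ML.
#'
#' @param map a `pd_map`.
#' @param state a [visibility_state()].
#' @return a new `pd_map`.
#' @export
induced_submap <- function(map, state) {
  s <- check_group(map, state$shown_nodes)
  open <- setdiff(ancestors(map, s), s)
  if (length(open)) {
    stop("visibility state is not ancestor-closed; hidden ancestor(s): ",
         paste(open, collapse = ", "))
  }
  sub <- restrict_map(map, s)
  sub$arcs <- sub$arcs[sub$arcs$id %in% state$shown_arcs, , drop = FALSE]
  sub
}
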