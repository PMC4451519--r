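#' Compound-graph set operators
#'
#' The four primitive operators the complexity-management closures are written
#' in: transitive containment down (`descendants`) and up (`ancestors`),
#' class-based selection, and arc adjacency. All take and return plain
#' character vectors of glyph ids ("node groups"); the group members
#' themselves are never part of the result — callers union explicitly.
#'
#' `ancestors()` and `descendants()` are transitive, not one-level: a
#' macromolecule inside a complex inside a compartment has both the complex
#' and the compartment as ancestors, so that containment closure holds for
#' arbitrarily deep complex-in-complex-in-compartment chains.
#'
#' `neighborhood()` is undirected and counts every arc class except
#' equivalence arcs (which are cosmetic tag links, ignored by all closure
#' algorithms); logic arcs do count, so logic operators participate in
#' adjacency like effector EPNs.
#'
#' @param map a `pd_map`.
#' @param group character vector of glyph ids; an unknown id is an error
#'   naming it.
#' @return character vector of glyph ids (sorted, no duplicates), excluding
#'   `group` members.
#' @examples
#' m <- fixture("fig2_like")
#' ancestors(m, "cx_myosin")   # enclosing complex, then compartment
#' descendants(m, "cx_actmyo") # all transitive members
#' @export
descendants <- function(map, group) {
  group <- check_group(map, group)
  if (!length(group)) return(character(0))
  parent <- map$glyphs$parent
  ids <- map$glyphs$id
  all <- group
  frontier <- group
  repeat {
    kids <- ids[!is.na(parent) & parent %in% frontier]
    new <- setdiff(kids, all)
    if (!length(new)) break
    all <- c(all, new)
    frontier <- new
  }
  sort(setdiff(all, group))
}

#' @rdname descendants
#' @export
ancestors <- function(map, group) {
  group <- check_group(map, group)
  if (!length(group)) return(character(0))
  parent <- map$glyphs$parent
  ids <- map$glyphs$id
  all <- group
  frontier <- group
  repeat {
    up <- parent[match(frontier, ids)]
    up <- unique(up[!is.na(up)])
    new <- setdiff(up, all)
    if (!length(new)) break
    all <- c(all, new)
    frontier <- new
  }
  sort(setdiff(all, group))
}

#' Filter a node group by class role
#'
#' Mirrors the selectors of the closure pseudocode: `"process"` keeps the five
#' process-node classes, `"not-process"` keeps everything else (EPNs,
#' compartments, logic operators, phenotypes, tags), `"complex"` keeps
#' complexes only.
#'
#' @inheritParams descendants
#' @param selector one of `"process"`, `"not-process"`, `"complex"`.
#' @return the matching subset of `group`, sorted.
#' @export
select_by_class <- function(map, group,
                            selector = c("process", "not-process", "complex")) {
  selector <- match.arg(selector)
  group <- check_group(map, group)
  if (!length(group)) return(character(0))
  cls <- glyph_class_of(map, group)
  keep <- switch(selector,
    "process" = is_process_class(cls),
    "not-process" = !is_process_class(cls),
    "complex" = cls == "complex"
  )
  sort(group[keep])
}

#' Arc neighborhood of a node group
#'
#' All glyphs connected to any group member by an arc in either direction
#' (equivalence arcs excluded), minus the group itself, optionally filtered by
#' a class selector.
#'
#' @inheritParams select_by_class
#' @param class_filter optional selector applied to the result
#'   (`"process"`, `"not-process"`, `"complex"`), or `NULL` for no filter.
#' @return character vector of neighbor glyph ids, sorted.
#' @export
neighborhood <- function(map, group, class_filter = NULL) {
  group <- check_group(map, group)
  if (!length(group)) return(character(0))
  a <- map$arcs[map$arcs$class != "equivalence arc", , drop = FALSE]
  nb <- c(a$target[a$source %in% group], a$source[a$target %in% group])
  nb <- sort(setdiff(unique(nb), group))
  if (!is.null(class_filter) && length(nb)) {
    nb <- select_by_class(map, nb, class_filter)
  }
  nb
}
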