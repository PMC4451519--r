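#' Construct a process-description map
#'
#' A `pd_map` is the in-memory compound-graph model of an SBGN-PD map: a glyph
#' table (nodes, with a `parent` column encoding both complex membership and
#' compartment location), an arc table (edges, endpoints already resolved to
#' glyph ids), an optional port table, and auxiliary decorations (state
#' variables, units of information) attached to their owner glyphs.
#'
#' The constructor enforces referential integrity — unique known-class glyph
#' ids, parent and arc endpoints that exist, parents of class complex or
#' compartment, no self-arcs — but deliberately not full PD well-formedness
#' (arc role legality, process completeness, parent acyclicity), which is the
#' job of [validate_structure()] so that broken maps can be built and reported
#' on.
#'
#' @param glyphs data frame with columns `id`, `class`, `label`, `parent`
#'   (`NA` for root glyphs), `x`, `y`, `w`, `h`.
#' @param arcs data frame with columns `id`, `class`, `source`, `target`
#'   (glyph ids), or `NULL` for none.
#' @param ports data frame with columns `id`, `owner`, `x`, `y`, or `NULL`.
#' @param aux named list: owner glyph id -> list of decorations, each a list
#'   with `id`, `class`, `label` and a numeric `bbox` c(x, y, w, h).
#' @param map_id id attribute for the SBGN-ML map element.
#' @param extra named list: glyph/arc id -> named character vector of unknown
#'   XML attributes preserved from parsing.
#' @return an object of class `pd_map`.
#' @seealso [pd_map_new()] for the incremental builder used by fixtures.
#' @export
pd_map <- function(glyphs = NULL, arcs = NULL, ports = NULL, aux = list(),
                   map_id = "map1", extra = list()) {
  glyphs <- normalize_glyphs(glyphs)
  arcs <- normalize_arcs(arcs)
  ports <- normalize_ports(ports)

  if (anyDuplicated(glyphs$id)) {
    stop("duplicate glyph id(s): ",
         paste(unique(glyphs$id[duplicated(glyphs$id)]), collapse = ", "))
  }
  bad_class <- setdiff(unique(glyphs$class), PD_GLYPH_CLASSES)
  if (length(bad_class)) {
    off <- glyphs$id[glyphs$class %in% bad_class]
    stop("unknown glyph class(es): ",
         paste(sprintf("%s (id %s)", glyphs$class[glyphs$class %in% bad_class],
                       off), collapse = ", "))
  }
  pre <- glyphs$parent[!is.na(glyphs$parent)]
  missing_parent <- setdiff(pre, glyphs$id)
  if (length(missing_parent)) {
    stop("parent id(s) not in map: ", paste(missing_parent, collapse = ", "))
  }
  pcls <- glyphs$class[match(glyphs$parent, glyphs$id)]
  bad_parent <- !is.na(glyphs$parent) & !pcls %in% c("complex", "compartment")
  if (any(bad_parent)) {
    stop("glyph(s) with a parent that is neither complex nor compartment: ",
         paste(glyphs$id[bad_parent], collapse = ", "))
  }
  comp_in_complex <- glyphs$class == "compartment" & !is.na(glyphs$parent) &
    pcls == "complex"
  if (any(comp_in_complex)) {
    stop("compartment(s) nested inside a complex: ",
         paste(glyphs$id[comp_in_complex], collapse = ", "))
  }
  if (nrow(arcs)) {
    bad_cls <- setdiff(unique(arcs$class), PD_ARC_CLASSES)
    if (length(bad_cls)) {
      stop("unknown arc class(es): ", paste(bad_cls, collapse = ", "))
    }
    ends <- unique(c(arcs$source, arcs$target))
    dangling <- setdiff(ends, glyphs$id)
    if (length(dangling)) {
      stop("arc endpoint(s) referencing nonexistent glyphs: ",
           paste(dangling, collapse = ", "))
    }
    if (any(arcs$source == arcs$target)) {
      stop("self-arc(s): ",
           paste(arcs$id[arcs$source == arcs$target], collapse = ", "))
    }
  }
  if (nrow(ports)) {
    miss <- setdiff(unique(ports$owner), glyphs$id)
    if (length(miss)) {
      stop("port owner(s) not in map: ", paste(miss, collapse = ", "))
    }
  }
  bad_aux <- setdiff(names(aux), glyphs$id)
  if (length(bad_aux)) {
    stop("auxiliary decoration owner(s) not in map: ",
         paste(bad_aux, collapse = ", "))
  }

  structure(
    list(glyphs = glyphs, arcs = arcs, ports = ports, aux = aux,
         map_id = map_id, extra = extra),
    class = "pd_map"
  )
}

normalize_glyphs <- function(glyphs) {
  if (is.null(glyphs) || !NROW(glyphs)) {
    return(data.frame(id = character(), class = character(),
                      label = character(), parent = character(),
                      x = numeric(), y = numeric(), w = numeric(),
                      h = numeric(), stringsAsFactors = FALSE))
  }
  glyphs <- as.data.frame(glyphs, stringsAsFactors = FALSE)
  if (is.null(glyphs$label)) glyphs$label <- ""
  if (is.null(glyphs$parent)) glyphs$parent <- NA_character_
  for (col in c("x", "y")) if (is.null(glyphs[[col]])) glyphs[[col]] <- 0
  for (col in c("w", "h")) if (is.null(glyphs[[col]])) glyphs[[col]] <- 0
  glyphs$class <- canon_glyph_class(as.character(glyphs$class))
  glyphs$id <- as.character(glyphs$id)
  glyphs$label <- as.character(glyphs$label)
  glyphs$parent <- as.character(glyphs$parent)
  if (any(glyphs$w < 0 | glyphs$h < 0, na.rm = TRUE)) {
    stop("negative bbox width/height")
  }
  rownames(glyphs) <- NULL
  glyphs[c("id", "class", "label", "parent", "x", "y", "w", "h")]
}

normalize_arcs <- function(arcs) {
  if (is.null(arcs) || !NROW(arcs)) {
    return(data.frame(id = character(), class = character(),
                      source = character(), target = character(),
                      source_ref = character(), target_ref = character(),
                      stringsAsFactors = FALSE))
  }
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  if (is.null(arcs$source_ref)) arcs$source_ref <- arcs$source
  if (is.null(arcs$target_ref)) arcs$target_ref <- arcs$target
  for (col in c("id", "class", "source", "target", "source_ref", "target_ref"))
    arcs[[col]] <- as.character(arcs[[col]])
  rownames(arcs) <- NULL
  arcs[c("id", "class", "source", "target", "source_ref", "target_ref")]
}

normalize_ports <- function(ports) {
  if (is.null(ports) || !NROW(ports)) {
    return(data.frame(id = character(), owner = character(),
                      x = numeric(), y = numeric(), stringsAsFactors = FALSE))
  }
  ports <- as.data.frame(ports, stringsAsFactors = FALSE)
  ports$id <- as.character(ports$id)
  ports$owner <- as.character(ports$owner)
  rownames(ports) <- NULL
  ports[c("id", "owner", "x", "y")]
}

#' Incrementally build a map
#'
#' `pd_map_new()` starts an empty map; `add_glyph()`, `add_arc()`,
#' `add_port()` and `add_aux()` each return the enlarged map, so fixtures can
#' be written as pipelines. Referential checks run on every addition.
#'
#' @param map_id id for the map element.
#' @return a `pd_map`.
#' @examples
#' m <- pd_map_new() |>
#'   add_glyph("a", "macromolecule", label = "kinase") |>
#'   add_glyph("p1", "process") |>
#'   add_glyph("b", "macromolecule", label = "kinase-P") |>
#'   add_arc("consumption", "a", "p1") |>
#'   add_arc("production", "p1", "b")
#' n_glyphs(m)
#' @export
pd_map_new <- function(map_id = "map1") {
  pd_map(map_id = map_id)
}

default_bbox_size <- function(class) {
  if (class %in% PD_PROCESS_CLASSES) return(c(20, 20))
  if (class %in% PD_LOGIC_CLASSES) return(c(30, 30))
  if (class == "simple chemical") return(c(40, 40))
  if (class == "compartment") return(c(300, 200))
  if (class == "complex") return(c(120, 80))
  c(80, 40)
}

#' @rdname pd_map_new
#' @param map a `pd_map`.
#' @param id glyph id (unique within the map).
#' @param class glyph class, one of `PD_GLYPH_CLASSES`.
#' @param label display label; cosmetic.
#' @param parent id of the containing complex or compartment, or `NA`.
#' @param x,y,w,h bounding box (top-left origin, y grows downward); `w`/`h`
#'   default to a class-typical size.
#' @export
add_glyph <- function(map, id, class, label = "", parent = NA_character_,
                      x = 0, y = 0, w = NULL, h = NULL) {
  stopifnot(inherits(map, "pd_map"))
  class <- canon_glyph_class(class)
  sz <- default_bbox_size(class)
  row <- data.frame(id = id, class = class, label = label,
                    parent = as.character(parent),
                    x = x, y = y, w = w %||% sz[1], h = h %||% sz[2],
                    stringsAsFactors = FALSE)
  pd_map(rbind(map$glyphs, row), map$arcs, map$ports, map$aux,
         map$map_id, map$extra)
}

#' @rdname pd_map_new
#' @param source,target endpoint glyph ids (after port resolution).
#' @export
add_arc <- function(map, class, source, target, id = NULL) {
  stopifnot(inherits(map, "pd_map"))
  id <- id %||% sprintf("arc%d", nrow(map$arcs) + 1L)
  row <- data.frame(id = id, class = class, source = source, target = target,
                    source_ref = source, target_ref = target,
                    stringsAsFactors = FALSE)
  pd_map(map$glyphs, rbind(map$arcs, row), map$ports, map$aux,
         map$map_id, map$extra)
}

#' @rdname pd_map_new
#' @param owner id of the glyph the port/decoration belongs to.
#' @export
add_port <- function(map, id, owner, x = 0, y = 0) {
  stopifnot(inherits(map, "pd_map"))
  row <- data.frame(id = id, owner = owner, x = x, y = y,
                    stringsAsFactors = FALSE)
  pd_map(map$glyphs, map$arcs, rbind(map$ports, row), map$aux,
         map$map_id, map$extra)
}

#' @rdname pd_map_new
#' @param aux_class one of `PD_AUX_CLASSES`.
#' @param bbox numeric `c(x, y, w, h)` of the decoration.
#' @export
add_aux <- function(map, owner, aux_class, label = "", id = NULL,
                    bbox = c(0, 0, 20, 10)) {
  stopifnot(inherits(map, "pd_map"), aux_class %in% PD_AUX_CLASSES)
  aux <- map$aux
  n <- sum(lengths(aux))
  entry <- list(id = id %||% sprintf("aux%d", n + 1L), class = aux_class,
                label = label, bbox = as.numeric(bbox))
  aux[[owner]] <- c(aux[[owner]], list(entry))
  pd_map(map$glyphs, map$arcs, map$ports, aux, map$map_id, map$extra)
}

#' Map accessors
#'
#' Small helpers over the `pd_map` tables: glyph/arc id vectors, counts,
#' direct children, parent lookup, and the maximum nesting depth of the
#' containment forest (a flat map has depth 1).
#'
#' @param map a `pd_map`.
#' @return `glyph_ids()`/`arc_ids()` character vectors; `n_glyphs()`/
#'   `n_arcs()` integers; `children_of()` the ids directly contained in `id`;
#'   `parent_of()` the parent id or `NA`; `nesting_depth()` an integer.
#' @export
glyph_ids <- function(map) map$glyphs$id

#' @rdname glyph_ids
#' @export
arc_ids <- function(map) map$arcs$id

#' @rdname glyph_ids
#' @export
n_glyphs <- function(map) nrow(map$glyphs)

#' @rdname glyph_ids
#' @export
n_arcs <- function(map) nrow(map$arcs)

#' @rdname glyph_ids
#' @param id a single glyph id.
#' @export
children_of <- function(map, id) {
  check_group(map, id)
  map$glyphs$id[!is.na(map$glyphs$parent) & map$glyphs$parent == id]
}

#' @rdname glyph_ids
#' @export
parent_of <- function(map, id) {
  check_group(map, id)
  map$glyphs$parent[match(id, map$glyphs$id)]
}

#' @rdname glyph_ids
#' @export
nesting_depth <- function(map) {
  if (!n_glyphs(map)) return(0L)
  depth <- rep(1L, n_glyphs(map))
  parent <- map$glyphs$parent
  idx <- match(parent, map$glyphs$id)
  for (i in seq_len(n_glyphs(map))) {
    d <- 1L
    j <- idx[i]
    while (!is.na(j) && d <= n_glyphs(map)) {
      d <- d + 1L
      j <- idx[j]
    }
    depth[i] <- d
  }
  max(depth)
}

glyph_class_of <- function(map, ids) {
  map$glyphs$class[match(ids, map$glyphs$id)]
}

# Validate a node group against a map: character vector, existing ids.
check_group <- function(map, ids) {
  if (is.null(ids) || !length(ids)) return(character(0))
  ids <- as.character(ids)
  unknown <- setdiff(ids, map$glyphs$id)
  if (length(unknown)) {
    stop("unknown glyph id(s): ", paste(unknown, collapse = ", "))
  }
  unique(ids)
}

# Restrict a map to a glyph subset for algorithmic purposes: arcs with a
# missing endpoint are dropped, parent links out of the subset are severed.
# Unlike induced_submap() this never errors on closure violations.
restrict_map <- function(map, keep) {
  keep <- unique(as.character(keep))
  g <- map$glyphs[map$glyphs$id %in% keep, , drop = FALSE]
  g$parent[!g$parent %in% g$id] <- NA_character_
  a <- map$arcs[map$arcs$source %in% g$id & map$arcs$target %in% g$id,
                , drop = FALSE]
  p <- map$ports[map$ports$owner %in% g$id, , drop = FALSE]
  aux <- map$aux[names(map$aux) %in% g$id]
  pd_map(g, a, p, aux, map$map_id, map$extra[names(map$extra) %in%
                                               c(g$id, a$id)])
}

#' Compare two maps structurally
#'
#' Two maps are structurally equal when they have identical glyph id sets with
#' identical classes, labels and parent links, identical arc sets (id, class,
#' resolved endpoints), and bounding boxes agreeing within `bbox_tol`. This is
#' the round-trip comparator: ids are preserved by I/O, so equality is checked
#' id-by-id rather than by graph isomorphism search.
#'
#' @param a,b `pd_map` objects.
#' @param bbox_tol absolute tolerance on bbox coordinates.
#' @return `TRUE`/`FALSE`.
#' @export
pd_map_equal <- function(a, b, bbox_tol = 1e-9) {
  ga <- a$glyphs[order(a$glyphs$id), , drop = FALSE]
  gb <- b$glyphs[order(b$glyphs$id), , drop = FALSE]
  if (!identical(ga$id, gb$id)) return(FALSE)
  if (!identical(ga$class, gb$class)) return(FALSE)
  if (!identical(ga$label, gb$label)) return(FALSE)
  pa <- ga$parent; pb <- gb$parent
  if (!identical(is.na(pa), is.na(pb))) return(FALSE)
  if (!identical(pa[!is.na(pa)], pb[!is.na(pb)])) return(FALSE)
  for (col in c("x", "y", "w", "h")) {
    if (length(ga[[col]]) &&
        max(abs(ga[[col]] - gb[[col]]), 0) > bbox_tol) return(FALSE)
  }
  aa <- a$arcs[order(a$arcs$id), , drop = FALSE]
  ab <- b$arcs[order(b$arcs$id), , drop = FALSE]
  if (!identical(aa$id, ab$id)) return(FALSE)
  if (!identical(aa$class, ab$class)) return(FALSE)
  if (!identical(aa$source, ab$source)) return(FALSE)
  if (!identical(aa$target, ab$target)) return(FALSE)
  TRUE
}

#' @export
print.pd_map <- function(x, ...) {
  cls <- table(x$glyphs$class)
  cat(sprintf("<pd_map '%s'> %d glyphs, %d arcs, nesting depth %d\n",
              x$map_id, n_glyphs(x), n_arcs(x), nesting_depth(x)))
  if (length(cls)) {
    cat("  glyphs:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
        "\n")
  }
  if (nrow(x$arcs)) {
    acl <- table(x$arcs$class)
    cat("  arcs:  ", paste(sprintf("%s=%d", names(acl), acl), collapse = ", "),
        "\n")
  }
  invisible(x)
}
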