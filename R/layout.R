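#' Configuration for the compound layout
#'
#' @param iterations spring-embedder iterations per sibling group.
#' @param ideal_edge_length target arc length in map units.
#' @param compartment_padding margin, in map units, between a container's
#'   border and its children; must be positive for strict containment.
#' @param seed RNG seed for the initial placement; identical (map, config)
#'   pairs give identical coordinates.
#' @return object of class `layout_config`.
#' @export
layout_config <- function(iterations = 80, ideal_edge_length = 80,
                          compartment_padding = 20, seed = 1) {
  if (compartment_padding < 0) stop("compartment_padding must be >= 0")
  if (iterations < 0) stop("iterations must be >= 0")
  structure(list(iterations = as.integer(iterations),
                 ideal_edge_length = ideal_edge_length,
                 compartment_padding = compartment_padding,
                 seed = as.integer(seed)),
            class = "layout_config")
}

#' Nesting-preserving compound layout
#'
#' A two-phase compound layout: each container's children are laid out
#' bottom-up with a seeded spring embedder (Fruchterman-Reingold style) over
#' the arcs projected onto that sibling level, sibling box overlaps are then
#' removed, and the container's box is fitted around its children plus
#' `compartment_padding`. Top-level connected components are finally placed
#' side by side. The result never destroys nesting: every child box lies
#' strictly inside its parent box (by the padding margin), and top-level
#' boxes do not overlap. Deterministic under a fixed config.
#'
#' Only sibling-level overlap is resolved; arc routing and overlaps between
#' nodes of different containers are out of scope. Port coordinates are left
#' untouched (they are cosmetic).
#'
#' @param map a structurally valid `pd_map`.
#' @param config a [layout_config()].
#' @return the map with updated bounding boxes, normalized to the origin.
#' @examples
#' m <- compound_layout(fixture("fig2_like"), layout_config(seed = 7))
#' nrow(containment_check(m)) == 0
#' @export
compound_layout <- function(map, config = layout_config()) {
  stopifnot(inherits(map, "pd_map"), inherits(config, "layout_config"))
  if (!n_glyphs(map)) return(map)
  with_local_seed(config$seed, {
    g <- map$glyphs
    rownames(g) <- g$id
    pad <- max(config$compartment_padding, 1e-6)

    # representative of `id` at the sibling level directly under `container`
    rep_under <- function(id, container) {
      cur <- id
      repeat {
        par <- g[cur, "parent"]
        if (is.na(par)) {
          if (is.na(container)) return(cur) else return(NA_character_)
        }
        if (!is.na(container) && par == container) return(cur)
        cur <- par
      }
    }

    sibling_edges <- function(sibs, container) {
      if (length(sibs) < 2 || !nrow(map$arcs)) {
        return(matrix(character(0), ncol = 2))
      }
      reps <- function(ids) vapply(ids, rep_under, "", container = container)
      within <- descendants_set(container)
      a <- map$arcs[map$arcs$source %in% within & map$arcs$target %in% within,
                    , drop = FALSE]
      if (!nrow(a)) return(matrix(character(0), ncol = 2))
      s <- reps(a$source)
      t <- reps(a$target)
      keep <- !is.na(s) & !is.na(t) & s != t & s %in% sibs & t %in% sibs
      unique(cbind(pmin(s[keep], t[keep]), pmax(s[keep], t[keep])))
    }

    descendants_set <- function(container) {
      if (is.na(container)) return(g$id)
      c(container, descendants(map, container))
    }

    # sizes after recursive layout; offsets of children relative to parent
    size_w <- stats::setNames(g$w, g$id)
    size_h <- stats::setNames(g$h, g$id)
    rel_x <- stats::setNames(numeric(nrow(g)), g$id)
    rel_y <- stats::setNames(numeric(nrow(g)), g$id)

    # place `sibs` (sizes known) in local coordinates; returns n x 2 matrix
    place_siblings <- function(sibs, container) {
      k <- length(sibs)
      w <- size_w[sibs]; h <- size_h[sibs]
      if (k == 1) {
        return(matrix(0, 1, 2, dimnames = list(sibs, NULL)))
      }
      el <- config$ideal_edge_length + mean(sqrt(w * h))
      side <- el * sqrt(k)
      pos <- matrix(stats::runif(2 * k, 0, side), k, 2,
                    dimnames = list(sibs, NULL))
      edges <- sibling_edges(sibs, container)
      ei <- match(edges[, 1], sibs)
      ej <- match(edges[, 2], sibs)
      temp <- side / 10
      for (it in seq_len(config$iterations)) {
        dx <- outer(pos[, 1], pos[, 1], "-")
        dy <- outer(pos[, 2], pos[, 2], "-")
        d2 <- pmax(dx * dx + dy * dy, 1e-6)
        inv <- el^2 / d2                 # repulsion along the pair vector
        diag(inv) <- 0
        disp <- cbind(rowSums(dx * inv), rowSums(dy * inv))
        if (length(ei)) {
          ax <- (pos[ei, 1] - pos[ej, 1])
          ay <- (pos[ei, 2] - pos[ej, 2])
          dist <- pmax(sqrt(ax * ax + ay * ay), 1e-3)
          f <- dist / el                 # attraction
          for (e in seq_along(ei)) {
            disp[ei[e], ] <- disp[ei[e], ] - c(ax[e], ay[e]) * f[e]
            disp[ej[e], ] <- disp[ej[e], ] + c(ax[e], ay[e]) * f[e]
          }
        }
        lim <- temp * (1 - it / (config$iterations + 1))
        len <- pmax(sqrt(rowSums(disp^2)), 1e-9)
        scale <- pmin(len, lim) / len
        pos <- pos + disp * scale
      }
      separate_boxes(pos, w, h, pad)
    }

    # deterministic pairwise push-apart; falls back to a row if not resolved
    separate_boxes <- function(pos, w, h, gap) {
      k <- nrow(pos)
      for (sweep in seq_len(30)) {
        moved <- FALSE
        for (i in seq_len(k - 1)) {
          for (j in (i + 1):k) {
            ox <- (w[i] + w[j]) / 2 + gap - abs(pos[i, 1] - pos[j, 1])
            oy <- (h[i] + h[j]) / 2 + gap - abs(pos[i, 2] - pos[j, 2])
            if (ox > 1e-9 && oy > 1e-9) {
              moved <- TRUE
              if (ox <= oy) {
                s <- if (pos[i, 1] <= pos[j, 1]) 1 else -1
                pos[i, 1] <- pos[i, 1] - s * ox / 2
                pos[j, 1] <- pos[j, 1] + s * ox / 2
              } else {
                s <- if (pos[i, 2] <= pos[j, 2]) 1 else -1
                pos[i, 2] <- pos[i, 2] - s * oy / 2
                pos[j, 2] <- pos[j, 2] + s * oy / 2
              }
            }
          }
        }
        if (!moved) return(pos)
      }
      # fallback: guaranteed overlap-free deterministic row (center coords)
      left <- cumsum(c(0, (w + gap)[-k]))
      cbind(left + w / 2, rep(0, k))
    }

    children_map <- split(g$id[!is.na(g$parent)], g$parent[!is.na(g$parent)])

    fit <- function(id) {
      kids <- children_map[[id]]
      if (is.null(kids) || !length(kids)) return(invisible(NULL))
      kids <- sort(kids)
      for (kid in kids) fit(kid)
      pos <- place_siblings(kids, id)
      # convert centers to top-left, normalize to padding offset
      tlx <- pos[, 1] - size_w[kids] / 2
      tly <- pos[, 2] - size_h[kids] / 2
      tlx <- tlx - min(tlx) + pad
      tly <- tly - min(tly) + pad
      rel_x[kids] <<- tlx
      rel_y[kids] <<- tly
      size_w[id] <<- max(tlx + size_w[kids]) + pad
      size_h[id] <<- max(tly + size_h[kids]) + pad
      invisible(NULL)
    }

    roots <- sort(g$id[is.na(g$parent)])
    for (r in roots) fit(r)

    # top level: connected components placed on a shelf
    comp_id <- stats::setNames(seq_along(roots), roots)
    edges <- sibling_edges(roots, NA_character_)
    if (nrow(edges)) {
      repeat {
        changed <- FALSE
        for (e in seq_len(nrow(edges))) {
          a <- edges[e, 1]; b <- edges[e, 2]
          m2 <- min(comp_id[a], comp_id[b])
          if (comp_id[a] != m2 || comp_id[b] != m2) {
            comp_id[comp_id %in% c(comp_id[a], comp_id[b])] <- m2
            changed <- TRUE
          }
        }
        if (!changed) break
      }
    }
    shelf_x <- 0
    abs_x <- stats::setNames(numeric(length(roots)), roots)
    abs_y <- stats::setNames(numeric(length(roots)), roots)
    for (cid in sort(unique(comp_id))) {
      members <- roots[comp_id == cid]
      pos <- place_siblings(members, NA_character_)
      tlx <- pos[, 1] - size_w[members] / 2
      tly <- pos[, 2] - size_h[members] / 2
      tlx <- tlx - min(tlx)
      tly <- tly - min(tly)
      abs_x[members] <- shelf_x + tlx
      abs_y[members] <- tly
      shelf_x <- shelf_x + max(tlx + size_w[members]) + 2 * pad
    }

    # push absolute coordinates down the tree
    out_x <- stats::setNames(numeric(nrow(g)), g$id)
    out_y <- stats::setNames(numeric(nrow(g)), g$id)
    assign_abs <- function(id, ox, oy) {
      out_x[id] <<- ox
      out_y[id] <<- oy
      for (kid in children_map[[id]] %||% character(0)) {
        assign_abs(kid, ox + rel_x[kid], oy + rel_y[kid])
      }
    }
    for (r in roots) assign_abs(r, abs_x[r], abs_y[r])

    g$x <- out_x[g$id]
    g$y <- out_y[g$id]
    g$w <- size_w[g$id]
    g$h <- size_h[g$id]
    pd_map(g, map$arcs, map$ports, map$aux, map$map_id, map$extra)
  })
}

#' List containment violations
#'
#' Every (child, parent) pair whose bounding boxes violate containment, i.e.
#' the child box is not entirely inside the parent box (tolerance `tol`).
#' Empty after [compound_layout()].
#'
#' @param map a `pd_map`.
#' @param tol numeric tolerance in map units.
#' @return data frame with columns `child`, `parent` (zero rows when clean).
#' @export
containment_check <- function(map, tol = 1e-6) {
  g <- map$glyphs
  has_parent <- !is.na(g$parent)
  child <- g[has_parent, , drop = FALSE]
  if (!nrow(child)) {
    return(data.frame(child = character(), parent = character(),
                      stringsAsFactors = FALSE))
  }
  pi <- match(child$parent, g$id)
  bad <- child$x < g$x[pi] - tol |
    child$y < g$y[pi] - tol |
    child$x + child$w > g$x[pi] + g$w[pi] + tol |
    child$y + child$h > g$y[pi] + g$h[pi] + tol
  data.frame(child = child$id[bad], parent = child$parent[bad],
             stringsAsFactors = FALSE)
}

svg_shape <- function(cls, x, y, w, h, label) {
  esc <- xml_escape
  body <- switch(cls,
    "compartment" = sprintf(
      '<rect class="compartment" x="%s" y="%s" width="%s" height="%s" rx="15" fill="none" stroke="#808040" stroke-width="4"/>',
      fmt_num(x), fmt_num(y), fmt_num(w), fmt_num(h)),
    "complex" = {
      c <- min(w, h) / 5
      pts <- rbind(c(x + c, y), c(x + w - c, y), c(x + w, y + c),
                   c(x + w, y + h - c), c(x + w - c, y + h), c(x + c, y + h),
                   c(x, y + h - c), c(x, y + c))
      sprintf('<polygon class="complex" points="%s" fill="#e8e8ff" fill-opacity="0.5" stroke="#404080" stroke-width="2"/>',
              paste(apply(pts, 1, function(p)
                paste(fmt_num(p[1]), fmt_num(p[2]), sep = ",")),
                collapse = " "))
    },
    "simple chemical" = sprintf(
      '<ellipse class="simple-chemical" cx="%s" cy="%s" rx="%s" ry="%s" fill="#f0fff0" stroke="#208020" stroke-width="1.5"/>',
      fmt_num(x + w / 2), fmt_num(y + h / 2), fmt_num(w / 2), fmt_num(h / 2)),
    "phenotype" = {
      c <- h / 2
      pts <- rbind(c(x + c, y), c(x + w - c, y), c(x + w, y + h / 2),
                   c(x + w - c, y + h), c(x + c, y + h), c(x, y + h / 2))
      sprintf('<polygon class="phenotype" points="%s" fill="#fff0f0" stroke="#802020" stroke-width="1.5"/>',
              paste(apply(pts, 1, function(p)
                paste(fmt_num(p[1]), fmt_num(p[2]), sep = ",")),
                collapse = " "))
    },
    if (cls %in% PD_LOGIC_CLASSES) sprintf(
      '<ellipse class="logic" cx="%s" cy="%s" rx="%s" ry="%s" fill="#ffffff" stroke="#000000" stroke-width="1.5"/>',
      fmt_num(x + w / 2), fmt_num(y + h / 2), fmt_num(w / 2), fmt_num(h / 2))
    else if (is_process_class(cls)) sprintf(
      '<rect class="process" x="%s" y="%s" width="%s" height="%s" fill="#ffffff" stroke="#000000" stroke-width="1.5"/>',
      fmt_num(x), fmt_num(y), fmt_num(w), fmt_num(h))
    else sprintf(
      '<rect class="%s" x="%s" y="%s" width="%s" height="%s" rx="8" fill="#f0f4ff" stroke="#204080" stroke-width="1.5"/>',
      gsub(" ", "-", cls), fmt_num(x), fmt_num(y), fmt_num(w), fmt_num(h))
  )
  if (nzchar(label)) {
    body <- c(body, sprintf(
      '<text x="%s" y="%s" font-size="11" text-anchor="middle" font-family="sans-serif">%s</text>',
      fmt_num(x + w / 2), fmt_num(y + h / 2 + 4), esc(label)))
  }
  body
}

SVG_MARKERS <- c(
  production = "arrow-filled", catalysis = "circle-open",
  stimulation = "arrow-open", inhibition = "bar",
  modulation = "diamond-open", `necessary stimulation` = "bar-arrow",
  `logic arc` = "", consumption = "", `equivalence arc` = ""
)

#' Export a map as SVG
#'
#' Draws the map with simplified PD glyph shapes — rounded rectangles for
#' macromolecules and other EPNs, ellipses for simple chemicals, small
#' squares for processes, cut-corner octagons for complexes, thick rounded
#' rectangles for compartments — and arcs as paths between bounding-box
#' centers with class-distinct arrowheads (filled triangle for production,
#' open circle for catalysis, open triangle for stimulation, bar for
#' inhibition, diamond for modulation). Containers are drawn before their
#' children.
#'
#' @param map a `pd_map` with bounding boxes (typically after
#'   [compound_layout()]).
#' @param path output file, or `NULL` to return the SVG text.
#' @return the SVG text, invisibly when written to `path`.
#' @export
export_svg <- function(map, path = NULL) {
  g <- map$glyphs
  margin <- 10
  if (nrow(g)) {
    x0 <- min(g$x) - margin; y0 <- min(g$y) - margin
    x1 <- max(g$x + g$w) + margin; y1 <- max(g$y + g$h) + margin
  } else {
    x0 <- 0; y0 <- 0; x1 <- 100; y1 <- 100
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" viewBox="%s %s %s %s" width="%s" height="%s">',
            fmt_num(x0), fmt_num(y0), fmt_num(x1 - x0), fmt_num(y1 - y0),
            fmt_num(x1 - x0), fmt_num(y1 - y0)),
    '<defs>',
    '<marker id="arrow-filled" viewBox="0 0 10 10" refX="9" refY="5" markerWidth="8" markerHeight="8" orient="auto-start-reverse"><path d="M 0 0 L 10 5 L 0 10 z" fill="#000"/></marker>',
    '<marker id="arrow-open" viewBox="0 0 10 10" refX="9" refY="5" markerWidth="8" markerHeight="8" orient="auto-start-reverse"><path d="M 0 0 L 10 5 L 0 10 z" fill="#fff" stroke="#000"/></marker>',
    '<marker id="circle-open" viewBox="0 0 10 10" refX="9" refY="5" markerWidth="8" markerHeight="8" orient="auto"><circle cx="5" cy="5" r="4" fill="#fff" stroke="#000"/></marker>',
    '<marker id="bar" viewBox="0 0 10 10" refX="5" refY="5" markerWidth="8" markerHeight="8" orient="auto"><rect x="4" y="0" width="2" height="10" fill="#000"/></marker>',
    '<marker id="diamond-open" viewBox="0 0 10 10" refX="9" refY="5" markerWidth="9" markerHeight="9" orient="auto"><path d="M 5 0 L 10 5 L 5 10 L 0 5 z" fill="#fff" stroke="#000"/></marker>',
    '<marker id="bar-arrow" viewBox="0 0 14 10" refX="13" refY="5" markerWidth="11" markerHeight="8" orient="auto"><rect x="0" y="0" width="2" height="10" fill="#000"/><path d="M 4 0 L 14 5 L 4 10 z" fill="#fff" stroke="#000"/></marker>',
    '</defs>'
  )
  if (nrow(g)) {
    # containers before children: sort by containment depth
    idx <- match(g$parent, g$id)
    depth <- vapply(seq_len(nrow(g)), function(i) {
      d <- 0L; j <- idx[i]
      while (!is.na(j) && d <= nrow(g)) { d <- d + 1L; j <- idx[j] }
      d
    }, 0L)
    ord <- order(depth, g$id)
    for (i in ord) {
      lines <- c(lines, svg_shape(g$class[i], g$x[i], g$y[i], g$w[i], g$h[i],
                                  g$label[i]))
    }
  }
  a <- map$arcs
  if (nrow(a)) {
    a <- a[order(a$id), , drop = FALSE]
    si <- match(a$source, g$id)
    ti <- match(a$target, g$id)
    mk <- SVG_MARKERS[a$class]
    mk_attr <- ifelse(nzchar(mk) & !is.na(mk),
                      sprintf(' marker-end="url(#%s)"', mk), "")
    lines <- c(lines, sprintf(
      '<path class="%s" d="M %s %s L %s %s" fill="none" stroke="#000" stroke-width="1.2"%s/>',
      gsub(" ", "-", a$class),
      fmt_num(g$x[si] + g$w[si] / 2), fmt_num(g$y[si] + g$h[si] / 2),
      fmt_num(g$x[ti] + g$w[ti] / 2), fmt_num(g$y[ti] + g$h[ti] / 2),
      mk_attr))
  }
  lines <- c(lines, "</svg>")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- tryCatch(file(path, open = "wb"),
                    error = function(e) stop("cannot write SVG to '", path,
                                             "': ", conditionMessage(e)))
    on.exit(close(con))
    writeBin(charToRaw(text), con)
    return(invisible(text))
  }
  text
}
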