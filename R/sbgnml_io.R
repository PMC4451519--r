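#' Read an SBGN-ML process description document
#'
#' Parses SBGN-ML XML into a [pd_map()], reconstructing the compound-graph
#' structure losslessly: complex membership from XML glyph nesting,
#' compartment membership from `compartmentRef` (XML nesting inside a complex
#' takes precedence when both are present), arc endpoints resolved from port
#' ids to the owning glyph, and auxiliary glyphs (state variables, units of
#' information) attached to their owner rather than kept as map nodes.
#' Unknown XML attributes on glyph/arc elements are preserved and re-emitted
#' by [write_sbgnml()]; unknown child elements are dropped.
#'
#' Targets the 0.2-era SBGN-ML dialect; only the process description language
#' is accepted.
#'
#' @param x for `read_sbgnml` a file path; for `parse_sbgnml` an XML string
#'   (a path also works — [xml2::read_xml()] dispatches on content).
#' @return a `pd_map`.
#' @section Errors:
#' Malformed XML (reported with the line number from the XML parser), a
#' missing map element, a map language other than process description, an
#' unknown glyph class (reported with the offending id), and arc endpoints
#' referencing nonexistent glyphs or ports are all errors.
#' @export
read_sbgnml <- function(x) {
  if (!file.exists(x)) stop("file not found: ", x)
  parse_sbgnml(x)
}

#' @rdname read_sbgnml
#' @export
parse_sbgnml <- function(x) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) stop("SBGN-ML parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "sbgn") {
    stop("not an SBGN-ML document: root element is <",
         xml2::xml_name(doc), ">, expected <sbgn>")
  }
  map_node <- xml2::xml_find_first(doc, "./map")
  if (inherits(map_node, "xml_missing")) {
    stop("SBGN-ML document contains no <map> element")
  }
  lang <- xml2::xml_attr(map_node, "language")
  if (is.na(lang) || lang != "process description") {
    stop("unsupported SBGN language: ",
         if (is.na(lang)) "<missing>" else sprintf("'%s'", lang),
         " (only 'process description' maps are supported)")
  }
  map_id <- xml2::xml_attr(map_node, "id")
  if (is.na(map_id)) map_id <- "map1"

  acc <- new.env(parent = emptyenv())
  acc$glyphs <- list()
  acc$ports <- list()
  acc$aux <- list()
  acc$extra <- list()

  for (g in xml2::xml_find_all(map_node, "./glyph")) {
    parse_glyph(g, NA_character_, NA_character_, acc)
  }

  glyphs <- do.call(rbind, acc$glyphs) %||% NULL
  ports <- do.call(rbind, acc$ports) %||% NULL
  gid <- if (is.null(glyphs)) character(0) else glyphs$id
  pid <- if (is.null(ports)) character(0) else ports$id
  powner <- if (is.null(ports)) character(0) else ports$owner

  arcs <- list()
  for (a in xml2::xml_find_all(map_node, "./arc")) {
    cls <- xml2::xml_attr(a, "class")
    id <- xml2::xml_attr(a, "id")
    if (is.na(id)) id <- sprintf("arc%d", length(arcs) + 1L)
    if (is.na(cls) || !cls %in% PD_ARC_CLASSES) {
      stop("unknown arc class '", cls, "' (id ", id, ")")
    }
    sref <- xml2::xml_attr(a, "source")
    tref <- xml2::xml_attr(a, "target")
    resolve <- function(ref) {
      if (is.na(ref)) return(NA_character_)
      if (ref %in% gid) return(ref)
      hit <- match(ref, pid)
      if (!is.na(hit)) return(powner[hit])
      NA_character_
    }
    src <- resolve(sref)
    tgt <- resolve(tref)
    if (is.na(src) || is.na(tgt)) {
      stop("dangling reference: arc '", id, "' endpoint '",
           if (is.na(src)) sref else tref,
           "' matches no glyph or port in the map")
    }
    ats <- xml2::xml_attrs(a)
    unknown <- ats[setdiff(names(ats), c("class", "id", "source", "target"))]
    if (length(unknown)) acc$extra[[id]] <- unknown
    arcs[[length(arcs) + 1L]] <- data.frame(
      id = id, class = cls, source = src, target = tgt,
      source_ref = sref, target_ref = tref, stringsAsFactors = FALSE)
  }
  arcs <- do.call(rbind, arcs) %||% NULL

  pd_map(glyphs, arcs, ports, acc$aux, map_id, acc$extra)
}

bbox_of <- function(el) {
  bb <- xml2::xml_find_first(el, "./bbox")
  if (inherits(bb, "xml_missing")) return(c(0, 0, 0, 0))
  vapply(c("x", "y", "w", "h"),
         function(a) {
           v <- suppressWarnings(as.numeric(xml2::xml_attr(bb, a)))
           if (is.na(v)) 0 else v
         }, numeric(1))
}

parse_glyph <- function(el, xml_parent_id, xml_parent_class, acc) {
  cls <- canon_glyph_class(xml2::xml_attr(el, "class"))
  id <- xml2::xml_attr(el, "id")
  if (is.na(id)) stop("glyph without an id attribute")

  lab_el <- xml2::xml_find_first(el, "./label")
  label <- if (inherits(lab_el, "xml_missing")) "" else {
    l <- xml2::xml_attr(lab_el, "text")
    if (is.na(l)) "" else l
  }
  bb <- bbox_of(el)

  if (!is.na(cls) && cls %in% PD_AUX_CLASSES) {
    if (is.na(xml_parent_id)) {
      stop("auxiliary glyph '", id, "' (", cls, ") has no owner glyph")
    }
    st <- xml2::xml_find_first(el, "./state")
    if (!inherits(st, "xml_missing")) {
      val <- xml2::xml_attr(st, "value")
      var <- xml2::xml_attr(st, "variable")
      label <- paste0(if (is.na(val)) "" else val,
                      if (!is.na(var) && nzchar(var)) paste0("@", var) else "")
    }
    acc$aux[[xml_parent_id]] <- c(
      acc$aux[[xml_parent_id]],
      list(list(id = id, class = cls, label = label, bbox = as.numeric(bb))))
    return(invisible(NULL))
  }
  if (is.na(cls) || !cls %in% PD_GLYPH_CLASSES) {
    stop("unknown glyph class '", cls, "' (id ", id, ")")
  }

  cref <- xml2::xml_attr(el, "compartmentRef")
  parent <- if (!is.na(xml_parent_class) && xml_parent_class == "complex") {
    xml_parent_id
  } else if (!is.na(cref)) {
    cref
  } else if (!is.na(xml_parent_id)) {
    xml_parent_id   # tolerate structural nesting inside a compartment
  } else {
    NA_character_
  }

  ats <- xml2::xml_attrs(el)
  unknown <- ats[setdiff(names(ats), c("class", "id", "compartmentRef"))]
  if (length(unknown)) acc$extra[[id]] <- unknown

  acc$glyphs[[length(acc$glyphs) + 1L]] <- data.frame(
    id = id, class = cls, label = label, parent = parent,
    x = bb[1], y = bb[2], w = bb[3], h = bb[4], stringsAsFactors = FALSE)

  for (p in xml2::xml_find_all(el, "./port")) {
    px <- suppressWarnings(as.numeric(xml2::xml_attr(p, "x")))
    py <- suppressWarnings(as.numeric(xml2::xml_attr(p, "y")))
    acc$ports[[length(acc$ports) + 1L]] <- data.frame(
      id = xml2::xml_attr(p, "id"), owner = id,
      x = if (is.na(px)) 0 else px, y = if (is.na(py)) 0 else py,
      stringsAsFactors = FALSE)
  }
  for (child in xml2::xml_find_all(el, "./glyph")) {
    parse_glyph(child, id, cls, acc)
  }
  invisible(NULL)
}

#' Write a map as SBGN-ML
#'
#' Serializes a [pd_map()] to SBGN-ML: complex members as nested glyph
#' elements, compartment membership as `compartmentRef`, ports re-emitted
#' under their owners, bounding boxes at full IEEE precision (`%.17g`, so a
#' parse-write-parse round trip reproduces coordinates bit-exactly). Element
#' order is deterministic (compartments first, then other top-level glyphs,
#' members and arcs, each sorted by id), so equal maps serialize to identical
#' bytes.
#'
#' The map must pass [validate_structure()]; a structurally broken map is
#' refused with its validation report.
#'
#' @param map a `pd_map`.
#' @param path output file path (`.sbgn`), or `NULL` to only return the text.
#' @param validate set `FALSE` to skip the structural pre-check.
#' @return the XML text, invisibly when written to `path`.
#' @export
write_sbgnml <- function(map, path = NULL, validate = TRUE) {
  stopifnot(inherits(map, "pd_map"))
  if (validate) {
    rep <- validate_structure(map)
    if (!attr(rep, "all_pass")) {
      bad <- rep[!rep$pass, , drop = FALSE]
      stop("map fails structural validation; refusing to write:\n",
           paste(sprintf("  - %s: %s", bad$check,
                         vapply(bad$offending, paste, "", collapse = ", ")),
                 collapse = "\n"))
    }
  }
  g <- map$glyphs
  pcls <- g$class[match(g$parent, g$id)]
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<sbgn xmlns=\"http://sbgn.org/libsbgn/0.2\">",
    sprintf("  <map language=\"process description\" id=\"%s\">",
            xml_escape(map$map_id))
  )

  extra_attrs <- function(id) {
    ex <- map$extra[[id]]
    if (!length(ex)) return("")
    ex <- ex[order(names(ex))]
    paste0(" ", paste(sprintf("%s=\"%s\"", names(ex), xml_escape(ex)),
                      collapse = " "))
  }

  emit_glyph <- function(id, indent) {
    i <- match(id, g$id)
    pad <- strrep(" ", indent)
    par <- g$parent[i]
    cref <- if (!is.na(par) && g$class[match(par, g$id)] == "compartment") {
      sprintf(" compartmentRef=\"%s\"", xml_escape(par))
    } else ""
    out <- sprintf("%s<glyph class=\"%s\" id=\"%s\"%s%s>",
                   pad, g$class[i], xml_escape(id), cref, extra_attrs(id))
    if (nzchar(g$label[i])) {
      out <- c(out, sprintf("%s  <label text=\"%s\"/>",
                            pad, xml_escape(g$label[i])))
    }
    out <- c(out, sprintf("%s  <bbox x=\"%s\" y=\"%s\" w=\"%s\" h=\"%s\"/>",
                          pad, fmt_num(g$x[i]), fmt_num(g$y[i]),
                          fmt_num(g$w[i]), fmt_num(g$h[i])))
    for (ax in map$aux[[id]]) {
      out <- c(out,
        sprintf("%s  <glyph class=\"%s\" id=\"%s\">",
                pad, ax$class, xml_escape(ax$id)),
        if (nzchar(ax$label)) sprintf("%s    <label text=\"%s\"/>",
                                      pad, xml_escape(ax$label)),
        sprintf("%s    <bbox x=\"%s\" y=\"%s\" w=\"%s\" h=\"%s\"/>",
                pad, fmt_num(ax$bbox[1]), fmt_num(ax$bbox[2]),
                fmt_num(ax$bbox[3]), fmt_num(ax$bbox[4])),
        sprintf("%s  </glyph>", pad))
    }
    pt <- map$ports[map$ports$owner == id, , drop = FALSE]
    if (nrow(pt)) {
      pt <- pt[order(pt$id), , drop = FALSE]
      out <- c(out, sprintf("%s  <port id=\"%s\" x=\"%s\" y=\"%s\"/>",
                            pad, xml_escape(pt$id),
                            fmt_num(pt$x), fmt_num(pt$y)))
    }
    # complex members nest structurally
    members <- g$id[!is.na(g$parent) & g$parent == id &
                      g$class[match(g$parent, g$id)] == "complex"]
    if (g$class[i] == "complex") {
      for (m in sort(members)) out <- c(out, emit_glyph(m, indent + 2L))
    }
    c(out, sprintf("%s</glyph>", pad))
  }

  top <- g$id[is.na(g$parent) | (!is.na(pcls) & pcls == "compartment")]
  top_cls <- g$class[match(top, g$id)]
  ordered <- c(sort(top[top_cls == "compartment"]),
               sort(top[top_cls != "compartment"]))
  for (id in ordered) lines <- c(lines, emit_glyph(id, 4L))

  a <- map$arcs
  if (nrow(a)) {
    a <- a[order(a$id), , drop = FALSE]
    lines <- c(lines, sprintf(
      "    <arc class=\"%s\" id=\"%s\" source=\"%s\" target=\"%s\"%s/>",
      a$class, xml_escape(a$id), xml_escape(a$source_ref),
      xml_escape(a$target_ref),
      vapply(a$id, extra_attrs, "")))
  }
  lines <- c(lines, "  </map>", "</sbgn>")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(text), con)
    return(invisible(text))
  }
  text
}
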