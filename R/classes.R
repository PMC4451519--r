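#' SBGN-PD glyph and arc class vocabulary
#'
#' Character vectors enumerating the node (glyph) and edge (arc) classes of the
#' SBGN Process Description language that this package models, plus the derived
#' role sets the closure algorithms are written in terms of.
#'
#' * `PD_GLYPH_CLASSES`: all supported glyph classes.
#' * `PD_PROCESS_CLASSES`: the process-node subset (process, omitted process,
#'   uncertain process, association, dissociation).
#' * `PD_EPN_CLASSES`: entity pool nodes (macromolecule, simple chemical,
#'   nucleic acid feature, unspecified entity, perturbing agent,
#'   source and sink, complex).
#' * `PD_LOGIC_CLASSES`: logic operators (and, or, not).
#' * `PD_ARC_CLASSES`: all supported arc classes.
#' * `PD_EFFECTOR_ARC_CLASSES`: the modulation family (modulation, stimulation,
#'   catalysis, inhibition, necessary stimulation).
#' * `PD_AUX_CLASSES`: auxiliary decorations (state variable, unit of
#'   information) that are attached to an owner glyph and invisible to all
#'   graph algorithms.
#'
#' @name pd_classes
#' @aliases PD_GLYPH_CLASSES PD_PROCESS_CLASSES PD_EPN_CLASSES
#'   PD_LOGIC_CLASSES PD_ARC_CLASSES PD_EFFECTOR_ARC_CLASSES PD_AUX_CLASSES
NULL

#' @export
PD_PROCESS_CLASSES <- c(
  "process", "omitted process", "uncertain process",
  "association", "dissociation"
)

#' @export
PD_EPN_CLASSES <- c(
  "macromolecule", "simple chemical", "nucleic acid feature",
  "unspecified entity", "perturbing agent", "source and sink", "complex"
)

#' @export
PD_LOGIC_CLASSES <- c("and", "or", "not")

#' @export
PD_GLYPH_CLASSES <- c(
  PD_EPN_CLASSES, "compartment", PD_PROCESS_CLASSES,
  "phenotype", "tag", PD_LOGIC_CLASSES
)

#' @export
PD_EFFECTOR_ARC_CLASSES <- c(
  "modulation", "stimulation", "catalysis", "inhibition",
  "necessary stimulation"
)

#' @export
PD_ARC_CLASSES <- c(
  "consumption", "production", PD_EFFECTOR_ARC_CLASSES,
  "logic arc", "equivalence arc"
)

#' @export
PD_AUX_CLASSES <- c("state variable", "unit of information")

#' Class-role predicates
#'
#' Vectorised predicates over glyph/arc class strings. `is_process_class()` is
#' `TRUE` exactly for the five PD process-node classes; phenotype is *not* a
#' process node (it enters sub-maps only through adjacency). `is_epn_class()`
#' is `TRUE` for entity pool nodes, including complexes and source-and-sink.
#' `is_effector_class()` is `TRUE` for the modulation-family arc classes.
#'
#' @param x character vector of class strings.
#' @return logical vector of the same length.
#' @examples
#' is_process_class(c("process", "complex", "association"))
#' is_epn_class("source and sink")
#' @export
is_process_class <- function(x) x %in% PD_PROCESS_CLASSES

#' @rdname is_process_class
#' @export
is_epn_class <- function(x) x %in% PD_EPN_CLASSES

#' @rdname is_process_class
#' @export
is_logic_class <- function(x) x %in% PD_LOGIC_CLASSES

#' @rdname is_process_class
#' @export
is_effector_class <- function(x) x %in% PD_EFFECTOR_ARC_CLASSES

# Canonicalize a glyph class string: the hyphenated "source-and-sink" spelling
# is accepted and normalized to the SBGN-ML form.
canon_glyph_class <- function(x) {
  x <- ifelse(x == "source-and-sink", "source and sink", x)
  x
}
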