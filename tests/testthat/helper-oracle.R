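# Independent naive oracle for the closure algorithms. Every primitive is a
# brute-force fixpoint or row-by-row scan over the raw tables, kept separate
# from the package implementation on purpose: the optimized operators are
# compared against these, never the other way round.

oracle_descendants <- function(map, group) {
  s <- group
  repeat {
    one_level <- map$glyphs$id[!is.na(map$glyphs$parent) &
                                 map$glyphs$parent %in% s]
    bigger <- unique(c(s, one_level))
    if (length(bigger) == length(s)) break
    s <- bigger
  }
  setdiff(s, group)
}

oracle_ancestors <- function(map, group) {
  res <- character(0)
  for (id in group) {
    cur <- map$glyphs$parent[map$glyphs$id == id]
    steps <- 0L
    while (!is.na(cur) && steps <= nrow(map$glyphs)) {
      res <- c(res, cur)
      cur <- map$glyphs$parent[map$glyphs$id == cur]
      steps <- steps + 1L
    }
  }
  setdiff(unique(res), group)
}

oracle_select <- function(map, group, selector) {
  cls <- map$glyphs$class[match(group, map$glyphs$id)]
  switch(selector,
    "process" = group[cls %in% PD_PROCESS_CLASSES],
    "not-process" = group[!cls %in% PD_PROCESS_CLASSES],
    "complex" = group[cls == "complex"]
  )
}

oracle_neighborhood <- function(map, group, filter = NULL) {
  res <- character(0)
  for (k in seq_len(nrow(map$arcs))) {
    if (map$arcs$class[k] == "equivalence arc") next
    if (map$arcs$source[k] %in% group) res <- c(res, map$arcs$target[k])
    if (map$arcs$target[k] %in% group) res <- c(res, map$arcs$source[k])
  }
  res <- setdiff(unique(res), group)
  if (!is.null(filter)) res <- oracle_select(map, res, filter)
  res
}

# Straight-line evaluation of the ten-line expansion, one naive set
# comprehension per line.
oracle_expand <- function(map, group) {
  if (!length(group)) return(character(0))
  ng <- unique(group)
  ng <- union(ng, oracle_descendants(map, ng))                            # 1
  ng <- union(ng, oracle_ancestors(map, ng))                              # 2
  ng <- union(ng, oracle_descendants(map, oracle_select(map, ng,
                                                        "complex")))      # 3
  processes <- oracle_select(map, ng, "process")                          # 4
  non_processes <- oracle_select(map, ng, "not-process")                  # 5
  neighbor_processes <- oracle_neighborhood(map, non_processes,
                                            "process")                    # 6
  ng <- union(ng, oracle_neighborhood(map, processes))                    # 7
  ng <- union(ng, neighbor_processes)
  ng <- union(ng, oracle_neighborhood(map, neighbor_processes))
  ng <- union(ng, oracle_ancestors(map, ng))                              # 8
  ng <- union(ng, oracle_descendants(map, oracle_select(map, ng,
                                                        "complex")))      # 9
  sort(ng)                                                                # 10
}

# Arcs with exactly one endpoint in `shown` — the hallmark of an invalid
# generic filter.
dangling_arc_count <- function(map, shown) {
  sum(xor(map$arcs$source %in% shown, map$arcs$target %in% shown))
}
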