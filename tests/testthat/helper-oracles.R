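# Independent oracles used to cross-check the implementation.

path_key <- function(p) {
  paste(paste(p$nodes, collapse = ">"), paste(p$signs, collapse = ","),
        sep = "|")
}

# Oracle 1: igraph's own simple-path enumerator on the collapsed graph,
# with parallel signed edges re-expanded combinatorially.
oracle_paths_igraph <- function(kg, source, target, lmax, min_length = 2) {
  pair_key <- paste(kg$edges$source, kg$edges$target, sep = "\r")
  signs_by_pair <- split(kg$edges$sign, pair_key)
  simple <- unique(kg$edges[, c("source", "target")])
  if (nrow(simple) == 0) return(character(0))
  g <- igraph::graph_from_data_frame(simple, directed = TRUE,
                                     vertices = kg$nodes)
  vps <- igraph::all_simple_paths(g, from = source, to = target, mode = "out")
  keys <- character(0)
  for (vp in vps) {
    nodes <- names(vp)
    len <- length(nodes) - 1
    if (len < min_length || len > lmax) next
    sign_opts <- lapply(seq_len(len), function(i)
      signs_by_pair[[paste(nodes[i], nodes[i + 1], sep = "\r")]])
    combos <- expand.grid(sign_opts, KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(combos))) {
      keys <- c(keys, paste(paste(nodes, collapse = ">"),
                            paste(unlist(combos[r, ]), collapse = ","),
                            sep = "|"))
    }
  }
  sort(keys)
}

# Oracle 2: brute-force generation of every node tuple (only viable for tiny
# graphs): enumerate all ordered selections of interior nodes, keep those
# where every consecutive edge exists, and expand parallel signs.
oracle_paths_exhaustive <- function(kg, source, target, lmax, min_length = 2) {
  pair_key <- paste(kg$edges$source, kg$edges$target, sep = "\r")
  signs_by_pair <- split(kg$edges$sign, pair_key)
  nodes_all <- kg$nodes$id
  keys <- character(0)
  for (len in min_length:lmax) {
    k <- len - 1  # interior slots
    grid <- expand.grid(rep(list(nodes_all), k), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
      interior <- unlist(grid[r, ], use.names = FALSE)
      seqn <- c(source, interior, target)
      if (anyDuplicated(seqn)) next
      pk <- paste(seqn[-length(seqn)], seqn[-1], sep = "\r")
      opts <- signs_by_pair[pk]
      if (any(vapply(opts, is.null, logical(1)))) next
      combos <- expand.grid(opts, KEEP.OUT.ATTRS = FALSE)
      for (cc in seq_len(nrow(combos))) {
        keys <- c(keys, paste(paste(seqn, collapse = ">"),
                              paste(unlist(combos[cc, ]), collapse = ","),
                              sep = "|"))
      }
    }
  }
  sort(keys)
}

# Brute-force error counter: one explicit if-chain per scored protein.
# `values` uses NA for "unmeasured". orientation +1 = concordance,
# -1 = anti-correlation.
oracle_count_errors <- function(inferred, values, orientation,
                                treat_zero_as_error = TRUE) {
  errs <- 0
  for (i in seq_along(inferred)) {
    v <- values[i]
    expected <- orientation * inferred[i]
    if (is.na(v)) {
      errs <- errs + 1
    } else if (v == 0) {
      if (treat_zero_as_error) errs <- errs + 1
    } else if (v != expected) {
      errs <- errs + 1
    }
  }
  errs
}
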