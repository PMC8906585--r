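## Bounded node-simple path enumeration and sign propagation.

#' Construct a causal path
#'
#' A node-simple directed path through the knowledge graph together with the
#' regulation signs it implies. The first node is the perturbation source
#' (a chemical in drug mode, the hypothesised upstream regulator protein in
#' target mode) and the last node is the disease. Every *interior* node
#' receives an inferred regulation equal to the product of the edge signs
#' from the path start up to that node; the `cumulative_effect` is the
#' product of all edge signs, i.e. the path's net predicted effect on its
#' endpoint.
#'
#' @param nodes character vector of node ids along the path (length >= 3).
#' @param signs integer vector of edge signs in `{-1, 1}`,
#'   `length(nodes) - 1` long.
#' @return An object of class `causal_path` with components `nodes`, `signs`,
#'   `inferred` (named signs of the interior nodes) and `cumulative_effect`.
#' @examples
#' p <- causal_path(c("c:1", "g:1", "g:2", "m:1"), c(-1, 1, -1))
#' p$inferred           # g:1 -> -1, g:2 -> -1
#' p$cumulative_effect  # +1
#' @export
causal_path <- function(nodes, signs) {
  nodes <- as.character(nodes)
  signs <- as.integer(signs)
  if (length(nodes) < 3L || length(signs) != length(nodes) - 1L)
    stop("a causal path needs >= 2 edges and one sign per edge")
  if (!all(signs %in% c(-1L, 1L))) stop("edge signs must be +1 or -1")
  if (anyDuplicated(nodes)) stop("path is not node-simple")
  cum <- cumprod(signs)
  interior <- nodes[seq(2L, length(nodes) - 1L)]
  structure(list(nodes = nodes,
                 signs = signs,
                 inferred = stats::setNames(as.integer(cum[seq_along(interior)]),
                                            interior),
                 cumulative_effect = as.integer(cum[length(cum)])),
            class = "causal_path")
}

#' @export
print.causal_path <- function(x, ...) {
  arrows <- ifelse(x$signs == 1L, "-(+)->", "-(-)->")
  cat(paste0(paste(rbind(x$nodes[-length(x$nodes)], arrows), collapse = " "),
             " ", x$nodes[length(x$nodes)], "\n"))
  cat(sprintf("cumulative effect: %+d\n", x$cumulative_effect))
  invisible(x)
}

#' Inferred regulation signs along a path
#'
#' Propagates edge signs from the path start: the i-th node past the source
#' is predicted up- (+1) or down- (-1) regulated according to the product of
#' the first i edge signs.
#'
#' @param path a [causal_path()].
#' @return Named integer vector of `{-1, +1}` signs for the interior nodes.
#' @export
infer_regulation <- function(path) {
  stopifnot(inherits(path, "causal_path"))
  path$inferred
}

## Adjacency cache: maps node id -> data.frame(target, sign), children sorted
## lexicographically by (target, sign) so enumeration order is deterministic.
build_adjacency <- function(kg, reverse = FALSE) {
  e <- kg$edges
  from <- if (reverse) e$target else e$source
  to <- if (reverse) e$source else e$target
  o <- order(from, to, e$sign, method = "radix")
  from <- from[o]; to <- to[o]; sgn <- e$sign[o]
  split(data.frame(target = to, sign = sgn, stringsAsFactors = FALSE), from)
}

#' Enumerate bounded acyclic causal paths between two nodes
#'
#' Depth-first enumeration of every node-simple directed path from `source`
#' to `target` with between `min_length` and `lmax` edges. Cyclic paths are
#' excluded by construction (no node may repeat); paths longer than `lmax`
#' edges are never materialised (the bound is applied during descent), under
#' the assumption that effects transmitted over longer chains are less
#' biologically relevant. Parallel edges with opposite signs yield distinct
#' paths. Results are ordered lexicographically by node sequence, then by
#' edge-sign sequence.
#'
#' @param kg a [causal_kg()].
#' @param source source node id (a chemical in drug mode).
#' @param target target node id (a disease).
#' @param lmax maximum path length in edges (default 7).
#' @param min_length minimum path length in edges (default 2: the shortest
#'   mechanistic path is chemical -> protein -> disease).
#' @return List of [causal_path()] objects (possibly empty).
#' @export
enumerate_causal_paths <- function(kg, source, target, lmax = 7L,
                                   min_length = 2L) {
  stopifnot(inherits(kg, "causal_kg"))
  if (!source %in% kg$nodes$id) stop("source node not in KG: ", source)
  if (!target %in% kg$nodes$id) stop("target node not in KG: ", target)
  if (lmax < 2L) stop("lmax must be >= 2")
  adj <- build_adjacency(kg)
  out <- dfs_paths(adj, source, target, lmax, min_length)
  lapply(out, function(p) causal_path(p$nodes, p$signs))
}

## Iterative-free recursive DFS; graphs here are sparse and lmax small.
dfs_paths <- function(adj, source, target, lmax, min_length) {
  acc <- list()
  n_acc <- 0L
  push <- function(nodes, signs) {
    n_acc <<- n_acc + 1L
    acc[[n_acc]] <<- list(nodes = nodes, signs = signs)
  }
  visit <- function(node, nodes, signs) {
    depth <- length(signs)
    if (node == target) {
      if (depth >= min_length) push(nodes, signs)
      return(invisible(NULL))  # target (a disease) terminates the path
    }
    if (depth == lmax) return(invisible(NULL))
    children <- adj[[node]]
    if (is.null(children)) return(invisible(NULL))
    for (i in seq_len(nrow(children))) {
      nxt <- children$target[[i]]
      if (nxt %in% nodes) next
      visit(nxt, c(nodes, nxt), c(signs, children$sign[[i]]))
    }
    invisible(NULL)
  }
  visit(source, source, integer(0))
  if (n_acc == 0L) return(list())
  acc[seq_len(n_acc)]
}

## All node-simple paths of length [min_length, lmax] ENDING at `target`,
## discovered by walking in-edges backwards from the disease. Returns raw
## node/sign lists oriented forwards (start -> ... -> target). Used by
## target prioritization, where every upstream protein is a candidate start.
enumerate_paths_into <- function(kg, target, lmax, min_length = 2L,
                                 start_kind = "protein") {
  stopifnot(inherits(kg, "causal_kg"))
  if (!target %in% kg$nodes$id) stop("target node not in KG: ", target)
  radj <- build_adjacency(kg, reverse = TRUE)
  kind_of <- node_kinds(kg)
  acc <- list()
  visit <- function(node, nodes, signs) {
    ## nodes/signs are stored reversed (target first)
    depth <- length(signs)
    if (depth >= min_length && kind_of[[node]] %in% start_kind)
      acc[[length(acc) + 1L]] <<- list(nodes = rev(nodes), signs = rev(signs))
    if (depth == lmax) return(invisible(NULL))
    parents <- radj[[node]]
    if (is.null(parents)) return(invisible(NULL))
    for (i in seq_len(nrow(parents))) {
      prv <- parents$target[[i]]
      if (prv %in% nodes) next
      visit(prv, c(nodes, prv), c(signs, parents$sign[[i]]))
    }
    invisible(NULL)
  }
  visit(target, target, integer(0))
  lapply(acc, function(p) causal_path(p$nodes, p$signs))
}
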