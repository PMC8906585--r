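## Typed, signed causal knowledge graph: data model and I/O.

NODE_KINDS <- c("chemical", "protein", "disease")

## Only these (source-kind, target-kind) strata may carry causal edges:
## a chemical perturbs a protein target, proteins signal to proteins, and
## proteins modify a disease phenotype.
ALLOWED_STRATA <- data.frame(
  source_kind = c("chemical", "protein", "protein"),
  target_kind = c("protein", "protein", "disease"),
  stringsAsFactors = FALSE
)

#' Construct a causal knowledge graph
#'
#' A `causal_kg` is a directed multigraph over three node kinds (`chemical`,
#' `protein`, `disease`) whose edges assert activation (`+1`) or inhibition
#' (`-1`). Only chemical->protein, protein->protein and protein->disease
#' edges are admitted; self-edges are rejected, and duplicate
#' (source, target, sign) rows are collapsed. Parallel edges with opposite
#' signs between the same node pair are retained as two distinct edges:
#' aggregated knowledge graphs carry conflicting assertions from different
#' sources, and collapsing them would silently discard mechanism hypotheses.
#'
#' @param nodes data.frame with columns `id` (unique, non-empty character)
#'   and `kind` (one of `"chemical"`, `"protein"`, `"disease"`).
#' @param edges data.frame with columns `source`, `target` (node ids) and
#'   `sign` (`+1` activation, `-1` inhibition); an optional `provenance`
#'   column is carried along.
#' @return An object of class `causal_kg` with components `nodes` and
#'   `edges` (both data.frames, edges sorted deterministically).
#' @examples
#' kg <- causal_kg(
#'   nodes = data.frame(id = c("c:1", "g:1", "m:1"),
#'                      kind = c("chemical", "protein", "disease")),
#'   edges = data.frame(source = c("c:1", "g:1"), target = c("g:1", "m:1"),
#'                      sign = c(-1, 1))
#' )
#' kg
#' @seealso [load_kg()], [write_kg()], [kg_stats()]
#' @export
causal_kg <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "kind") %in% names(nodes)))
  if (nrow(edges) == 0L) {
    edges <- data.frame(source = character(0), target = character(0),
                        sign = integer(0), provenance = character(0),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source", "target", "sign") %in% names(edges)))
  nodes$id <- as.character(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.integer(edges$sign)
  if (!"provenance" %in% names(edges)) edges$provenance <- NA_character_

  ## de-duplicate identical (source, target, sign) assertions
  key <- paste(edges$source, edges$target, edges$sign, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]

  kg <- structure(list(nodes = nodes, edges = edges), class = "causal_kg")
  validate_causal_kg(kg)
  ## deterministic ordering
  kg$nodes <- kg$nodes[order(kg$nodes$id, method = "radix"), , drop = FALSE]
  kg$edges <- kg$edges[order(kg$edges$source, kg$edges$target, kg$edges$sign,
                             method = "radix"), , drop = FALSE]
  rownames(kg$nodes) <- NULL
  rownames(kg$edges) <- NULL
  kg
}

validate_causal_kg <- function(kg) {
  nodes <- kg$nodes
  edges <- kg$edges
  if (anyNA(nodes$id) || any(!nzchar(nodes$id)))
    stop("node ids must be non-empty strings")
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  bad_kind <- setdiff(unique(nodes$kind), NODE_KINDS)
  if (length(bad_kind))
    stop("unknown node kind(s): ", paste(bad_kind, collapse = ", "))
  if (nrow(edges)) {
    if (!all(edges$sign %in% c(-1L, 1L)))
      stop("edge signs must be +1 or -1")
    missing <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(missing))
      stop("edge endpoints absent from node table: ",
           paste(missing, collapse = ", "))
    if (any(edges$source == edges$target))
      stop("self-edges are not allowed (they only create cycles, which path ",
           "reasoning excludes)")
    kind_of <- stats::setNames(nodes$kind, nodes$id)
    sk <- kind_of[edges$source]
    tk <- kind_of[edges$target]
    ok <- paste(sk, tk) %in% paste(ALLOWED_STRATA$source_kind,
                                   ALLOWED_STRATA$target_kind)
    if (!all(ok)) {
      i <- which(!ok)[1L]
      stop(sprintf("edge %s -> %s has disallowed kind pair (%s -> %s)",
                   edges$source[i], edges$target[i], sk[i], tk[i]))
    }
  }
  invisible(kg)
}

node_kinds <- function(kg) stats::setNames(kg$nodes$kind, kg$nodes$id)

nodes_of_kind <- function(kg, kind) kg$nodes$id[kg$nodes$kind == kind]

#' @export
print.causal_kg <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind, levels = NODE_KINDS))
  cat(sprintf(
    "causal_kg: %d nodes (%d chemical, %d protein, %d disease), %d signed edges (%d inhibitory)\n",
    nrow(x$nodes), kinds[["chemical"]], kinds[["protein"]], kinds[["disease"]],
    nrow(x$edges), sum(x$edges$sign == -1L)))
  invisible(x)
}

#' Load a causal knowledge graph from disk
#'
#' Reads either the package's native tab-separated edge list (columns
#' `source_id`, `source_kind`, `relation`, `target_id`, `target_kind`, with
#' `relation` one of `activates`/`inhibits`, `#` comment lines allowed) or a
#' GraphML file with node attribute `kind` and edge attribute `sign`.
#'
#' In `strict` mode (default) any malformed row aborts the load with its line
#' number; in `lenient` mode offending rows are skipped and reported in the
#' `"rejected"` attribute of the result. Duplicate (source, target, sign)
#' rows are collapsed either way.
#'
#' @param path file to read.
#' @param dialect `"tsv"` (native edge list) or `"graphml"`.
#' @param mode `"strict"` or `"lenient"`.
#' @param quiet suppress the load summary message.
#' @return A [causal_kg()]; in lenient mode with a data.frame of rejected
#'   rows (line, reason) attached as attribute `"rejected"`.
#' @export
load_kg <- function(path, dialect = c("tsv", "graphml"),
                    mode = c("strict", "lenient"), quiet = FALSE) {
  dialect <- match.arg(dialect)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path)

  if (dialect == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    kg <- igraph_to_kg(g)
    if (!quiet) message(kg_summary_line(kg))
    return(kg)
  }

  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  raw <- raw[keep]
  if (!length(raw)) stop("file has no header: ", path)
  header <- strsplit(raw[1L], "\t", fixed = TRUE)[[1L]]
  expected <- c("source_id", "source_kind", "relation", "target_id", "target_kind")
  if (!identical(trimws(header), expected))
    stop("bad header in ", path, "; expected: ", paste(expected, collapse = "\t"))
  body <- raw[-1L]
  lineno <- lineno[-1L]

  rejected <- data.frame(line = integer(0), reason = character(0),
                         stringsAsFactors = FALSE)
  src <- tgt <- sk <- tk <- character(length(body))
  sgn <- integer(length(body))
  ok <- logical(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    reason <- NULL
    if (length(f) != 5L) {
      reason <- sprintf("expected 5 fields, got %d", length(f))
    } else {
      f <- trimws(f)
      if (!f[3L] %in% c("activates", "inhibits"))
        reason <- paste0("unknown relation token '", f[3L], "'")
      else if (!f[2L] %in% NODE_KINDS)
        reason <- paste0("unknown node kind '", f[2L], "'")
      else if (!f[5L] %in% NODE_KINDS)
        reason <- paste0("unknown node kind '", f[5L], "'")
      else if (!paste(f[2L], f[5L]) %in%
               paste(ALLOWED_STRATA$source_kind, ALLOWED_STRATA$target_kind))
        reason <- sprintf("edge between disallowed kinds (%s -> %s)", f[2L], f[5L])
      else if (f[1L] == f[4L])
        reason <- "self-edge"
      else if (!nzchar(f[1L]) || !nzchar(f[4L]))
        reason <- "empty node id"
    }
    if (is.null(reason)) {
      src[i] <- f[1L]; sk[i] <- f[2L]; tgt[i] <- f[4L]; tk[i] <- f[5L]
      sgn[i] <- if (f[3L] == "activates") 1L else -1L
      ok[i] <- TRUE
    } else {
      if (mode == "strict")
        stop(sprintf("%s line %d: %s", path, lineno[i], reason))
      rejected <- rbind(rejected,
                        data.frame(line = lineno[i], reason = reason,
                                   stringsAsFactors = FALSE))
    }
  }
  src <- src[ok]; tgt <- tgt[ok]; sk <- sk[ok]; tk <- tk[ok]; sgn <- sgn[ok]

  ids <- c(src, tgt)
  kinds <- c(sk, tk)
  ## a node mentioned with two different kinds is a validation error
  kd <- !duplicated(ids)
  node_tab <- data.frame(id = ids[kd], kind = kinds[kd], stringsAsFactors = FALSE)
  conflict <- tapply(kinds, ids, function(k) length(unique(k)) > 1L)
  if (any(conflict))
    stop("node(s) declared with conflicting kinds: ",
         paste(names(conflict)[conflict], collapse = ", "))

  kg <- causal_kg(nodes = node_tab,
                  edges = data.frame(source = src, target = tgt, sign = sgn,
                                     stringsAsFactors = FALSE))
  if (mode == "lenient") attr(kg, "rejected") <- rejected
  if (!quiet) message(kg_summary_line(kg))
  kg
}

kg_summary_line <- function(kg) {
  kinds <- table(factor(kg$nodes$kind, levels = NODE_KINDS))
  sprintf("loaded KG: %d chemicals, %d proteins, %d diseases; %d edges (%d activating, %d inhibiting)",
          kinds[["chemical"]], kinds[["protein"]], kinds[["disease"]],
          nrow(kg$edges), sum(kg$edges$sign == 1L), sum(kg$edges$sign == -1L))
}

#' Write a causal knowledge graph to disk
#'
#' Inverse of [load_kg()]: `load_kg(write_kg(kg, path))` reproduces the same
#' node and signed-edge sets, including parallel contradictory edges.
#'
#' @param kg a [causal_kg()].
#' @param path output file.
#' @param dialect `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_kg <- function(kg, path, dialect = c("tsv", "graphml")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(kg, "causal_kg"))
  if (dialect == "graphml") {
    igraph::write_graph(kg_to_igraph(kg), path, format = "graphml")
    return(invisible(path))
  }
  kind_of <- node_kinds(kg)
  lines <- c(
    paste(c("source_id", "source_kind", "relation", "target_id", "target_kind"),
          collapse = "\t"),
    if (nrow(kg$edges))
      paste(kg$edges$source, kind_of[kg$edges$source],
            ifelse(kg$edges$sign == 1L, "activates", "inhibits"),
            kg$edges$target, kind_of[kg$edges$target], sep = "\t")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

## igraph bridge: multigraph with vertex attr `kind`, edge attr `sign`.
kg_to_igraph <- function(kg) {
  g <- igraph::graph_from_data_frame(
    kg$edges[, c("source", "target", "sign"), drop = FALSE],
    directed = TRUE, vertices = kg$nodes)
  g
}

igraph_to_kg <- function(g) {
  nodes <- data.frame(id = igraph::vertex_attr(g, "name"),
                      kind = igraph::vertex_attr(g, "kind"),
                      stringsAsFactors = FALSE)
  el <- igraph::as_data_frame(g, what = "edges")
  causal_kg(nodes = nodes,
            edges = data.frame(source = el$from, target = el$to,
                               sign = as.integer(el$sign),
                               stringsAsFactors = FALSE))
}

#' Descriptive statistics of a causal knowledge graph
#'
#' Counts nodes per kind, edges per (source-kind, target-kind, sign) stratum,
#' and per-node in/out degrees -- the descriptive breakdown usually reported
#' alongside a knowledge graph.
#'
#' @param kg a [causal_kg()].
#' @return A list of class `kg_stats` with components `nodes_per_kind`
#'   (named integer), `edge_strata` (data.frame `source_kind`, `target_kind`,
#'   `sign`, `n`), and `degrees` (data.frame `id`, `kind`, `in_degree`,
#'   `out_degree`).
#' @export
kg_stats <- function(kg) {
  stopifnot(inherits(kg, "causal_kg"))
  nodes_per_kind <- stats::setNames(
    as.integer(table(factor(kg$nodes$kind, levels = NODE_KINDS))), NODE_KINDS)
  kind_of <- node_kinds(kg)
  if (nrow(kg$edges)) {
    strata <- stats::aggregate(
      list(n = rep(1L, nrow(kg$edges))),
      by = list(source_kind = kind_of[kg$edges$source],
                target_kind = kind_of[kg$edges$target],
                sign = kg$edges$sign),
      FUN = sum)
    strata <- strata[order(strata$source_kind, strata$target_kind, strata$sign,
                           method = "radix"), , drop = FALSE]
    rownames(strata) <- NULL
  } else {
    strata <- data.frame(source_kind = character(0), target_kind = character(0),
                         sign = integer(0), n = integer(0))
  }
  degrees <- data.frame(
    id = kg$nodes$id,
    kind = kg$nodes$kind,
    in_degree = as.integer(table(factor(kg$edges$target, levels = kg$nodes$id))),
    out_degree = as.integer(table(factor(kg$edges$source, levels = kg$nodes$id))),
    stringsAsFactors = FALSE)
  structure(list(nodes_per_kind = nodes_per_kind,
                 edge_strata = strata,
                 degrees = degrees,
                 n_nodes = nrow(kg$nodes),
                 n_edges = nrow(kg$edges)),
            class = "kg_stats")
}

#' @export
print.kg_stats <- function(x, ...) {
  cat("Nodes per kind:\n")
  print(x$nodes_per_kind)
  cat("Edges per stratum:\n")
  print(x$edge_strata)
  invisible(x)
}
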