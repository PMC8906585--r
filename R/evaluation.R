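## Precision-based validation, chance baseline, proximity baselines.

#' Construct a positive-label set
#'
#' Drug-disease pairs with external support (in practice: pairs that have
#' been clinically investigated), used as positive labels when evaluating a
#' prioritization run. Duplicates are dropped; pairs are plain CURIE strings
#' assumed pre-harmonized to the KG's namespaces.
#'
#' @param drug_id,disease_id equal-length character vectors.
#' @param provenance free-text origin of the labels.
#' @return A data.frame of class `label_set` with columns `drug_id`,
#'   `disease_id`.
#' @export
label_set <- function(drug_id, disease_id, provenance = NA_character_) {
  drug_id <- as.character(drug_id)
  disease_id <- as.character(disease_id)
  stopifnot(length(drug_id) == length(disease_id))
  df <- data.frame(drug_id = drug_id, disease_id = disease_id,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$drug_id, df$disease_id, sep = "\r")), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(df, provenance = provenance, class = c("label_set", "data.frame"))
}

#' Load a positive-label TSV (columns `drug_id`, `disease_id`)
#'
#' @param path TSV file.
#' @return A [label_set()].
#' @export
load_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_id", "disease_id") %in% names(tab)))
  label_set(tab$drug_id, tab$disease_id, provenance = path)
}

pair_keys <- function(pairs) {
  if (inherits(pairs, "prioritization_ranking"))
    pairs <- pairs$table[pairs$table$prioritized, , drop = FALSE]
  if (is.data.frame(pairs))
    return(unique(paste(pairs$drug_id, pairs$disease_id, sep = "\r")))
  stop("expected a data.frame of pairs or a prioritization_ranking")
}

#' Precision of a prioritized set against positive labels
#'
#' The fraction of prioritized drug-disease pairs that are positive labels,
#' TP / (TP + FP). In the early-retrieval regime only the small prioritized
#' set matters, which is why precision rather than a full-ranking metric
#' (e.g. ROC) is the appropriate score. Invariant to ordering and
#' duplicates. An empty prioritized set yields `NA` (undefined), not 0.
#'
#' @param prioritized data.frame with `drug_id`/`disease_id` columns, or a
#'   `prioritization_ranking` (its prioritized pairs are used).
#' @param labels a [label_set()] or data.frame of positive pairs.
#' @return A single number in `[0, 1]`, or `NA_real_` for an empty set.
#' @export
precision <- function(prioritized, labels) {
  keys <- pair_keys(prioritized)
  if (!length(keys)) return(NA_real_)
  pos <- pair_keys(labels)
  sum(keys %in% pos) / length(keys)
}

#' Precision expected by chance
#'
#' The probability of drawing a positive label uniformly at random from the
#' candidate pairs, where a candidate is any drug-disease combination
#' connected by at least one causal path. This is the baseline a
#' prioritization method must beat.
#'
#' @param candidates data.frame of candidate pairs (`drug_id`,
#'   `disease_id`), or a `prioritization_ranking` -- in that case every
#'   evaluated pair with `n_paths >= 1` is a candidate.
#' @param labels a [label_set()] or data.frame of positive pairs.
#' @return A single number in `[0, 1]`.
#' @export
expected_precision_by_chance <- function(candidates, labels) {
  if (inherits(candidates, "prioritization_ranking"))
    candidates <- candidates$table[candidates$table$n_paths >= 1L, , drop = FALSE]
  keys <- pair_keys(candidates)
  if (!length(keys)) stop("candidate set is empty")
  pos <- pair_keys(labels)
  sum(keys %in% pos) / length(keys)
}

#' Network-proximity baseline scores for a drug-disease pair
#'
#' Two generic topology-only scores of the kind used by proximity-based
#' repurposing methods, provided as comparison plumbing (they ignore edge
#' signs and transcriptomics entirely): the directed shortest-path length
#' from drug to disease (`Inf` when disconnected), and the number of shared
#' interactors -- proteins targeted by the drug that also carry an edge to
#' the disease.
#'
#' @param kg a [causal_kg()].
#' @param drug_id chemical node id.
#' @param disease_id disease node id.
#' @return List with `shortest_path_length` and `n_shared_interactors`.
#' @export
proximity_baselines <- function(kg, drug_id, disease_id) {
  if (!drug_id %in% kg$nodes$id) stop("node not in KG: ", drug_id)
  if (!disease_id %in% kg$nodes$id) stop("node not in KG: ", disease_id)
  g <- kg_to_igraph(kg)
  d <- igraph::distances(g, v = drug_id, to = disease_id, mode = "out")[1, 1]
  drug_targets <- unique(kg$edges$target[kg$edges$source == drug_id])
  disease_modifiers <- unique(kg$edges$source[kg$edges$target == disease_id])
  list(shortest_path_length = d,
       n_shared_interactors = length(intersect(drug_targets, disease_modifiers)))
}
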