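## Concordance scoring and drug/target prioritization.

#' Reasoning configuration
#'
#' Tunable parameters of the path-reasoning core.
#'
#' * `lmax` -- maximum path length in edges (default 7). Paths longer than
#'   this are assumed biologically diffuse and are never enumerated.
#' * `max_errors` -- error budget applied *per check* (default 1): within the
#'   drug-concordance check and, separately, within the disease
#'   anti-correlation check, at most this many proteins on a path may be
#'   unmeasured, unchanged, or contradict the inferred regulation. One error
#'   absorbs the sparse coverage of transcriptomic panels, the arbitrariness
#'   of the fold-change cutoff, and causal edges that act post-transcriptionally.
#' * `require_disease_inhibition` -- when `TRUE` (default) a path must have a
#'   net inhibitory effect on the disease (cumulative edge-sign product
#'   `-1`): a therapeutic mechanism should revert, not promote, the disease
#'   condition. Exposed as a flag for sensitivity analysis.
#' * `treat_zero_as_error` -- when `TRUE` (default) a measured-but-unchanged
#'   gene (call `0`) counts as an error, like an unmeasured one: it supplies
#'   no supporting direction for the path.
#'
#' @param lmax integer >= 2.
#' @param max_errors integer >= 0.
#' @param require_disease_inhibition logical.
#' @param treat_zero_as_error logical.
#' @return A list of class `reasoning_config`.
#' @export
reasoning_config <- function(lmax = 7L, max_errors = 1L,
                             require_disease_inhibition = TRUE,
                             treat_zero_as_error = TRUE) {
  lmax <- as.integer(lmax)
  max_errors <- as.integer(max_errors)
  if (is.na(lmax) || lmax < 2L) stop("lmax must be an integer >= 2")
  if (is.na(max_errors) || max_errors < 0L) stop("max_errors must be >= 0")
  structure(list(lmax = lmax, max_errors = max_errors,
                 require_disease_inhibition = isTRUE(require_disease_inhibition),
                 treat_zero_as_error = isTRUE(treat_zero_as_error)),
            class = "reasoning_config")
}

## Count path errors against a signature. `orientation` +1 compares the
## signature call to the inferred regulation directly (drug concordance,
## target mode), -1 to its negation (disease anti-correlation). An error is
## an interior protein that is unmeasured, measured-but-unchanged (when
## treat_zero_as_error), or whose call contradicts orientation * inferred.
count_path_errors <- function(path, sig, orientation, config) {
  inferred <- path$inferred
  vals <- sig$values[names(inferred)]        # NA for unmeasured genes
  expected <- orientation * inferred
  errs <- is.na(vals) |
    (vals == 0L & config$treat_zero_as_error) |
    (!is.na(vals) & vals != 0L & vals != expected)
  ## a 0 with treat_zero_as_error = FALSE is a silent pass
  sum(errs, na.rm = TRUE) + sum(is.na(errs))
}

#' Is a path concordant with a drug-perturbation signature?
#'
#' Walks the interior proteins of a path and counts errors: a protein whose
#' gene is unmeasured, measured but unchanged (configurable), or whose
#' binarized call disagrees with the regulation sign inferred from the edge
#' signs. The path is concordant when the error count stays within
#' `config$max_errors`.
#'
#' @param path a [causal_path()].
#' @param drug_sig a [causal_signature()] from a perturbation experiment with
#'   the path's source chemical.
#' @param config a [reasoning_config()].
#' @return List with `ok` (logical) and `errors` (integer count).
#' @export
is_concordant <- function(path, drug_sig, config = reasoning_config()) {
  stopifnot(inherits(path, "causal_path"), inherits(drug_sig, "causal_signature"))
  errors <- count_path_errors(path, drug_sig, orientation = +1L, config = config)
  list(ok = errors <= config$max_errors, errors = as.integer(errors))
}

#' Is a path anti-correlated with a disease signature?
#'
#' Identical error accounting to [is_concordant()], except that a match
#' requires the disease signature call to equal the *negated* inferred
#' regulation: a therapeutic path should oppose the dysregulation observed
#' in the disease state.
#'
#' @inheritParams is_concordant
#' @param disease_sig a [causal_signature()] for the path's target disease.
#' @return List with `ok` (logical) and `errors` (integer count).
#' @export
is_anti_correlated <- function(path, disease_sig, config = reasoning_config()) {
  stopifnot(inherits(path, "causal_path"),
            inherits(disease_sig, "causal_signature"))
  errors <- count_path_errors(path, disease_sig, orientation = -1L,
                              config = config)
  list(ok = errors <= config$max_errors, errors = as.integer(errors))
}

#' Should a drug be prioritized for a disease?
#'
#' The core decision function. Step 1 enumerates all acyclic paths of at
#' most `config$lmax` edges from the drug to the disease (optionally keeping
#' only paths whose cumulative effect inhibits the disease). Step 2 keeps
#' paths concordant with the drug-perturbation signature within the error
#' budget. Step 3 keeps, among those, paths anti-correlated with the disease
#' signature. The drug is prioritized when at least one path survives all
#' three steps; the surviving paths are returned as the proposed mechanism
#' of action.
#'
#' @param kg a [causal_kg()].
#' @param drug_id chemical node id.
#' @param disease_id disease node id.
#' @param drug_sig drug-perturbation [causal_signature()] (`context "drug"`,
#'   `context_id` matching `drug_id` when set).
#' @param disease_sig disease [causal_signature()].
#' @param config a [reasoning_config()].
#' @return A list of class `prioritization_result`: `source_id`, `target_id`,
#'   `prioritized`, counts `n_paths_total` (all enumerated),
#'   `n_inhibiting` (after the cumulative-effect filter), `n_concordant`,
#'   `n_surviving`, and `surviving_paths` (list of `causal_path` with
#'   attached `drug_errors`/`disease_errors`).
#' @export
is_drug_prioritized <- function(kg, drug_id, disease_id, drug_sig, disease_sig,
                                config = reasoning_config()) {
  kind_of <- node_kinds(kg)
  if (!drug_id %in% names(kind_of) || kind_of[[drug_id]] != "chemical")
    stop("drug_id must be a chemical node of the KG: ", drug_id)
  if (!disease_id %in% names(kind_of) || kind_of[[disease_id]] != "disease")
    stop("disease_id must be a disease node of the KG: ", disease_id)
  check_context(drug_sig, "drug", drug_id)
  check_context(disease_sig, "disease", disease_id)

  paths <- enumerate_causal_paths(kg, drug_id, disease_id, lmax = config$lmax)
  n_total <- length(paths)
  if (config$require_disease_inhibition)
    paths <- Filter(function(p) p$cumulative_effect == -1L, paths)
  n_inhib <- length(paths)

  concordant <- list()
  for (p in paths) {
    v <- is_concordant(p, drug_sig, config)
    if (v$ok) {
      attr(p, "drug_errors") <- v$errors
      concordant[[length(concordant) + 1L]] <- p
    }
  }
  surviving <- list()
  for (p in concordant) {
    v <- is_anti_correlated(p, disease_sig, config)
    if (v$ok) {
      attr(p, "disease_errors") <- v$errors
      surviving[[length(surviving) + 1L]] <- p
    }
  }
  structure(list(source_id = drug_id,
                 target_id = disease_id,
                 prioritized = length(surviving) >= 1L,
                 n_paths_total = n_total,
                 n_inhibiting = n_inhib,
                 n_concordant = length(concordant),
                 n_surviving = length(surviving),
                 surviving_paths = surviving),
            class = "prioritization_result")
}

check_context <- function(sig, context, id) {
  stopifnot(inherits(sig, "causal_signature"))
  if (!identical(sig$context, context))
    stop(sprintf("signature context is '%s' but a '%s' signature is required",
                 sig$context, context))
  if (!is.na(sig$context_id) && !identical(sig$context_id, id))
    stop(sprintf("signature context_id '%s' does not match node '%s'",
                 sig$context_id, id))
  invisible(sig)
}

#' @export
print.prioritization_result <- function(x, ...) {
  cat(sprintf("%s -> %s: %s (%d paths, %d inhibiting, %d concordant, %d surviving)\n",
              x$source_id, x$target_id,
              if (x$prioritized) "PRIORITIZED" else "not prioritized",
              x$n_paths_total, x$n_inhibiting, x$n_concordant, x$n_surviving))
  invisible(x)
}

#' Prioritize every drug-disease combination
#'
#' Runs [is_drug_prioritized()] over each pair formed from the supplied drug
#' and disease signatures whose nodes exist in the KG. Pairs are ranked:
#' prioritized pairs first, by the number of surviving paths (descending),
#' ties broken by the surviving fraction `n_surviving / n_paths_total`
#' (descending) and then lexicographically by pair id. Entirely
#' deterministic.
#'
#' @param kg a [causal_kg()].
#' @param drug_sigs named list of drug [causal_signature()]s (names are
#'   chemical node ids), or a manifest TSV path for
#'   [load_signature_manifest()].
#' @param disease_sigs named list of disease signatures, or a manifest path.
#' @param config a [reasoning_config()].
#' @return A list of class `prioritization_ranking` with `table` (ranked
#'   data.frame: `drug_id`, `disease_id`, `n_paths`, `n_concordant`,
#'   `n_surviving`, `prioritized`), `results` (the per-pair
#'   `prioritization_result`s, keyed `"drug|disease"`), `funnel` (pairs
#'   evaluated, with >= 1 path, with >= 1 concordant path, with >= 1
#'   surviving path) and `skipped` (signature ids without a KG node).
#' @export
prioritize_pairs <- function(kg, drug_sigs, disease_sigs,
                             config = reasoning_config()) {
  if (is.character(drug_sigs)) drug_sigs <- load_signature_manifest(drug_sigs)
  if (is.character(disease_sigs)) disease_sigs <- load_signature_manifest(disease_sigs)
  if (!length(drug_sigs) || !length(disease_sigs))
    stop("need at least one drug and one disease signature")
  kind_of <- node_kinds(kg)
  drug_ids <- names(drug_sigs)
  disease_ids <- names(disease_sigs)
  skip_drugs <- drug_ids[!(drug_ids %in% names(kind_of) &
                             kind_of[drug_ids] == "chemical")]
  skip_dis <- disease_ids[!(disease_ids %in% names(kind_of) &
                              kind_of[disease_ids] == "disease")]
  drug_ids <- sort(setdiff(drug_ids, skip_drugs))
  disease_ids <- sort(setdiff(disease_ids, skip_dis))
  if (length(skip_drugs) || length(skip_dis))
    message("skipped signatures without a matching KG node: ",
            paste(c(skip_drugs, skip_dis), collapse = ", "))

  results <- list()
  rows <- vector("list", length(drug_ids) * length(disease_ids))
  k <- 0L
  for (d in drug_ids) {
    for (x in disease_ids) {
      res <- is_drug_prioritized(kg, d, x, drug_sigs[[d]], disease_sigs[[x]],
                                 config)
      k <- k + 1L
      results[[paste(d, x, sep = "|")]] <- res
      rows[[k]] <- data.frame(drug_id = d, disease_id = x,
                              n_paths = res$n_paths_total,
                              n_concordant = res$n_concordant,
                              n_surviving = res$n_surviving,
                              prioritized = res$prioritized,
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  frac <- ifelse(tab$n_paths > 0, tab$n_surviving / tab$n_paths, 0)
  ord <- order(-as.integer(tab$prioritized), -tab$n_surviving, -frac,
               tab$drug_id, tab$disease_id, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  funnel <- c(pairs_evaluated = nrow(tab),
              pairs_with_path = sum(tab$n_paths > 0L),
              pairs_concordant = sum(tab$n_concordant > 0L),
              pairs_surviving = sum(tab$prioritized))
  structure(list(table = tab, results = results, funnel = funnel,
                 skipped = c(skip_drugs, skip_dis), config = config),
            class = "prioritization_ranking")
}

#' @export
print.prioritization_ranking <- function(x, ...) {
  f <- x$funnel
  cat(sprintf("pair funnel: %d evaluated -> %d with a path -> %d concordant -> %d prioritized\n",
              f[["pairs_evaluated"]], f[["pairs_with_path"]],
              f[["pairs_concordant"]], f[["pairs_surviving"]]))
  print(utils::head(x$table, 10L))
  if (nrow(x$table) > 10L) cat(sprintf("... %d more pairs\n", nrow(x$table) - 10L))
  invisible(x)
}

#' Prioritize upstream protein targets for a disease
#'
#' The reverse variant of the algorithm: starting from a disease, every
#' node-simple path `protein -> ... -> disease` of 2..`lmax` edges is
#' enumerated by walking in-edges backwards from the disease. The start
#' protein plays the role of the perturbation hypothesis (assumed active)
#' and is not itself scored; the interior proteins are scored against the
#' disease signature with *direct* sign matching -- an upstream regulator is
#' supported when the signs it propagates reproduce the dysregulations
#' observed in the disease. Proteins are ranked by their number of
#' concordant paths; the number of distinct nodes appearing in those paths
#' is reported alongside as a measure of mechanism breadth.
#'
#' @param kg a [causal_kg()].
#' @param disease_id disease node id.
#' @param disease_sig the disease [causal_signature()].
#' @param config a [reasoning_config()]; the same `lmax` is used as in drug
#'   mode.
#' @return A list of class `target_ranking` with `table` (data.frame
#'   `protein_id`, `n_paths`, `n_concordant`, `n_nodes_concordant`) ranked by
#'   `n_concordant` descending, and `concordant_paths` (named list of path
#'   lists per protein).
#' @export
prioritize_targets <- function(kg, disease_id, disease_sig,
                               config = reasoning_config()) {
  kind_of <- node_kinds(kg)
  if (!disease_id %in% names(kind_of) || kind_of[[disease_id]] != "disease")
    stop("disease_id must be a disease node of the KG: ", disease_id)
  check_context(disease_sig, "disease", disease_id)

  paths <- enumerate_paths_into(kg, disease_id, lmax = config$lmax)
  if (!length(paths)) {
    return(structure(list(
      table = data.frame(protein_id = character(0), n_paths = integer(0),
                         n_concordant = integer(0),
                         n_nodes_concordant = integer(0),
                         stringsAsFactors = FALSE),
      concordant_paths = list()), class = "target_ranking"))
  }
  starts <- vapply(paths, function(p) p$nodes[1L], character(1))
  by_start <- split(paths, starts)
  rows <- vector("list", length(by_start))
  conc <- list()
  for (i in seq_along(by_start)) {
    prot <- names(by_start)[i]
    ps <- by_start[[i]]
    keep <- vapply(ps, function(p)
      count_path_errors(p, disease_sig, orientation = +1L,
                        config = config) <= config$max_errors,
      logical(1))
    cp <- ps[keep]
    conc[[prot]] <- cp
    rows[[i]] <- data.frame(
      protein_id = prot,
      n_paths = length(ps),
      n_concordant = length(cp),
      n_nodes_concordant = length(unique(unlist(lapply(cp, `[[`, "nodes")))),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$n_concordant, -tab$n_paths, tab$protein_id,
                   method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, concordant_paths = conc),
            class = "target_ranking")
}

#' @export
print.target_ranking <- function(x, ...) {
  cat(sprintf("%d candidate upstream proteins\n", nrow(x$table)))
  print(utils::head(x$table, 10L))
  invisible(x)
}

#' Extract the mechanism-of-action subgraph of a prioritized pair
#'
#' The union of all surviving paths of a prioritized drug-disease pair,
#' returned as a valid [causal_kg()]. Each edge carries a
#' `traversal_count` column recording how many surviving paths use it --
#' edges shared by many paths are the load-bearing steps of the proposed
#' mechanism.
#'
#' @param result a prioritized `prioritization_result` from
#'   [is_drug_prioritized()].
#' @param kg the [causal_kg()] the result was computed on (provides node
#'   kinds).
#' @return A `causal_kg` whose `edges` have an extra `traversal_count`
#'   column.
#' @export
extract_mechanism_subgraph <- function(result, kg) {
  stopifnot(inherits(result, "prioritization_result"))
  if (!result$prioritized)
    stop("no mechanism subgraph: the pair was not prioritized")
  kind_of <- node_kinds(kg)
  edge_rows <- list()
  for (p in result$surviving_paths) {
    n <- length(p$nodes)
    edge_rows[[length(edge_rows) + 1L]] <-
      data.frame(source = p$nodes[-n], target = p$nodes[-1L], sign = p$signs,
                 stringsAsFactors = FALSE)
  }
  all_edges <- do.call(rbind, edge_rows)
  key <- paste(all_edges$source, all_edges$target, all_edges$sign, sep = "\r")
  counts <- table(key)
  uniq <- all_edges[!duplicated(key), , drop = FALSE]
  uniq$traversal_count <- as.integer(counts[paste(uniq$source, uniq$target,
                                                  uniq$sign, sep = "\r")])
  ids <- unique(c(uniq$source, uniq$target))
  sub <- causal_kg(nodes = data.frame(id = ids, kind = kind_of[ids],
                                      stringsAsFactors = FALSE),
                   edges = uniq)
  sub
}

#' Write a ranked prioritization table as TSV
#'
#' Columns: `drug_id`, `disease_id`, `n_paths`, `n_concordant`,
#' `n_surviving`, `prioritized`.
#'
#' @param ranking a `prioritization_ranking` from [prioritize_pairs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(ranking, path) {
  stopifnot(inherits(ranking, "prioritization_ranking"))
  utils::write.table(ranking$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
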