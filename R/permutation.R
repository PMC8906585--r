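## Degree-preserving XSwap null model and permutation experiments.

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG state afterwards. All randomness in this package flows
## through this helper.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

#' Permutation experiment specification
#'
#' @param n_permutations number of permuted replicates (>= 1).
#' @param swap_multiplier attempted XSwap swaps per KG edge (>= 1).
#' @param seed integer seed; replicate i derives its own seed from it.
#' @param permute_kg permute KG edges with XSwap?
#' @param permute_signatures shuffle signature values?
#' @return A list of class `permutation_spec`.
#' @export
permutation_spec <- function(n_permutations = 20L, swap_multiplier = 10L,
                             seed = 1L, permute_kg = TRUE,
                             permute_signatures = TRUE) {
  n_permutations <- as.integer(n_permutations)
  swap_multiplier <- as.integer(swap_multiplier)
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (swap_multiplier < 1L) stop("swap_multiplier must be >= 1")
  if (!isTRUE(permute_kg) && !isTRUE(permute_signatures))
    stop("at least one of permute_kg / permute_signatures must be TRUE")
  structure(list(n_permutations = n_permutations,
                 swap_multiplier = swap_multiplier,
                 seed = as.integer(seed),
                 permute_kg = isTRUE(permute_kg),
                 permute_signatures = isTRUE(permute_signatures)),
            class = "permutation_spec")
}

#' Degree-preserving XSwap permutation of a causal KG
#'
#' Randomizes the KG while preserving every node's exact in- and out-degree
#' and the edge count of every (source-kind, target-kind) stratum. Swaps are
#' attempted only *within* a stratum, so the typed edge constraints can
#' never be violated: a candidate swap takes two edges `a->b`, `c->d` and
#' proposes `a->d`, `c->b`, with each edge's sign travelling with its source
#' stub. A swap is rejected (not retried elsewhere) when it would create a
#' self-edge or duplicate an existing (source, target, sign) triple --
#' the standard rejection scheme, which keeps the sampler simple and
#' degree-exact. Strata with fewer than two edges are left untouched.
#' Optionally the edge signs themselves can additionally be shuffled within
#' each stratum.
#'
#' @param kg a [causal_kg()].
#' @param swap_multiplier attempted swaps = `swap_multiplier * n_edges` per
#'   stratum.
#' @param seed integer seed (reproducible; `NULL` uses the current RNG
#'   state).
#' @param shuffle_signs also permute edge signs within each stratum.
#' @return A permuted [causal_kg()] on the same node set.
#' @export
xswap_permute_kg <- function(kg, swap_multiplier = 10L, seed = NULL,
                             shuffle_signs = FALSE) {
  stopifnot(inherits(kg, "causal_kg"))
  with_seed(seed, {
    e <- kg$edges
    if (nrow(e) < 2L) return(kg)
    kind_of <- node_kinds(kg)
    stratum <- paste(kind_of[e$source], kind_of[e$target])
    seen <- new.env(parent = emptyenv(), hash = TRUE)
    for (k in seq_len(nrow(e)))
      assign(paste(e$source[k], e$target[k], e$sign[k], sep = "\r"), TRUE,
             envir = seen)
    for (s in sort(unique(stratum))) {
      idx <- which(stratum == s)
      m <- length(idx)
      if (m < 2L) next
      n_attempts <- swap_multiplier * m
      for (a in seq_len(n_attempts)) {
        ij <- idx[sample.int(m, 2L)]
        i <- ij[1L]; j <- ij[2L]
        si <- e$source[i]; ti <- e$target[i]; gi <- e$sign[i]
        sj <- e$source[j]; tj <- e$target[j]; gj <- e$sign[j]
        if (ti == tj) next                 # no-op swap
        if (si == tj || sj == ti) next     # would create a self-edge
        k1 <- paste(si, tj, gi, sep = "\r")
        k2 <- paste(sj, ti, gj, sep = "\r")
        if (exists(k1, envir = seen, inherits = FALSE) ||
            exists(k2, envir = seen, inherits = FALSE)) next
        rm(list = c(paste(si, ti, gi, sep = "\r"),
                    paste(sj, tj, gj, sep = "\r")), envir = seen)
        assign(k1, TRUE, envir = seen)
        assign(k2, TRUE, envir = seen)
        e$target[i] <- tj
        e$target[j] <- ti
      }
      if (shuffle_signs) {
        perm <- sample(e$sign[idx])
        ## keep the triple set duplicate-free: only accept the shuffle if it
        ## introduces no duplicate (source, target, sign)
        cand <- e
        cand$sign[idx] <- perm
        key <- paste(cand$source, cand$target, cand$sign, sep = "\r")
        if (!anyDuplicated(key)) e <- cand
      }
    }
    causal_kg(nodes = kg$nodes, edges = e)
  })
}

#' Shuffle the values of a binarized signature
#'
#' Reassigns the observed calls to the same gene-id key set by a seeded
#' uniform shuffle. The value multiset (counts of -1/0/+1) is preserved
#' exactly and unmeasured genes remain unmeasured, so only the *assignment*
#' of directions to genes is destroyed.
#'
#' @param sig a [causal_signature()].
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @return A permuted [causal_signature()].
#' @export
permute_signature <- function(sig, seed = NULL) {
  stopifnot(inherits(sig, "causal_signature"))
  with_seed(seed, {
    v <- sig$values
    if (length(v) > 1L)
      v <- stats::setNames(sample(unname(sig$values)), names(sig$values))
    causal_signature(v, context = sig$context, context_id = sig$context_id,
                     cutoff_used = sig$cutoff_used)
  })
}

#' Permutation null experiment for a prioritization run
#'
#' Runs [prioritize_pairs()] on the observed KG and signatures, then on
#' `n_permutations` replicates in which the KG is XSwap-permuted and/or all
#' signature values are shuffled (both preserving their marginal structure).
#' If the signal exploited by the method is real, permutation should
#' collapse the number of prioritized pairs and their precision. Empirical
#' one-sided p-values use the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n_permutations)`, which cannot return
#' zero at finite `n_permutations`.
#'
#' @param kg a [causal_kg()].
#' @param drug_sigs,disease_sigs named signature lists (or manifest paths),
#'   as in [prioritize_pairs()].
#' @param labels optional [label_set()]; when given, precision is also
#'   tracked across replicates.
#' @param config a [reasoning_config()].
#' @param spec a [permutation_spec()].
#' @return A list of class `permutation_report`: `observed`
#'   (`n_prioritized`, `precision`), `null` (data.frame per replicate),
#'   `p_n_prioritized`, `p_precision` (NA without labels), and the spec.
#' @export
permutation_experiment <- function(kg, drug_sigs, disease_sigs, labels = NULL,
                                   config = reasoning_config(),
                                   spec = permutation_spec()) {
  stopifnot(inherits(spec, "permutation_spec"))
  if (is.character(drug_sigs)) drug_sigs <- load_signature_manifest(drug_sigs)
  if (is.character(disease_sigs)) disease_sigs <- load_signature_manifest(disease_sigs)

  obs <- prioritize_pairs(kg, drug_sigs, disease_sigs, config)
  obs_n <- sum(obs$table$prioritized)
  obs_prec <- if (!is.null(labels)) precision(obs, labels) else NA_real_

  null_rows <- vector("list", spec$n_permutations)
  for (r in seq_len(spec$n_permutations)) {
    rep_seed <- (spec$seed + 104729L * r) %% 2147483647L
    pkg <- if (spec$permute_kg)
      xswap_permute_kg(kg, spec$swap_multiplier, seed = rep_seed) else kg
    if (spec$permute_signatures) {
      ds <- lapply(seq_along(drug_sigs), function(i)
        permute_signature(drug_sigs[[i]], seed = rep_seed + i))
      names(ds) <- names(drug_sigs)
      xs <- lapply(seq_along(disease_sigs), function(i)
        permute_signature(disease_sigs[[i]], seed = rep_seed + 10000L + i))
      names(xs) <- names(disease_sigs)
    } else {
      ds <- drug_sigs; xs <- disease_sigs
    }
    run <- prioritize_pairs(pkg, ds, xs, config)
    null_rows[[r]] <- data.frame(
      replicate = r,
      n_prioritized = sum(run$table$prioritized),
      precision = if (!is.null(labels)) precision(run, labels) else NA_real_)
  }
  null <- do.call(rbind, null_rows)
  p_n <- (1 + sum(null$n_prioritized >= obs_n)) / (1 + spec$n_permutations)
  p_prec <- if (!is.null(labels) && !is.na(obs_prec)) {
    np <- null$precision
    np[is.na(np)] <- 0  # an empty null prioritized set cannot beat observed
    (1 + sum(np >= obs_prec)) / (1 + spec$n_permutations)
  } else NA_real_
  structure(list(observed = list(n_prioritized = obs_n, precision = obs_prec),
                 null = null,
                 p_n_prioritized = p_n,
                 p_precision = p_prec,
                 spec = spec),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("observed: %d prioritized pairs (precision %s)\n",
              x$observed$n_prioritized,
              format(x$observed$precision, digits = 3)))
  cat(sprintf("null (%d permutations): prioritized mean %.2f, max %d; p = %.4f\n",
              nrow(x$null), mean(x$null$n_prioritized),
              max(x$null$n_prioritized), x$p_n_prioritized))
  invisible(x)
}

#' Write a permutation report (per-replicate TSV + JSON summary)
#'
#' @param report a `permutation_report`.
#' @param tsv_path per-replicate counts TSV.
#' @param json_path JSON summary (observed, null mean/sd, empirical p).
#' @return Invisibly, the two paths.
#' @export
write_permutation_report <- function(report, tsv_path, json_path) {
  stopifnot(inherits(report, "permutation_report"))
  utils::write.table(report$null, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(observed = report$observed,
         null_mean = mean(report$null$n_prioritized),
         null_sd = stats::sd(report$null$n_prioritized),
         null_max = max(report$null$n_prioritized),
         p_n_prioritized = report$p_n_prioritized,
         p_precision = report$p_precision,
         n_permutations = report$spec$n_permutations),
    json_path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(c(tsv_path, json_path))
}
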