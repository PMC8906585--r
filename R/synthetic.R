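## Synthetic planted-mechanism benchmarks.

#' Specification for a synthetic benchmark
#'
#' Describes a random typed signed KG with planted drug -> ... -> disease
#' mechanisms and matching signatures. Defaults emulate a small, sparse
#' curated causal KG: sub-critical protein-protein branching so that path
#' counts stay biologically plausible, roughly 30% inhibitory edges, and a
#' background binarized call rate of 15% up / 15% down per measured gene
#' (loosely what a |log2FC| >= 1 cutoff retains).
#'
#' @param n_chemicals,n_proteins,n_diseases node counts (>= 1).
#' @param density_chem_prot,density_prot_prot,density_prot_dis per-stratum
#'   edge probabilities in `(0, 1]`.
#' @param inhibition_fraction probability that an edge is inhibitory.
#' @param n_planted_pairs number of drug-disease pairs with a planted
#'   mechanism; this generator assigns each planted chemical and disease at
#'   most one mechanism, so it must not exceed
#'   `min(n_chemicals, n_diseases)`.
#' @param planted_path_length length (edges) of each planted path, in
#'   `[2, lmax]`.
#' @param signature_noise per-gene probability of corrupting a planted
#'   signature value.
#' @param noise_mode `"both"` (flip or zero with equal probability),
#'   `"flip"` (sign inversion only) or `"zero"` (erasure to 0 only) --
#'   the two failure modes of the error definition (wrong direction, absent
#'   support), separable for testing.
#' @param missingness per-gene probability of dropping a value from a
#'   signature entirely (unmeasured).
#' @param background_probs probabilities of `-1`, `0`, `+1` for off-path
#'   measured genes.
#' @param lmax path-length bound the benchmark is meant to be analysed with.
#' @param isolate_planted when `TRUE` (default) planted chemicals get no
#'   background out-edges and planted diseases no background in-edges,
#'   emulating selective probes: every path of a planted pair then passes
#'   through the planted entry and exit proteins.
#' @param certify_decoys when `TRUE` (default) and mechanisms are planted,
#'   background signature values are zeroed until no decoy (non-planted)
#'   pair retains a surviving path with `certify_max_errors` errors or
#'   fewer, so planted labels are recoverable at perfect precision at that
#'   budget.
#' @param certify_max_errors error budget used for decoy certification.
#' @param seed integer seed; the whole benchmark is reproducible from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_chemicals = 10L, n_proteins = 60L,
                           n_diseases = 5L,
                           density_chem_prot = 0.03,
                           density_prot_prot = 0.015,
                           density_prot_dis = 0.04,
                           inhibition_fraction = 0.3,
                           n_planted_pairs = 5L,
                           planted_path_length = 4L,
                           signature_noise = 0,
                           noise_mode = c("both", "flip", "zero"),
                           missingness = 0,
                           background_probs = c(0.15, 0.70, 0.15),
                           lmax = 7L,
                           isolate_planted = TRUE,
                           certify_decoys = TRUE,
                           certify_max_errors = 0L,
                           seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(n_chemicals >= 1L, n_proteins >= 1L, n_diseases >= 1L,
            density_chem_prot > 0, density_chem_prot <= 1,
            density_prot_prot > 0, density_prot_prot <= 1,
            density_prot_dis > 0, density_prot_dis <= 1,
            inhibition_fraction >= 0, inhibition_fraction <= 1,
            n_planted_pairs >= 0L,
            planted_path_length >= 2L, planted_path_length <= lmax,
            signature_noise >= 0, signature_noise <= 1,
            missingness >= 0, missingness < 1,
            length(background_probs) == 3L, all(background_probs >= 0),
            abs(sum(background_probs) - 1) < 1e-8)
  if (n_planted_pairs > n_chemicals * n_diseases)
    stop("more planted pairs requested than chemical x disease combinations")
  if (n_planted_pairs > min(n_chemicals, n_diseases))
    stop("this generator plants at most one mechanism per chemical and per ",
         "disease; n_planted_pairs must be <= min(n_chemicals, n_diseases)")
  if (n_planted_pairs * (planted_path_length - 1L) > n_proteins)
    stop("not enough proteins for disjoint planted mechanisms")
  structure(list(n_chemicals = as.integer(n_chemicals),
                 n_proteins = as.integer(n_proteins),
                 n_diseases = as.integer(n_diseases),
                 density_chem_prot = density_chem_prot,
                 density_prot_prot = density_prot_prot,
                 density_prot_dis = density_prot_dis,
                 inhibition_fraction = inhibition_fraction,
                 n_planted_pairs = as.integer(n_planted_pairs),
                 planted_path_length = as.integer(planted_path_length),
                 signature_noise = signature_noise,
                 noise_mode = noise_mode,
                 missingness = missingness,
                 background_probs = background_probs,
                 lmax = as.integer(lmax),
                 isolate_planted = isTRUE(isolate_planted),
                 certify_decoys = isTRUE(certify_decoys),
                 certify_max_errors = as.integer(certify_max_errors),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

pad_ids <- function(prefix, n) sprintf("%s:%0*d", prefix, nchar(n), seq_len(n))

rsign <- function(n, inhibition_fraction) {
  ifelse(stats::runif(n) < inhibition_fraction, -1L, 1L)
}

## Bernoulli edge sampling for one stratum over from x to (self pairs and
## excluded endpoints removed). Returns a data.frame(source, target, sign).
sample_stratum <- function(from, to, density, inhibition_fraction,
                           exclude_sources = character(0),
                           exclude_targets = character(0)) {
  from <- setdiff(from, exclude_sources)
  to_all <- setdiff(to, exclude_targets)
  if (!length(from) || !length(to_all))
    return(data.frame(source = character(0), target = character(0),
                      sign = integer(0), stringsAsFactors = FALSE))
  grid <- expand.grid(source = from, target = to_all,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, , drop = FALSE]
  grid <- grid[order(grid$source, grid$target, method = "radix"), , drop = FALSE]
  keep <- stats::runif(nrow(grid)) < density
  grid <- grid[keep, , drop = FALSE]
  grid$sign <- rsign(nrow(grid), inhibition_fraction)
  grid
}

#' Generate a synthetic planted-mechanism benchmark
#'
#' Builds (i) a background KG by stratified Bernoulli edge sampling, (ii)
#' one guaranteed mechanism path per planted drug-disease pair whose
#' cumulative effect inhibits the disease, with globally disjoint
#' intermediate proteins, (iii) drug signatures assigning each on-path
#' protein its inferred regulation sign and disease signatures its
#' negation, with configurable noise and missingness, off-path genes drawn
#' from the background call distribution, and (iv) planted pairs as the
#' positive label set. With `noise = missingness = 0`, every planted pair
#' has at least one zero-error surviving path by construction; with
#' decoy certification (default), no non-planted pair has one.
#'
#' @param spec a [synthetic_spec()].
#' @return A list of class `synthetic_benchmark`: `kg` ([causal_kg()]),
#'   `drug_sigs` and `disease_sigs` (named signature lists covering every
#'   chemical/disease), `labels` ([label_set()] of planted pairs), and
#'   `truth` (planted pairs and paths, decoy pairs, the generator's own
#'   per-stratum edge counts, and the spec).
#' @export
generate_benchmark <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_benchmark_impl(spec))
}

generate_benchmark_impl <- function(spec) {
  chems <- pad_ids("chem", spec$n_chemicals)
  prots <- pad_ids("prot", spec$n_proteins)
  dises <- pad_ids("dis", spec$n_diseases)

  ## -- planted mechanisms ---------------------------------------------------
  n_plant <- spec$n_planted_pairs
  planted_chems <- if (n_plant) sample(chems, n_plant) else character(0)
  planted_dises <- if (n_plant) sample(dises, n_plant) else character(0)
  n_inter <- spec$planted_path_length - 1L
  inter_pool <- if (n_plant) sample(prots, n_plant * n_inter) else character(0)
  planted_paths <- list()
  planted_edges <- list()
  for (i in seq_len(n_plant)) {
    inter <- inter_pool[seq.int((i - 1L) * n_inter + 1L, i * n_inter)]
    nodes <- c(planted_chems[i], inter, planted_dises[i])
    signs <- rsign(spec$planted_path_length, spec$inhibition_fraction)
    if (prod(signs) != -1L)  # the mechanism must revert the disease
      signs[length(signs)] <- -signs[length(signs)]
    p <- causal_path(nodes, signs)
    planted_paths[[paste(planted_chems[i], planted_dises[i], sep = "|")]] <- p
    planted_edges[[i]] <- data.frame(source = nodes[-length(nodes)],
                                     target = nodes[-1L], sign = signs,
                                     stringsAsFactors = FALSE)
  }

  ## -- background KG --------------------------------------------------------
  excl_src <- if (spec$isolate_planted) planted_chems else character(0)
  excl_tgt <- if (spec$isolate_planted) planted_dises else character(0)
  bg <- rbind(
    sample_stratum(chems, prots, spec$density_chem_prot,
                   spec$inhibition_fraction, exclude_sources = excl_src),
    sample_stratum(prots, prots, spec$density_prot_prot,
                   spec$inhibition_fraction),
    sample_stratum(prots, dises, spec$density_prot_dis,
                   spec$inhibition_fraction, exclude_targets = excl_tgt))
  edges <- rbind(bg, do.call(rbind, planted_edges))
  if (is.null(edges))
    edges <- data.frame(source = character(0), target = character(0),
                        sign = integer(0), stringsAsFactors = FALSE)
  key <- paste(edges$source, edges$target, edges$sign, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]

  nodes <- data.frame(
    id = c(chems, prots, dises),
    kind = rep(c("chemical", "protein", "disease"),
               c(spec$n_chemicals, spec$n_proteins, spec$n_diseases)),
    stringsAsFactors = FALSE)
  kg <- causal_kg(nodes, edges)

  ## generator-side stratum bookkeeping (independent of kg_stats)
  kind_of <- stats::setNames(nodes$kind, nodes$id)
  stratum_counts <- table(paste(kind_of[edges$source], kind_of[edges$target],
                                edges$sign))

  ## -- signatures -----------------------------------------------------------
  draw_background <- function() {
    stats::setNames(
      sample(c(-1L, 0L, 1L), spec$n_proteins, replace = TRUE,
             prob = spec$background_probs),
      prots)
  }
  corrupt <- function(v) {
    hit <- stats::runif(length(v)) < spec$signature_noise
    if (!any(hit)) return(v)
    mode <- spec$noise_mode
    how <- switch(mode,
                  flip = rep("flip", sum(hit)),
                  zero = rep("zero", sum(hit)),
                  both = sample(c("flip", "zero"), sum(hit), replace = TRUE))
    v[hit][how == "flip"] <- -v[hit][how == "flip"]
    v[hit][how == "zero"] <- 0L
    v
  }
  thin <- function(v) {
    if (spec$missingness <= 0) return(v)
    v[stats::runif(length(v)) >= spec$missingness]
  }

  drug_sigs <- stats::setNames(vector("list", length(chems)), chems)
  for (d in chems) {
    v <- draw_background()
    j <- match(d, planted_chems)
    if (!is.na(j)) {
      p <- planted_paths[[paste(d, planted_dises[j], sep = "|")]]
      v[names(p$inferred)] <- corrupt(p$inferred)
    }
    drug_sigs[[d]] <- causal_signature(thin(v), context = "drug",
                                       context_id = d)
  }
  disease_sigs <- stats::setNames(vector("list", length(dises)), dises)
  for (x in dises) {
    v <- draw_background()
    j <- match(x, planted_dises)
    if (!is.na(j)) {
      p <- planted_paths[[paste(planted_chems[j], x, sep = "|")]]
      v[names(p$inferred)] <- corrupt(-p$inferred)
    }
    disease_sigs[[x]] <- causal_signature(thin(v), context = "disease",
                                          context_id = x)
  }

  ## -- decoy bookkeeping ----------------------------------------------------
  combos <- expand.grid(drug_id = chems, disease_id = dises,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  planted_key <- paste(planted_chems, planted_dises, sep = "\r")
  is_planted <- paste(combos$drug_id, combos$disease_id, sep = "\r") %in%
    planted_key
  decoys <- combos[!is_planted, , drop = FALSE]
  rownames(decoys) <- NULL

  ## -- decoy certification --------------------------------------------------
  ## Zero out background signature support until no decoy pair retains a
  ## surviving path within certify_max_errors. Zeroing only ever adds
  ## errors, so this converges, never revives a path, and never touches a
  ## planted on-path value.
  if (spec$certify_decoys && n_plant > 0L && nrow(decoys)) {
    cert_cfg <- reasoning_config(lmax = spec$lmax,
                                 max_errors = spec$certify_max_errors)
    on_drug_path <- function(chem) {
      j <- match(chem, planted_chems)
      if (is.na(j)) character(0)
      else names(planted_paths[[paste(chem, planted_dises[j], sep = "|")]]$inferred)
    }
    on_disease_path <- function(dis) {
      j <- match(dis, planted_dises)
      if (is.na(j)) character(0)
      else names(planted_paths[[paste(planted_chems[j], dis, sep = "|")]]$inferred)
    }
    for (r in seq_len(nrow(decoys))) {
      d <- decoys$drug_id[r]; x <- decoys$disease_id[r]
      for (iter in 1:10000) {
        res <- is_drug_prioritized(kg, d, x, drug_sigs[[d]], disease_sigs[[x]],
                                   cert_cfg)
        if (!res$prioritized) break
        p <- res$surviving_paths[[1L]]
        interiors <- names(p$inferred)
        cand <- setdiff(interiors, on_drug_path(d))
        cand <- cand[cand %in% names(drug_sigs[[d]]$values) &
                       drug_sigs[[d]]$values[cand] != 0L]
        if (length(cand)) {
          drug_sigs[[d]]$values[cand[1L]] <- 0L
        } else {
          cand <- setdiff(interiors, on_disease_path(x))
          cand <- cand[cand %in% names(disease_sigs[[x]]$values) &
                         disease_sigs[[x]]$values[cand] != 0L]
          if (!length(cand))
            stop("decoy certification could not break a surviving path")
          disease_sigs[[x]]$values[cand[1L]] <- 0L
        }
      }
    }
  }

  labels <- label_set(planted_chems, planted_dises,
                      provenance = "planted synthetic mechanisms")
  truth <- list(
    planted_pairs = data.frame(drug_id = planted_chems,
                               disease_id = planted_dises,
                               stringsAsFactors = FALSE),
    planted_paths = planted_paths,
    decoy_pairs = decoys,
    stratum_counts = stratum_counts,
    spec = spec)
  structure(list(kg = kg, drug_sigs = drug_sigs, disease_sigs = disease_sigs,
                 labels = labels, truth = truth),
            class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat("synthetic_benchmark\n")
  print(x$kg)
  cat(sprintf("%d planted pairs, %d decoy pairs, %d drug and %d disease signatures\n",
              nrow(x$truth$planted_pairs), nrow(x$truth$decoy_pairs),
              length(x$drug_sigs), length(x$disease_sigs)))
  invisible(x)
}

#' Write a benchmark to a directory in the package's file formats
#'
#' Emits `kg.tsv`, per-signature TSVs under `signatures/`,
#' `drug_manifest.tsv`, `disease_manifest.tsv`, `labels.tsv` and
#' `truth.json`. Fully deterministic given the benchmark object.
#'
#' @param bench a `synthetic_benchmark` from [generate_benchmark()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "synthetic_benchmark"))
  dir.create(file.path(dir, "signatures"), recursive = TRUE,
             showWarnings = FALSE)
  write_kg(bench$kg, file.path(dir, "kg.tsv"))
  write_manifest <- function(sigs, context, manifest_path) {
    rows <- vector("list", length(sigs))
    ids <- sort(names(sigs))
    for (i in seq_along(ids)) {
      id <- ids[i]
      fn <- file.path("signatures",
                      paste0(context, "_", gsub("[^A-Za-z0-9._-]", "_", id),
                             ".tsv"))
      write_signature(sigs[[id]], file.path(dir, fn))
      rows[[i]] <- data.frame(context_id = id, path = fn, context = context,
                              stringsAsFactors = FALSE)
    }
    utils::write.table(do.call(rbind, rows), manifest_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_manifest(bench$drug_sigs, "drug", file.path(dir, "drug_manifest.tsv"))
  write_manifest(bench$disease_sigs, "disease",
                 file.path(dir, "disease_manifest.tsv"))
  utils::write.table(as.data.frame(bench$labels), file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- bench$truth
  jsonlite::write_json(
    list(planted_pairs = truth$planted_pairs,
         planted_paths = lapply(truth$planted_paths, function(p)
           list(nodes = p$nodes, signs = p$signs)),
         decoy_pairs = truth$decoy_pairs,
         stratum_counts = as.list(truth$stratum_counts),
         spec = unclass(truth$spec)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' The five-node worked example
#'
#' A miniature KG used throughout the documentation: chemical `D`
#' (`pubchem.compound:1`), proteins `P1`-`P3` (`ncbigene:1`-`3`), disease
#' `X` (`mondo:0000001`), with edges `D -(-)-> P1`, `P1 -(+)-> P2`,
#' `P2 -(-)-> P3`, `P3 -(+)-> X`, and `D -(+)-> P2`. Two acyclic paths
#' connect D to X; the signatures are built around the 3-edge path
#' `D -> P2 -> P3 -> X` (inferred P2 up, P3 down, net inhibition of X), so
#' the pair (D, X) is prioritized with one zero-error surviving path under
#' the default configuration.
#'
#' @return List with `kg`, `drug_sig`, `disease_sig`, and the node ids
#'   (`drug_id`, `disease_id`).
#' @examples
#' fx <- worked_fixture()
#' is_drug_prioritized(fx$kg, fx$drug_id, fx$disease_id,
#'                     fx$drug_sig, fx$disease_sig)
#' @export
worked_fixture <- function() {
  D <- "pubchem.compound:1"
  P <- paste0("ncbigene:", 1:3)
  X <- "mondo:0000001"
  kg <- causal_kg(
    nodes = data.frame(id = c(D, P, X),
                       kind = c("chemical", rep("protein", 3), "disease"),
                       stringsAsFactors = FALSE),
    edges = data.frame(
      source = c(D, P[1], P[2], P[3], D),
      target = c(P[1], P[2], P[3], X, P[2]),
      sign = c(-1L, 1L, -1L, 1L, 1L),
      stringsAsFactors = FALSE))
  drug_sig <- causal_signature(
    stats::setNames(c(-1L, 1L, -1L), P), context = "drug", context_id = D)
  disease_sig <- causal_signature(
    stats::setNames(c(1L, -1L, 1L), P), context = "disease", context_id = X)
  list(kg = kg, drug_sig = drug_sig, disease_sig = disease_sig,
       drug_id = D, disease_id = X)
}
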