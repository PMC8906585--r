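## Transcriptomic signatures: fold-change tables, binarization, KG coverage.

#' Construct a fold-change table
#'
#' Gene-level log2 fold changes from a differential-expression contrast,
#' before binarization. Gene identifiers are opaque strings expected to match
#' the protein node ids of the knowledge graph (typically ENTREZ-style
#' CURIEs); no identifier resolution is performed.
#'
#' @param gene_id character vector of unique gene ids.
#' @param log2fc finite numeric log2 fold changes, one per gene.
#' @param p_value optional numeric p-values in `[0, 1]`.
#' @param context `"drug"` (drug-perturbation experiment) or `"disease"`.
#' @param context_id CURIE of the perturbing drug or the disease.
#' @return A data.frame of class `fold_change_table`.
#' @export
fold_change_table <- function(gene_id, log2fc, p_value = NULL,
                              context = c("drug", "disease"),
                              context_id = NA_character_) {
  context <- match.arg(context)
  gene_id <- as.character(gene_id)
  log2fc <- as.numeric(log2fc)
  if (anyDuplicated(gene_id))
    stop("duplicate gene id(s): ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(!is.finite(log2fc)))
    stop("log2fc values must be finite")
  if (is.null(p_value)) p_value <- rep(NA_real_, length(gene_id))
  stopifnot(length(p_value) == length(gene_id))
  structure(
    data.frame(gene_id = gene_id, log2fc = log2fc, p_value = as.numeric(p_value),
               stringsAsFactors = FALSE),
    context = context, context_id = context_id,
    class = c("fold_change_table", "data.frame"))
}

#' Construct a binarized signature
#'
#' A signature maps gene ids to calls in `{-1, 0, +1}` (down-regulated,
#' measured-but-unchanged, up-regulated). Genes absent from the mapping are
#' semantically *unmeasured*, which is distinct from a measured `0`.
#'
#' @param values named integer vector with values in `{-1, 0, 1}`; names are
#'   gene ids.
#' @param context `"drug"` or `"disease"`.
#' @param context_id CURIE of the drug or disease the signature describes.
#' @param cutoff_used the |log2FC| cutoff that produced the calls (`NA` for
#'   signatures distributed pre-binarized).
#' @return An object of class `causal_signature`.
#' @seealso [binarize()], [load_signature()]
#' @export
causal_signature <- function(values, context = c("drug", "disease"),
                             context_id = NA_character_, cutoff_used = NA_real_) {
  context <- match.arg(context)
  v <- as.integer(values)
  names(v) <- names(values)
  if (length(v) && (is.null(names(v)) || anyNA(names(v)) || any(!nzchar(names(v)))))
    stop("signature values must be named by gene id")
  if (anyDuplicated(names(v)))
    stop("duplicate gene id(s): ",
         paste(unique(names(v)[duplicated(names(v))]), collapse = ", "))
  if (length(v) && !all(v %in% c(-1L, 0L, 1L)))
    stop("signature values must be in {-1, 0, 1}")
  structure(list(values = v, context = context, context_id = context_id,
                 cutoff_used = cutoff_used),
            class = "causal_signature")
}

#' @export
print.causal_signature <- function(x, ...) {
  cat(sprintf("causal_signature [%s%s]: %d genes (%d up, %d down, %d unchanged)\n",
              x$context,
              if (is.na(x$context_id)) "" else paste0(": ", x$context_id),
              length(x$values), sum(x$values == 1L), sum(x$values == -1L),
              sum(x$values == 0L)))
  invisible(x)
}

#' Binarize a fold-change table
#'
#' Calls a gene up-regulated (`+1`) when `log2fc >= fc_cutoff`, down-regulated
#' (`-1`) when `log2fc <= -fc_cutoff`, and unchanged (`0`) otherwise. The
#' comparison is inclusive: a gene exactly at the cutoff is called
#' dysregulated. The conventional cutoff is `|log2FC| = 1`, i.e. a two-fold
#' change; stricter cutoffs retain fewer dysregulated genes. An optional
#' p-value filter (off by default) additionally requires
#' `p_value <= p_threshold` for a nonzero call; genes with a missing p-value
#' are left unfiltered.
#'
#' @param table a [fold_change_table()].
#' @param fc_cutoff non-negative |log2FC| cutoff (default 1).
#' @param p_threshold optional p-value ceiling in `(0, 1]`.
#' @return A [causal_signature()] covering the same genes.
#' @examples
#' tab <- fold_change_table(c("gA", "gB", "gC"), c(1.5, -0.3, -2),
#'                          context = "drug", context_id = "pubchem.compound:1")
#' binarize(tab, fc_cutoff = 1)$values
#' @export
binarize <- function(table, fc_cutoff = 1, p_threshold = NULL) {
  stopifnot(inherits(table, "fold_change_table"))
  if (!is.numeric(fc_cutoff) || length(fc_cutoff) != 1L || fc_cutoff < 0)
    stop("fc_cutoff must be a single non-negative number")
  if (!is.null(p_threshold) &&
      (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1))
    stop("p_threshold must lie in (0, 1]")
  v <- integer(nrow(table))
  ## an exact zero is never dysregulated, even at cutoff 0
  v[table$log2fc >= fc_cutoff & table$log2fc > 0] <- 1L
  v[table$log2fc <= -fc_cutoff & table$log2fc < 0] <- -1L
  if (!is.null(p_threshold)) {
    fails_p <- !is.na(table$p_value) & table$p_value > p_threshold
    v[fails_p] <- 0L
  }
  causal_signature(stats::setNames(v, table$gene_id),
                   context = attr(table, "context"),
                   context_id = attr(table, "context_id"),
                   cutoff_used = fc_cutoff)
}

#' Load a signature or fold-change table from a TSV file
#'
#' Accepts either a `gene_id`/`binary` file (values in `{-1, 0, 1}`, the form
#' in which some perturbation compendia distribute their calls) returning a
#' [causal_signature()] directly, or a `gene_id`/`log2fc`(/`p_value`) file
#' returning a [fold_change_table()] to be passed through [binarize()].
#'
#' @param path TSV file with a header.
#' @param context `"drug"` or `"disease"`.
#' @param context_id CURIE bound to the signature.
#' @return A `causal_signature` or `fold_change_table` depending on columns.
#' @export
load_signature <- function(path, context = c("drug", "disease"),
                           context_id = NA_character_) {
  context <- match.arg(context)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(gene_id = "character"))
  if (!"gene_id" %in% names(tab)) stop("missing column gene_id in ", path)
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene id(s) in ", path, ": ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  if ("binary" %in% names(tab)) {
    if (!is.numeric(tab$binary) || !all(tab$binary %in% c(-1, 0, 1)))
      stop("column 'binary' must contain only -1, 0, 1 in ", path)
    causal_signature(stats::setNames(as.integer(tab$binary), tab$gene_id),
                     context = context, context_id = context_id)
  } else if ("log2fc" %in% names(tab)) {
    if (!is.numeric(tab$log2fc)) stop("column 'log2fc' must be numeric in ", path)
    fold_change_table(tab$gene_id, tab$log2fc,
                      p_value = if ("p_value" %in% names(tab)) tab$p_value,
                      context = context, context_id = context_id)
  } else {
    stop("expected a 'binary' or 'log2fc' column in ", path)
  }
}

#' Write a binarized signature as a gene_id/binary TSV
#'
#' @param sig a [causal_signature()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "causal_signature"))
  df <- data.frame(gene_id = names(sig$values), binary = unname(sig$values),
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a signature manifest
#'
#' The manifest is a TSV with columns `context_id`, `path`, `context` binding
#' one signature file per drug or disease to its KG node. Relative paths are
#' resolved against the manifest's directory. Fold-change files are binarized
#' with `fc_cutoff`.
#'
#' @param path manifest TSV.
#' @param fc_cutoff |log2FC| cutoff applied to fold-change files.
#' @return Named list of [causal_signature()]s keyed by `context_id`.
#' @export
load_signature_manifest <- function(path, fc_cutoff = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("context_id", "path", "context") %in% names(man)))
  base <- dirname(path)
  sigs <- vector("list", nrow(man))
  names(sigs) <- man$context_id
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    obj <- load_signature(p, context = man$context[i],
                          context_id = man$context_id[i])
    if (inherits(obj, "fold_change_table")) obj <- binarize(obj, fc_cutoff)
    sigs[[i]] <- obj
  }
  sigs
}

#' Coverage of KG protein nodes by a signature
#'
#' Transcriptomic panels measure only a subset of the proteins in a knowledge
#' graph; unmeasured proteins count as path errors during reasoning, so the
#' coverage fraction bounds how many paths can survive.
#'
#' @param sig a [causal_signature()].
#' @param kg a [causal_kg()].
#' @return A list with counts and fractions of KG protein nodes that are
#'   `measured` (present in the signature), `dysregulated` (call is +/-1),
#'   and `unmeasured`.
#' @export
kg_coverage <- function(sig, kg) {
  stopifnot(inherits(sig, "causal_signature"), inherits(kg, "causal_kg"))
  prot <- nodes_of_kind(kg, "protein")
  measured <- prot[prot %in% names(sig$values)]
  dysreg <- measured[sig$values[measured] != 0L]
  n <- length(prot)
  list(n_proteins = n,
       n_measured = length(measured),
       n_dysregulated = length(dysreg),
       n_unmeasured = n - length(measured),
       frac_measured = if (n) length(measured) / n else NA_real_,
       frac_dysregulated = if (n) length(dysreg) / n else NA_real_,
       frac_unmeasured = if (n) (n - length(measured)) / n else NA_real_)
}
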