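# Fixtures built in code; no data files.

# Random typed signed KG for oracle comparisons. Built directly from edge
# sampling (independent of the synthetic benchmark generator).
random_typed_kg <- function(n_chem = 2, n_prot = 6, n_dis = 2, p_edge = 0.3,
                            p_parallel = 0.1, seed = 1) {
  set.seed(seed)
  chems <- sprintf("c:%d", seq_len(n_chem))
  prots <- sprintf("p:%d", seq_len(n_prot))
  dises <- sprintf("d:%d", seq_len(n_dis))
  pairs <- rbind(
    expand.grid(source = chems, target = prots, stringsAsFactors = FALSE),
    expand.grid(source = prots, target = prots, stringsAsFactors = FALSE),
    expand.grid(source = prots, target = dises, stringsAsFactors = FALSE))
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  keep <- runif(nrow(pairs)) < p_edge
  e <- pairs[keep, , drop = FALSE]
  e$sign <- sample(c(-1L, 1L), nrow(e), replace = TRUE)
  dup <- e[runif(nrow(e)) < p_parallel, , drop = FALSE]
  dup$sign <- -dup$sign   # contradictory parallel edges
  e <- rbind(e, dup)
  causal_kg(
    nodes = data.frame(id = c(chems, prots, dises),
                       kind = rep(c("chemical", "protein", "disease"),
                                  c(n_chem, n_prot, n_dis)),
                       stringsAsFactors = FALSE),
    edges = e)
}

write_fixture_kg_tsv <- function(path = tempfile(fileext = ".tsv")) {
  fx <- worked_fixture()
  write_kg(fx$kg, path)
  path
}

# Write the worked fixture as a full CLI input set (kg, manifests, labels).
write_fixture_inputs <- function(dir = tempfile()) {
  dir.create(file.path(dir, "sigs"), recursive = TRUE, showWarnings = FALSE)
  fx <- worked_fixture()
  write_kg(fx$kg, file.path(dir, "kg.tsv"))
  write_signature(fx$drug_sig, file.path(dir, "sigs", "drug.tsv"))
  write_signature(fx$disease_sig, file.path(dir, "sigs", "disease.tsv"))
  write.table(data.frame(context_id = fx$drug_id,
                         path = file.path("sigs", "drug.tsv"),
                         context = "drug"),
              file.path(dir, "drug_manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(context_id = fx$disease_id,
                         path = file.path("sigs", "disease.tsv"),
                         context = "disease"),
              file.path(dir, "disease_manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(drug_id = fx$drug_id, disease_id = fx$disease_id),
              file.path(dir, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dir
}

prioritized_pair_keys <- function(ranking) {
  tab <- ranking$table[ranking$table$prioritized, , drop = FALSE]
  sort(paste(tab$drug_id, tab$disease_id, sep = "|"))
}
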