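test_that("pair ranking finds exactly the planted pair among all combos", {
  bench <- generate_benchmark(synthetic_spec(
    n_chemicals = 2, n_proteins = 20, n_diseases = 2, n_planted_pairs = 1,
    seed = 41))
  ranking <- prioritize_pairs(bench$kg, bench$drug_sigs, bench$disease_sigs,
                              reasoning_config(max_errors = 0))
  planted <- paste(bench$truth$planted_pairs$drug_id,
                   bench$truth$planted_pairs$disease_id, sep = "|")
  expect_equal(prioritized_pair_keys(ranking), planted)
  expect_equal(nrow(ranking$table), 4)

  # funnel counts never increase across the three steps
  f <- ranking$funnel
  expect_true(f[["pairs_with_path"]] <= f[["pairs_evaluated"]])
  expect_true(f[["pairs_concordant"]] <= f[["pairs_with_path"]])
  expect_true(f[["pairs_surviving"]] <= f[["pairs_concordant"]])
})

test_that("signatures without a KG node are skipped and reported", {
  fx <- worked_fixture()
  sigs <- list(fx$drug_sig,
               causal_signature(c(g1 = 1L), context = "drug",
                                context_id = "pubchem.compound:999"))
  names(sigs) <- c(fx$drug_id, "pubchem.compound:999")
  expect_message(
    ranking <- prioritize_pairs(fx$kg, sigs,
                                stats::setNames(list(fx$disease_sig),
                                                fx$disease_id),
                                reasoning_config(max_errors = 0)),
    "pubchem.compound:999")
  expect_equal(ranking$skipped, "pubchem.compound:999")
  expect_equal(nrow(ranking$table), 1)
  expect_true(ranking$table$prioritized[1])

  expect_error(prioritize_pairs(fx$kg, list(), list()), "at least one")
})

test_that("target mode ranks the planted upstream regulator first", {
  # one regulator R feeding 5 concordant 2-edge paths R -> Ai -> disease;
  # a competitor protein Q with a single path.
  A <- paste0("A", 1:5)
  nodes <- data.frame(id = c("R", "Q", A, "dis"),
                      kind = c(rep("protein", 7), "disease"))
  edges <- rbind(
    data.frame(source = "R", target = A, sign = c(1, -1, 1, -1, 1)),
    data.frame(source = A, target = "dis", sign = -1),
    data.frame(source = "Q", target = A[1], sign = 1))
  kg <- causal_kg(nodes, edges)
  # disease signature matching R's propagated signs exactly
  sig <- causal_signature(stats::setNames(c(1L, -1L, 1L, -1L, 1L), A),
                          context = "disease", context_id = "dis")
  rk <- prioritize_targets(kg, "dis", sig, reasoning_config(max_errors = 0))
  expect_equal(rk$table$protein_id[1], "R")
  expect_equal(rk$table$n_concordant[1], 5)
  # nodes in R's concordant paths: R, A1..A5, dis
  expect_equal(rk$table$n_nodes_concordant[1], 7)
  expect_true(all(rk$table$n_concordant[-1] <= 1))

  # disease with no incoming paths of length >= 2
  lonely <- causal_kg(data.frame(id = c("P", "dis2"),
                                 kind = c("protein", "disease")),
                      data.frame(source = "P", target = "dis2", sign = 1))
  rk0 <- prioritize_targets(lonely, "dis2",
                            causal_signature(integer(0), context = "disease"))
  expect_equal(nrow(rk0$table), 0)

  expect_error(prioritize_targets(kg, "nope", sig), "disease")
})

test_that("target-mode counts equal per-protein brute-force enumeration", {
  kg <- random_typed_kg(n_chem = 1, n_prot = 7, n_dis = 1, p_edge = 0.35,
                        seed = 43)
  set.seed(44)
  prots <- kg$nodes$id[kg$nodes$kind == "protein"]
  sig <- causal_signature(
    stats::setNames(sample(c(-1L, 0L, 1L), length(prots), TRUE), prots),
    context = "disease", context_id = "d:1")
  cfg <- reasoning_config(lmax = 5, max_errors = 1)
  rk <- prioritize_targets(kg, "d:1", sig, cfg)
  for (p in prots) {
    keys <- oracle_paths_igraph(kg, p, "d:1", lmax = 5)
    n_conc <- 0
    for (key in keys) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      nodes <- strsplit(parts[1], ">", fixed = TRUE)[[1]]
      signs <- as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]])
      interior <- nodes[-c(1, length(nodes))]
      inferred <- cumprod(signs)[seq_along(interior)]
      vals <- unname(sig$values[interior])
      if (oracle_count_errors(inferred, vals, +1) <= 1) n_conc <- n_conc + 1
    }
    got <- rk$table$n_concordant[rk$table$protein_id == p]
    if (length(keys) == 0) {
      expect_length(got, 0)
    } else {
      expect_equal(got, n_conc, info = p)
    }
  }
})

test_that("mechanism subgraphs union the surviving paths with traversal counts", {
  fx <- worked_fixture()
  res <- is_drug_prioritized(fx$kg, fx$drug_id, fx$disease_id, fx$drug_sig,
                             fx$disease_sig, reasoning_config(max_errors = 0))
  sub <- extract_mechanism_subgraph(res, fx$kg)
  # one surviving 3-edge path: 4 nodes, 3 edges, all counts 1
  expect_equal(nrow(sub$nodes), 4)
  expect_equal(nrow(sub$edges), 3)
  expect_true(all(sub$edges$traversal_count == 1))
  expect_no_error(validate <- causal_kg(sub$nodes, sub$edges))

  # two paths sharing their last edge
  kg2 <- causal_kg(
    data.frame(id = c("D", "P1", "P2", "P3", "X"),
               kind = c("chemical", "protein", "protein", "protein", "disease")),
    data.frame(source = c("D", "D", "P1", "P2", "P3"),
               target = c("P1", "P2", "P3", "P3", "X"),
               sign = c(1, 1, 1, 1, -1)))
  dsig <- causal_signature(c(P1 = 1L, P2 = 1L, P3 = 1L), context = "drug")
  xsig <- causal_signature(c(P1 = -1L, P2 = -1L, P3 = -1L), context = "disease")
  res2 <- is_drug_prioritized(kg2, "D", "X", dsig, xsig,
                              reasoning_config(max_errors = 0))
  expect_equal(res2$n_surviving, 2)
  sub2 <- extract_mechanism_subgraph(res2, kg2)
  shared <- sub2$edges[sub2$edges$source == "P3" & sub2$edges$target == "X", ]
  expect_equal(shared$traversal_count, 2L)

  # node set equals the union of path node sets, across random results
  for (seed in 1:20) {
    bench <- generate_benchmark(synthetic_spec(
      n_chemicals = 3, n_proteins = 20, n_diseases = 2, n_planted_pairs = 2,
      seed = 600 + seed))
    pr <- bench$truth$planted_pairs
    d <- pr$drug_id[1]; x <- pr$disease_id[1]
    res <- is_drug_prioritized(bench$kg, d, x, bench$drug_sigs[[d]],
                               bench$disease_sigs[[x]],
                               reasoning_config(max_errors = 1))
    if (!res$prioritized) next
    sub <- extract_mechanism_subgraph(res, bench$kg)
    expect_setequal(sub$nodes$id,
                    unique(unlist(lapply(res$surviving_paths, `[[`, "nodes"))))
  }

  res_no <- res2; res_no$prioritized <- FALSE
  expect_error(extract_mechanism_subgraph(res_no, kg2), "not prioritized")
})

test_that("budget and length monotonicity hold on seeded benchmarks", {
  for (seed in 1:8) {
    bench <- generate_benchmark(synthetic_spec(
      n_chemicals = 4, n_proteins = 25, n_diseases = 3, n_planted_pairs = 2,
      signature_noise = 0.2, missingness = 0.1, certify_decoys = FALSE,
      seed = 700 + seed))
    sets_err <- lapply(0:2, function(k)
      prioritized_pair_keys(prioritize_pairs(
        bench$kg, bench$drug_sigs, bench$disease_sigs,
        reasoning_config(max_errors = k))))
    expect_true(all(sets_err[[1]] %in% sets_err[[2]]))
    expect_true(all(sets_err[[2]] %in% sets_err[[3]]))
    sets_len <- lapply(c(3, 5, 7), function(L)
      prioritized_pair_keys(prioritize_pairs(
        bench$kg, bench$drug_sigs, bench$disease_sigs,
        reasoning_config(lmax = L, max_errors = 1))))
    expect_true(all(sets_len[[1]] %in% sets_len[[2]]))
    expect_true(all(sets_len[[2]] %in% sets_len[[3]]))
  }
})
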