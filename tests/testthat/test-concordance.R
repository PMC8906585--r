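# The reference path for most checks: D -(-)-> P1 -(+)-> P2 -(-)-> P3 -(+)-> X,
# inferred regulation {P1: -1, P2: -1, P3: +1}.
ref_path <- function() causal_path(c("D", "P1", "P2", "P3", "X"), c(-1, 1, -1, 1))

dsig <- function(...) causal_signature(c(...), context = "drug")
xsig <- function(...) causal_signature(c(...), context = "disease")

test_that("concordance counts signature errors along the path", {
  p <- ref_path()
  cfg0 <- reasoning_config(max_errors = 0)
  cfg1 <- reasoning_config(max_errors = 1)

  exact <- dsig(P1 = -1L, P2 = -1L, P3 = 1L)
  expect_equal(is_concordant(p, exact, cfg0), list(ok = TRUE, errors = 0L))

  one_off <- dsig(P1 = -1L, P2 = 1L, P3 = 1L)
  expect_equal(is_concordant(p, one_off, cfg1), list(ok = TRUE, errors = 1L))
  expect_false(is_concordant(p, one_off, cfg0)$ok)

  # unmeasured genes are errors too
  sparse <- dsig(P1 = -1L)
  expect_equal(is_concordant(p, sparse, cfg1), list(ok = FALSE, errors = 2L))
})

test_that("anti-correlation requires the negated inferred signs", {
  p <- ref_path()
  cfg0 <- reasoning_config(max_errors = 0)
  cfg1 <- reasoning_config(max_errors = 1)

  negated <- xsig(P1 = 1L, P2 = 1L, P3 = -1L)
  expect_equal(is_anti_correlated(p, negated, cfg0),
               list(ok = TRUE, errors = 0L))

  same_as_drug <- xsig(P1 = -1L, P2 = -1L, P3 = 1L)
  expect_equal(is_anti_correlated(p, same_as_drug, cfg1),
               list(ok = FALSE, errors = 3L))
})

test_that("a measured zero can be a silent pass when configured", {
  p <- ref_path()
  with_zero <- dsig(P1 = -1L, P2 = 0L, P3 = 1L)
  strict <- reasoning_config(max_errors = 0, treat_zero_as_error = TRUE)
  lax <- reasoning_config(max_errors = 0, treat_zero_as_error = FALSE)
  expect_equal(is_concordant(p, with_zero, strict)$errors, 1L)
  expect_equal(is_concordant(p, with_zero, lax)$errors, 0L)
})

test_that("error counts match the brute-force counter over all states", {
  # every inferred-sign x signature-state combination for 1..3 proteins
  states <- c(-1L, 0L, 1L, NA_integer_)  # NA = unmeasured
  for (k in 1:3) {
    sign_grid <- expand.grid(rep(list(c(-1L, 1L)), k))
    state_grid <- expand.grid(rep(list(states), k))
    for (i in seq_len(nrow(sign_grid))) {
      inferred <- unlist(sign_grid[i, ])
      # build a path realizing this inferred sequence: edge j sign =
      # inferred_j / inferred_{j-1}
      edge_signs <- c(inferred[1], if (k > 1) inferred[-1] / inferred[-k], 1L)
      p <- causal_path(c("D", paste0("P", 1:k), "X"), edge_signs)
      expect_equal(unname(infer_regulation(p)), unname(inferred))
      for (j in seq_len(nrow(state_grid))) {
        vals <- unlist(state_grid[j, ])
        named <- stats::setNames(vals[!is.na(vals)],
                                 paste0("P", 1:k)[!is.na(vals)])
        sig <- causal_signature(named, context = "drug")
        cfg <- reasoning_config(max_errors = 1)
        expect_equal(is_concordant(p, sig, cfg)$errors,
                     oracle_count_errors(inferred, vals, +1))
        expect_equal(is_anti_correlated(p, sig, cfg)$errors,
                     oracle_count_errors(inferred, vals, -1))
      }
    }
  }
})

test_that("anti-correlation equals concordance on the sign-negated path", {
  set.seed(31)
  for (i in 1:100) {
    len <- sample(2:6, 1)
    signs <- sample(c(-1L, 1L), len, replace = TRUE)
    nodes <- c("D", paste0("P", seq_len(len - 1)), "X")
    p <- causal_path(nodes, signs)
    neg <- signs
    neg[1] <- -neg[1]  # negating the first edge negates every inferred sign
    p_neg <- causal_path(nodes, neg)
    vals <- sample(c(-1L, 0L, 1L), len - 1, replace = TRUE)
    sig <- causal_signature(stats::setNames(vals, nodes[2:len]),
                            context = "disease")
    cfg <- reasoning_config(max_errors = 1)
    expect_equal(is_anti_correlated(p, sig, cfg)$errors,
                 is_concordant(p_neg,
                               causal_signature(sig$values, context = "drug"),
                               cfg)$errors)
  }
})

test_that("the three-step decision prioritizes the fixture pair", {
  fx <- worked_fixture()
  res <- is_drug_prioritized(fx$kg, fx$drug_id, fx$disease_id,
                             fx$drug_sig, fx$disease_sig,
                             reasoning_config(max_errors = 0))
  expect_true(res$prioritized)
  expect_equal(res$n_paths_total, 2)
  expect_equal(res$n_inhibiting, 1)  # the 4-edge path net-activates X
  expect_gte(res$n_surviving, 1)
  expect_true(res$n_surviving <= res$n_concordant)
  expect_true(res$n_concordant <= res$n_paths_total)

  # disease signature equal to the drug signature: anti-correlation fails
  same <- causal_signature(fx$drug_sig$values, context = "disease",
                           context_id = fx$disease_id)
  res2 <- is_drug_prioritized(fx$kg, fx$drug_id, fx$disease_id,
                              fx$drug_sig, same)
  expect_false(res2$prioritized)

  expect_error(
    is_drug_prioritized(fx$kg, "ncbigene:1", fx$disease_id, fx$drug_sig,
                        fx$disease_sig),
    "chemical")
  wrong <- causal_signature(fx$drug_sig$values, context = "disease")
  expect_error(
    is_drug_prioritized(fx$kg, fx$drug_id, fx$disease_id, wrong,
                        fx$disease_sig),
    "context")
})

test_that("planted pairs pass and scrambled decoys fail across random KGs", {
  for (seed in 1:10) {
    bench <- generate_benchmark(synthetic_spec(
      n_chemicals = 4, n_proteins = 25, n_diseases = 3, n_planted_pairs = 2,
      seed = 500 + seed))
    cfg <- reasoning_config(max_errors = 0)
    for (r in seq_len(nrow(bench$truth$planted_pairs))) {
      d <- bench$truth$planted_pairs$drug_id[r]
      x <- bench$truth$planted_pairs$disease_id[r]
      expect_true(is_drug_prioritized(bench$kg, d, x, bench$drug_sigs[[d]],
                                      bench$disease_sigs[[x]], cfg)$prioritized,
                  info = sprintf("seed %d pair %s|%s", seed, d, x))
      # fully scrambled drug signature: every on-path value contradicted
      planted <- bench$truth$planted_paths[[paste(d, x, sep = "|")]]
      flipped <- bench$drug_sigs[[d]]
      flipped$values[names(planted$inferred)] <- -planted$inferred
      expect_false(is_drug_prioritized(bench$kg, d, x, flipped,
                                       bench$disease_sigs[[x]],
                                       cfg)$prioritized)
    }
  }
})
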