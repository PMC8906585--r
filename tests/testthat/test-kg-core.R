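test_that("TSV edge lists parse into validated graphs", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "source_id\tsource_kind\trelation\ttarget_id\ttarget_kind",
    "# a comment line",
    "chem:a\tchemical\tinhibits\tprot:1\tprotein",
    "prot:1\tprotein\tactivates\tprot:2\tprotein",
    "prot:2\tprotein\tactivates\tprot:3\tprotein",
    "prot:3\tprotein\tactivates\tdis:x\tdisease"), path)
  kg <- load_kg(path, quiet = TRUE)
  expect_equal(nrow(kg$nodes), 5)
  expect_equal(nrow(kg$edges), 4)
  expect_equal(sum(kg$edges$sign == -1), 1)

  # header-only file: a valid empty graph
  empty <- tempfile(fileext = ".tsv")
  writeLines("source_id\tsource_kind\trelation\ttarget_id\ttarget_kind", empty)
  kg0 <- load_kg(empty, quiet = TRUE)
  expect_equal(nrow(kg0$nodes), 0)
  expect_equal(nrow(kg0$edges), 0)

  expect_error(load_kg(tempfile()), "no such file")
})

test_that("disallowed rows abort strict loads and are skipped leniently", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "source_id\tsource_kind\trelation\ttarget_id\ttarget_kind",
    "mondo:1\tdisease\tactivates\tncbigene:2\tprotein",
    "chem:a\tchemical\tactivates\tprot:1\tprotein",
    "prot:1\tprotein\tfrobnicates\tprot:2\tprotein"), path)
  expect_error(load_kg(path, quiet = TRUE), "line 2.*disallowed kinds")
  kg <- load_kg(path, mode = "lenient", quiet = TRUE)
  expect_equal(nrow(kg$edges), 1)
  rej <- attr(kg, "rejected")
  expect_equal(rej$line, c(2L, 4L))
  expect_match(rej$reason[2], "unknown relation")
})

test_that("constructor enforces the typed-edge invariants", {
  nodes <- data.frame(id = c("c:1", "p:1", "d:1"),
                      kind = c("chemical", "protein", "disease"))
  expect_error(
    causal_kg(nodes, data.frame(source = "p:1", target = "p:1", sign = 1)),
    "self-edges")
  expect_error(
    causal_kg(nodes, data.frame(source = "c:1", target = "d:1", sign = 1)),
    "disallowed kind pair")
  expect_error(
    causal_kg(nodes, data.frame(source = "c:1", target = "p:1", sign = 0)),
    "signs")
  expect_error(
    causal_kg(nodes, data.frame(source = "c:1", target = "p:9", sign = 1)),
    "absent")
  # duplicate (source, target, sign) rows collapse; opposite signs stay
  kg <- causal_kg(nodes, data.frame(source = c("c:1", "c:1", "c:1"),
                                    target = "p:1", sign = c(1, 1, -1)))
  expect_equal(nrow(kg$edges), 2)
})

test_that("write/load round trip preserves the exact signed edge multiset", {
  fx <- worked_fixture()
  kgs <- list(
    fixture = fx$kg,
    parallel = causal_kg(
      nodes = data.frame(id = c("p:1", "p:2"), kind = "protein"),
      edges = data.frame(source = "p:1", target = "p:2", sign = c(1, -1))),
    empty = causal_kg(nodes = data.frame(id = "p:1", kind = "protein"),
                      edges = data.frame(source = character(0),
                                         target = character(0),
                                         sign = integer(0))))
  for (dialect in c("tsv", "graphml")) {
    for (kg in kgs) {
      path <- tempfile()
      write_kg(kg, path, dialect)
      back <- load_kg(path, dialect, quiet = TRUE)
      expect_equal(back$edges[, c("source", "target", "sign")],
                   kg$edges[, c("source", "target", "sign")])
      if (nrow(kg$edges) > 0) {
        # the TSV edge list cannot carry isolated nodes, so node sets are
        # only guaranteed for graphs where every node touches an edge
        expect_setequal(paste(back$nodes$id, back$nodes$kind),
                        paste(kg$nodes$id, kg$nodes$kind))
      }
      # strict re-load of our own output never raises
      expect_no_error(load_kg(path, dialect, mode = "strict", quiet = TRUE))
    }
  }
})

test_that("kg_stats counts nodes, strata and degrees consistently", {
  fx <- worked_fixture()
  # 4-edge sub-fixture (without the D->P2 shortcut)
  sub <- causal_kg(fx$kg$nodes,
                   fx$kg$edges[!(fx$kg$edges$source == fx$drug_id &
                                   fx$kg$edges$target == "ncbigene:2"), ])
  st <- kg_stats(sub)
  expect_equal(unname(st$nodes_per_kind),
               c(1L, 3L, 1L))  # chemical, protein, disease
  agg <- stats::aggregate(n ~ source_kind + target_kind, st$edge_strata, sum)
  expect_equal(agg$n[agg$source_kind == "chemical"], 1L)
  expect_equal(agg$n[agg$source_kind == "protein" &
                       agg$target_kind == "protein"], 2L)
  expect_equal(agg$n[agg$target_kind == "disease"], 1L)
  expect_equal(sum(st$edge_strata$n[st$edge_strata$sign == -1]), 2L)

  # full 5-edge fixture
  st5 <- kg_stats(fx$kg)
  expect_equal(sum(st5$nodes_per_kind), nrow(fx$kg$nodes))
  expect_equal(sum(st5$edge_strata$n), nrow(fx$kg$edges))
  expect_equal(sum(st5$degrees$in_degree), nrow(fx$kg$edges))
  expect_equal(sum(st5$degrees$out_degree), nrow(fx$kg$edges))

  empty <- causal_kg(nodes = data.frame(id = character(0), kind = character(0)),
                     edges = data.frame(source = character(0),
                                        target = character(0),
                                        sign = integer(0)))
  st0 <- kg_stats(empty)
  expect_equal(sum(st0$nodes_per_kind), 0L)
  expect_equal(nrow(st0$edge_strata), 0L)
})
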