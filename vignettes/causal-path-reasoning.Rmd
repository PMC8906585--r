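---
title: "Signature-guided causal path reasoning: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-guided causal path reasoning: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalpaths)
```

## The problem and the model

Drug repurposing methods that work purely from network topology (shortest
paths, shared neighbours) cannot distinguish a mechanism that would *revert*
a disease from one that would aggravate it, and they ignore whether the
mechanism is actually active in the relevant biological context.
`causalpaths` combines two complementary sources of evidence:

1. **Prior knowledge**: a causal knowledge graph (KG) whose nodes are
   chemicals, proteins and diseases, and whose directed edges assert
   activation (+1) or inhibition (−1). Only three edge types exist —
   chemical→protein (a drug perturbs its target), protein→protein
   (signalling), protein→disease (a protein modifies the phenotype) — so
   every path from a drug to a disease has the shape of a plausible
   mechanism of action: target engagement, a signalling cascade, a
   phenotype effect.
2. **Context-specific data**: binarized transcriptomic signatures, one from
   a perturbation experiment with the drug (which genes went up or down
   when cells were treated) and one from the disease state (which genes are
   dysregulated in patients or disease models).

For a node-simple path $c \to p_1 \to \dots \to p_k \to d$ with edge signs
$s_1, \dots, s_{k+1} \in \{-1,+1\}$, the *inferred regulation* of protein
$p_i$ is $r_i = \prod_{j \le i} s_j$ — the direction the path predicts that
protein moves when the drug is applied — and the *cumulative effect* on the
disease is $\prod_j s_j$. A path is retained as a mechanism hypothesis when

- **(concordance)** the drug signature agrees with $r_i$ at the interior
  proteins, within an error budget;
- **(anti-correlation)** the disease signature agrees with $-r_i$, within
  the same per-check budget — the disease state should show the *opposite*
  of what the drug does; and
- **(reversion)** optionally, the cumulative effect on the disease is −1.

A drug–disease pair is *prioritized* when at least one path survives all
checks; the union of surviving paths is the proposed mechanism-of-action
subgraph, with per-edge traversal counts marking its load-bearing steps.

An *error* at a protein is any of: the gene is unmeasured, it is measured
but unchanged (call 0), or its call contradicts the inferred sign.
Transcriptomic panels cover only a fraction of KG proteins, the
fold-change cutoff is arbitrary near the threshold, and some causal edges
act post-transcriptionally (e.g. phosphorylation), so demanding perfection
would eliminate essentially all paths; allowing many errors lets paths pass
on missingness alone. One error per check is the compromise used as the
default.

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `lmax` | 7 edges | longest path considered; longer chains are assumed biologically diffuse. Both drug and target mode use the same bound. |
| `max_errors` | 1 per check | error budget applied separately inside the concordance and the anti-correlation check. The two checks are separate functions with separate evidence (drug vs. disease experiment); a shared budget can be emulated by setting 0. |
| `require_disease_inhibition` | `TRUE` | surviving paths must net-inhibit the disease: a therapeutic mechanism reverts the phenotype. Exposed as a flag because the two signature checks alone are sometimes of interest. |
| `treat_zero_as_error` | `TRUE` | a measured-but-unchanged gene supplies no supporting direction, so it counts like an unmeasured one. Turning it off makes 0 a silent pass. |
| `fc_cutoff` | 1 (|log2FC|) | binarization cutoff, inclusive at the boundary; 1 (two-fold) retains more dysregulated genes than stricter cutoffs and is the conventional choice. An exact zero fold change is never called dysregulated, even at cutoff 0. |

Minimum path length is 2 edges: a direct chemical→disease edge type does
not exist in the data model, and in target mode a length-1 protein→disease
path would contain no scorable protein and be trivially "concordant".

## Target prioritization (reverse mode)

`prioritize_targets()` asks the converse question: which proteins are
plausible upstream regulators of an observed disease signature? Paths
`protein -> ... -> disease` up to `lmax` edges are enumerated by walking
in-edges backwards from the disease. The start protein is the perturbation
*hypothesis* — assumed active, carrying the empty sign product +1 — and is
deliberately not scored against the signature; the interior proteins are
scored with **direct** sign matching, because an upstream driver explains
the disease signature rather than opposing it. Proteins are ranked by the
number of concordant paths, with the number of distinct nodes in those
paths reported as a measure of mechanism breadth. This mode is much more
expensive than drug mode: it enumerates paths from every protein rather
than from a handful of chemicals.

## What the synthetic generator emulates

`generate_benchmark()` stands in for the external inputs (curated KGs,
perturbation compendia, clinical-trial labels) so that every claim the
package makes is testable offline:

- **Background KG**: stratified Bernoulli edge sampling with sparse
  defaults (chemical→protein 0.03, protein→protein 0.015, protein→disease
  0.04, 30% inhibitory). Protein branching is kept sub-critical so path
  counts between random pairs stay small and biologically plausible.
- **Planted mechanisms**: for each planted drug–disease pair one guaranteed
  path of `planted_path_length` edges (default 4) whose cumulative effect
  is −1, with globally disjoint intermediate proteins. By default
  (`isolate_planted = TRUE`) planted chemicals receive no background
  out-edges and planted diseases no background in-edges — the planted
  chemical behaves like a selective probe — which has the useful
  consequence that *every* path of a planted pair passes through the
  planted entry and exit proteins. Full sign-flip noise therefore forces at
  least two errors on every such path, making the noise ablation an exact
  construction guarantee rather than a probabilistic one.
- **Signatures**: on-path proteins carry their inferred signs (drug) or the
  negated signs (disease); all other proteins draw i.i.d. from
  {−1, 0, +1} with probabilities 0.15/0.70/0.15, loosely emulating the
  call rate of a |log2FC| ≥ 1 cutoff. Noise flips and/or zeroes planted
  values (the two failure modes of the error definition, separable via
  `noise_mode`); missingness removes genes entirely, so the measured
  fraction of KG proteins is 1 − missingness in expectation.
- **Decoy certification** (`certify_decoys = TRUE`): after signature
  generation, background values are zeroed until no non-planted pair
  retains a surviving path at `certify_max_errors` (default 0). Zeroing
  only ever *adds* errors, so the procedure terminates, never revives a
  path, and never touches a planted on-path value (planted intermediate
  sets are disjoint, so every offending path has an interior protein that
  is background for at least one of the two signatures). This makes
  "precision 1.0 against planted labels at a zero error budget" a property
  of the construction, not of a lucky seed.

What the generator does **not** emulate: the degree distributions and scale
of real curated KGs, correlated measurement noise across genes, platform
effects, or raw expression counts (only binarized calls). Passing the
planted-recovery tests therefore demonstrates algorithmic correctness —
that the method recovers exactly the signal it is designed to detect and
nothing under its nulls — not clinical performance on real data.

## Numerical and determinism choices

- The reasoning core contains no randomness. Path enumeration is
  depth-first with children visited in radix-sorted (byte) order, so output
  is lexicographic by node sequence and byte-identical across runs; ranked
  tables break ties by surviving-path fraction and then pair id.
- Parallel contradictory edges (A activates B *and* A inhibits B) are kept
  as two distinct edges and yield distinct paths: aggregated KGs carry
  conflicting assertions, and collapsing them would silently discard
  mechanism hypotheses. Self-edges are rejected at load (they can only
  create cycles, which the path definition excludes).
- The TSV edge-list format carries nodes only through their edges; isolated
  nodes survive a round trip only in the GraphML dialect.
- XSwap permutation operates within each (source-kind, target-kind)
  stratum, exchanging the targets of two edges with signs travelling on the
  source stub; swaps that would create a self-edge or duplicate a
  (source, target, sign) triple are rejected rather than retried, the
  standard rejection scheme that keeps every node's in/out degree exact.
  Strata with fewer than two edges are left untouched. Signature
  permutation shuffles values over the same gene key set, preserving the
  value multiset exactly. Empirical p-values use the add-one estimator
  `(1 + #{null >= observed}) / (1 + n)`, which cannot report zero.
- Degenerate inputs: an empty prioritized set has undefined (`NA`)
  precision rather than 0; an empty candidate set is an error; a disease
  with no incoming paths yields an empty target ranking.
- All seeded randomness flows through one helper that saves and restores
  the caller's RNG state, so library calls never perturb user code.

## Problem sizes used in the test suite

The default benchmark (10 chemicals, 60 proteins, 5 diseases, 5 planted
pairs) evaluates 50 drug–disease combinations in well under a second;
the property suites use 200 random small graphs for the enumeration oracle,
50 seeded benchmarks for monotonicity, and 20-replicate permutation nulls.
These sizes were chosen to exercise every code path with exhaustive or
independent oracles (igraph's simple-path enumerator, brute-force tuple
generation, hand-rolled error counters) while keeping a full run of the
suite in the low minutes.

## Known limitations

- Only three node kinds and three edge types are modelled; other modalities
  (metabolites, phenotypic readouts) would need a schema extension.
- Evidence is binarized; effect sizes and p-values beyond the cutoff do not
  influence ranking.
- The per-check error budget treats "unmeasured" and "contradicted"
  identically; with very sparse panels, paths can survive mostly on
  missingness at larger budgets — the reason the default budget is 1.
- Target mode scores a single activation hypothesis per start protein; a
  down-regulated regulator is captured only insofar as its paths' signs
  propagate that information.
- The two proximity baselines are generic topology scores provided for
  harness comparison, not reimplementations of any published benchmark
  suite.
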