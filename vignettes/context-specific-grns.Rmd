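---
title: "Contextualizing gene regulatory networks with epigenomic evidence filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextualizing gene regulatory networks with epigenomic evidence filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigrn)
```

## The model

A *reference* gene regulatory network (GRN) collects every known or
possible regulation in an organism, regardless of developmental stage,
tissue or condition. epigrn builds one from transcription factor binding
sites (TFBSs): a TF is assigned to the regulation of every gene whose
transcription start site (TSS) lies within a distance threshold `d`
downstream of one of the TF's binding sites — operationally, the TFBS must
overlap the strand-aware upstream promoter window of the gene. Curated
miRNA→target pairs are merged in as a second edge kind. Such a network
over-predicts on purpose: it is the union of regulations over all contexts.

Condition specificity comes from a cascade of knowledge-based filters,
each consuming one kind of experimental evidence generated *in the
condition of interest*:

1. **DNA methylation** — a methylated TFBS is assumed unavailable for TF
   binding; an edge falls only when *all* of its supporting TFBSs are
   methylated.
2. **Chromatin accessibility** — an edge survives if open chromatin (e.g.
   a DNase-seq peak) is observed within the target's `d`-window.
3. **Histone marks** — each mark type is classed *active* (permits TF
   binding) or *repressive*. An edge survives if at least one active mark
   overlaps one of its TFBSs; each distinct active mark type adds +1 to
   the edge weight. Repressive marks never credit.
4. **Regulator expression** — out-edges of TFs whose gene is not expressed
   are removed. This is the tool's minimum input: with expression alone
   the output is still a meaningful context network.
5. **miRNA abundance** — the same rule for miRNA→target edges.

Each surviving edge's integer **weight** is the number of filter
identifiers it was credited: with expression data only, every edge has
weight 1; one supporting active mark raises it to 2; and with methylation
and accessibility tracks also supplied the weight of an edge supported by
`k` active mark types is `3 + k`. Thresholding the weighted network trades
recall for (slightly) higher precision.

Two properties are worth stating precisely because the implementation
leans on them:

* **Filters are conjunctive vetoes over immutable evidence.** A filter
  never edits the TFBS evidence that later filters see; it only drops
  edges and records credits. The surviving edge *set* is therefore
  invariant to filter order (the cascade order only affects which filter
  is blamed in the removal report), and the test suite asserts this over
  all 120 permutations of the five filters.
* **Evidence monotonicity.** Adding an active-mark peak can only keep or
  credit edges; adding a methylation peak can only remove them. This is
  what makes the weights interpretable as accumulated support.

## Benchmarking

A **gold standard** is built from per-TF ChIP-seq occupancy: the
reference is restricted to the assayed TFs, and an edge is kept only if
one of its TFBSs overlaps (≥ 1 bp) a ChIP peak of the same TF. Before
comparison, predicted networks are restricted to the gold standard's
regulator set so that false positives measure occupancy disagreement,
not regulator coverage.

Comparison treats network membership as binary classification, at two
granularities:

* **Edges** keyed by (regulator, target, kind), with
  `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`.
* **Graphlets**: directed three-node induced subgraphs (triads). An
  instance is an unordered node triple whose induced subgraph, ignoring
  self-loops, is weakly connected, together with its isomorphism class
  (one of the standard 13 connected triad classes, labelled 021D … 300).
  A triple whose class changes between two networks is a different
  instance in each, so it counts as one FP plus one FN. Restricting the
  instance universe to those containing one node gives a per-node local
  topology F1; nodes are then binned into the intervals [0, 0.5),
  [0.5, 0.7), [0.7, 0.9) and [0.9, 1.0] by gene type (TFs, non-TF coding
  genes, non-coding genes — miRNAs counted with the latter).

Triad classification uses a canonical 6-bit arc code minimized over the
six node permutations, with the class-name table constructed at install
time from explicit representatives and verified exhaustively (all 64 arc
configurations on an ordered triple; mutual non-isomorphism is
cross-checked against igraph in the test suite). Enumeration is
edge-anchored — every connected triple contains a node adjacent to the
other two, so expanding each arc by its endpoints' neighbourhoods visits
every instance without scanning all `n^3` triples.

## Parameters that matter

| parameter | default | notes |
|---|---|---|
| `d` (nt) | none; 1500, 2000 and 5000 are the conventional choices | window size for TFBS→gene assignment and the accessibility filter; edge sets are nested in `d` |
| window side | upstream only | downstream TFBSs are never assigned; known regulations driven by downstream or distal (8–20 kb) sites are invisible at these thresholds |
| overlap rule | ≥ 1 bp | `contained = TRUE` requires the TFBS fully inside the window |
| `expression_threshold` | 0, strict `>` | abundance units are taken as provided (counts, RPKM, FPKM); regulators absent from the table count as not expressed |
| `mark_effects` | 13 marks, see `default_mark_effects()` | e.g. H3K4me3 active, H3K27me3/H3K9me2/H3K9me3/H4K20me3 repressive; extensible to custom marks |
| `repressive_policy` | `veto_if_no_active` | mixed active+repressive evidence keeps the edge and credits only the actives; `always_veto` removes on any repressive mark |
| `accessibility_scope` | `window` | `tfbs` instead requires the open-chromatin peak to overlap the binding site itself |

Choices the data did not dictate, made once and kept: BED-style 0-based
half-open coordinates everywhere (GTF/GFF3 converted on read); exact
chromosome-name matching with no "chr" aliasing; overlapping peaks within
a track are not merged (any-overlap semantics make merging a no-op);
exact-coordinate duplicate TFBSs per TF are deduplicated; methylation and
accessibility credit +1 like every other passed filter; degenerate metric
denominators yield 0 with an explicit flag rather than NaN; reported
metrics are rounded to 3 decimals (round-half-even) while internal values
stay at full precision.

## What the synthetic fixtures emulate — and what they do not

`generate_fixture()` builds a toy genome in which genes are spaced so
their promoter windows do not overlap, and every piece of evidence is
planted to produce a known outcome: the expected reference edge set, the
surviving edge set *with weights*, per-filter removal counts and the
ChIP-occupancy gold standard are all computed from the planting plan, not
by running the pipeline. The `mixed` scenario routes edges through eight
distinct fates (pass with one or two marks, methylated, closed promoter,
repressive-only, no marks, mixed marks, silent regulator) and silences
one miRNA; `overlapping_promoters` checks that one TFBS in shared
upstream sequence yields two edges; `generate_timeseries_fixture()`
rewires a fixed fraction of edges per time step with exact TP/FP/FN
bookkeeping. Fixture sizes default to 16 genes (3 TFs, 2 miRNAs) and the
test suite uses 50 random digraphs of up to 20 nodes for the triad
oracle — sizes chosen so each property is exercised in well under a
second while every code path (both strands, shared windows, every filter
fate) is hit.

Passing these tests shows the machinery is exact on its own semantics.
It does *not* show that real peak calls are clean, that the mark-effect
table is right for a given tissue, that expression of a regulator's gene
is a good proxy for regulator activity (maternally deposited proteins are
a known counterexample in early embryos), or that promoter-window
assignment captures enhancer-mediated regulation — those are properties
of the biology and the upstream data, not of this implementation.

## Known limitations

* Regulation through distal enhancers and downstream-proximal TFBSs is
  out of reach of the distance rule by construction.
* The mark-effect table is a coarse binary summary of a combinatorial
  epigenetic code; contradictory marks at one site are resolved by policy,
  not learned.
* Filters are binary (any peak counts, signal strength ignored) — BED
  scores are stored but never thresholded.
* Graphlets are limited to triads; larger graphlets and orbit signatures
  are out of scope.
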