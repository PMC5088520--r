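---
title: "From pathway charts to expression-specific protein networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pathway charts to expression-specific protein networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathexnet)
```

## The problem and the model

Curated pathway databases describe signalling as charts: boxes that may
bundle several paralogous proteins, and typed links (activation,
inhibition, expression, phosphorylation, ...) between boxes. pathexnet
turns a corpus of such charts (KGML files) into analyzable protein
networks and asks a context question of them: *which part of this
pathway is actually expressed in a given cell type?*

The transformation makes three modelling commitments.

**Proteins, not boxes.** The unit of the network is the UniProt
accession. A KGML entry naming *k* genes becomes *k* protein nodes, and
a relation between entries with *m* and *n* mapped accessions becomes
*m × n* candidate edges. KGML `group` entries (complexes) are fanned
out over their components first. This follows the convention that a
pathway box shows all the distinct proteins it contains; no selection
among paralogs is attempted, because pathway charts give no rule for
one. Self-pairs arising when two entries share an accession are
dropped, and pairs are stored unordered in lexicographic order.

**Undirected, categorised edges.** Edges are undirected to keep the
networks amenable to standard graph analysis. The many KGML subtype
names collapse onto four display categories — activation; inhibition
(including repression); expression; everything else, or a missing
subtype, is *other*. A relation carrying several subtypes takes a
single category by the precedence activation > inhibition > expression
> other; the same precedence picks the display category when parallel
relations of different categories merge into one edge. The precedence
is a documented convention, not biology: the source format defines no
tie rule.

**Two scopes.** The *local* network is exactly the canonical pathway.
The *global* network adds every relation in the whole corpus that
touches a local protein, plus the external endpoints of those
relations. Expansion is deliberately one hop: external nodes' own
further neighbours are not pulled in, because transitive closure would
reconstruct the entire interactome and defeat the purpose of a
pathway-centred view. Relations through small compounds (`PCrel`) and
chart-to-chart `maplink` links contribute no protein pairs; no
defensible protein-pair semantics exists for them.

The deduplicated corpus lives in two indexed tables — one row per
protein, one row per (unordered pair, category) with the union of
contributing pathways and raw subtypes — serialized as a portable SQL
dump plus canonical TSV exports. An embedded, file-based store replaces
a client–server database deliberately: it makes builds reproducible
and testable with zero configuration, and the dump remains loadable by
any SQL engine.

## Expression overlay

Expression enters as a gene-or-accession × context score table. For
barcode-style resources the score is the fraction of samples of a
context in which the gene is called expressed against its own
unexpressed reference distribution: sample *x* counts as expressed when
\((x - \mu)/\sigma > z\). The overlay then assigns each network node
one of three states:

* **ON** — score strictly greater than the threshold,
* **OFF** — score less than or equal to the threshold,
* **NA** — the protein (and all of its mapped gene ids) is absent from
  the resource, i.e. not measurable on the platform.

Filtering removes OFF nodes with their incident edges. NA nodes are
**retained**: absence of measurement is not evidence of absence, and
removing them would silently disconnect measurable neighbourhoods.

Parameters that matter:

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.4 | ON/OFF cut on the score; strict `>` for ON. Exposed everywhere; 0.4 is the conventional barcode-fraction operating point for calling a gene present. For FPKM/EST resources there is **no** default — an absolute threshold must be supplied, since a defensible universal cut does not exist for abundance units. |
| `z_cutoff` | 5.0 | z-score above the unexpressed null at which a single sample counts as expressed. Identifying expression thresholds is genuinely hard; 5 is conservative (false-positive calls are rare under the null) and the value is plain configuration, not a claim. |
| `combine` | `"max"` | when several gene-level rows map to one accession: maximum preserves "any evidence of expression"; `"mean"` is available for a stricter reading. |

The strict inequality is load-bearing: a score exactly at the
threshold is OFF. The fixture generator can plant exact-threshold
scores (`boundary_scores = TRUE`) to exercise precisely this edge.

Identifier unification collapses dash-suffixed isoform accessions to
their canonical stem — an interpretation, flagged as such: isoform-level
expression is rarely resolvable in the gene-level resources consumed
here, and keeping isoforms would fragment nodes arbitrarily. Mapping is
otherwise taken as authoritative and many-to-many: one gene id mapping
to *k* accessions yields *k* nodes.

## Topology

Metrics are computed on the undirected simple graph: degree;
betweenness as unnormalized shortest-path counting with even split
across equal-length paths (a `normalized` flag divides by the pair
count); local clustering coefficient with nodes of degree < 2 set to 0;
eigenvector centrality computed per connected component and scaled to
max 1 within each component, isolated nodes 0. Per-component
computation is a choice: the global eigenvector of a disconnected graph
concentrates all mass on the densest component and reports
uninformative zeros elsewhere. Hub selection ranks by degree with
accession as tie-break, so results are deterministic; top-*k* clamps to
the node count, and the quantile rule takes nodes at or above the
requested degree quantile. The betweenness and clustering
implementations are cross-checked in the test suite against a
brute-force oracle (explicit simple-path enumeration and direct
triangle counting) on hundreds of small random graphs.

## What the synthetic fixtures do and do not establish

`generate_corpus()` writes a complete miniature world: KGML files with
multi-gene entries, group-free gene boxes, one compound and one map
entry per pathway (whose relations must be ignored downstream), a
KEGG→UniProt mapping, a per-context score table, a PPI pair list with
decoys, and a `ground_truth.json` manifest of every count the pipeline
must reproduce — entries, relations, store rows, per-context ON/OFF/NA
and filtered node/edge counts. All randomness flows from one integer
seed through a locally scoped RNG, so corpora are byte-reproducible and
the global RNG stream is untouched.

Generator defaults state a small but structured world: 3 pathways of
8–16 genes, a 25 % chance that an entry is a 2–3-gene box, relation
density 0.25, 20 % cross-pathway protein sharing, 5 % of genes absent
from the platform, ON scores drawn from [0.45, 0.99] and OFF scores
from [0.01, 0.35] so that no score sits on the threshold unless
explicitly requested. The packaged `notch_like_fixture()` fixes the
shape of a receptor-signalling case study: 48 proteins in
paralog boxes, three contexts with nested ON sets (32 ON + 2 NA
B-cell-like; 24 and 22 ON T-cell-like), ligand-like proteins OFF in
every context, and one regulator scoring 1.00/0.41/0.17 to pin the
strict-threshold behaviour at a printed boundary value (0.41 → ON,
0.17 → OFF).

A green suite therefore establishes the *mechanics* — parsing fidelity,
expansion and deduplication arithmetic, threshold semantics, subgraph
relations, metric correctness — on inputs whose truth is known by
construction. It does not establish anything about real KEGG content or
real microarray data: real pathway releases change counts, real
expression requires platform-specific preprocessing (fRMA-style
normalization is out of scope; scores are consumed, not derived from
raw arrays), and the two-component expressed/unexpressed model does not
emulate realistic intensity distributions.

## Numerical and degenerate-input choices

* Parsing validates referentially: a relation naming a missing entry,
  or a group with an unresolvable component, is an error listing the
  offending ids; parse failures of individual corpus files are skipped
  with a warning so one broken file cannot poison a build.
* `expand_groups` is idempotent; serialize → re-parse round-trips the
  model exactly.
* Store builds are deterministic (canonically sorted tables, byte-identical
  exports) and idempotent under corpus duplication.
* Empty cases are defined, not accidental: a pathway with no relations
  is valid; an empty mapping file warns and yields an empty table; a
  store without relations dumps schema only; an unknown pathway id in a
  query warns and returns empty tables, while asking to *build* a
  network for one is an error naming the known ids.
* PPI evidence decorates existing edges by default and never changes
  the node set; union mode (`add_edges = TRUE`) adds PPI-only edges
  between existing nodes as category *other* with empty pathway
  provenance.
* Run configuration for the CLI is JSON with command-line override;
  every run writes a manifest with the tool version, option hash and
  input checksums.

## Known limitations

* KGML `reaction` elements, graphics coordinates and metabolic
  semantics are ignored; the networks are protein–protein, not
  metabolic.
* Directionality is discarded by design; analyses needing signed,
  directed signalling logic should not be run on these graphs.
* The simplified barcode caller assumes an externally supplied
  unexpressed reference (μ, σ) per gene and samples from a single
  context; it does not normalize arrays.
* Release-dependent magnitudes (how many proteins or interactions a
  real pathway yields) are properties of the input corpus, not of this
  package, and are intentionally never asserted.
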