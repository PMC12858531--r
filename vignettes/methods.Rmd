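---
title: "Methods: assembling, grouping and clustering CGPD tetramers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembling, grouping and clustering CGPD tetramers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgpdgroup)
```

## The model

The unit of evidence is the CGPD tetramer: a chemical *C* interacts
with a gene product *G*, is associated with a non-disease phenotype *P*
(a GO biological-process term) that is also annotated to *G*, and both
*C* and *G* are associated with a disease *D*. Five curated statements
back each tetramer: C–G, C–P, C–D and G–D interactions in the CTD dump
dialect, and a G–P annotation in gene2go format. The pipeline is a
filtered multi-way join, not an inference procedure: a tetramer exists
if and only if all five edges survive their filters. The working
assumption is that chemicals sharing many such blocks perturb similar
biology and are candidates for joint assessment; the package makes no
claim about effect direction or size, which the source data do not
carry.

Assembly proceeds in the order the data dictate. Step 1 compiles the
chemical universe from chemical–phenotype interactions (these carry
organism and anatomy annotation, so they anchor both filters). Step 2
collects chemical–gene interactions for those chemicals. Steps 3–4
collect chemical–disease and gene–disease edges, Step 5 joins them into
chemical–gene–disease triplets, Steps 6–7 attach phenotypes linked to
both the chemical and the gene. One open point in the workflow is
whether Step 3 should draw on chemicals surviving Step 1 or Step 2; we
restrict to the Step-1 set, since the disease edges branch off the
chemical universe rather than the gene edges, and the final three-way
join makes the choice immaterial for any chemical that retains a C–G
edge.

### Gene identifiers

C–G interactions carry *primary* Entrez IDs assigned irrespective of
the curated organism. `remap_gene_ids()` adds a species-specific ID:
kept as-is when the primary gene's own taxon (from a gene-info lookup)
equals the curated organism, otherwise resolved through the pairwise
`gene_orthologs` table, symmetrically in both directions. Records
without an ortholog in the curated organism are excluded and counted; a
gene absent from the lookup is excluded under a distinct reason rather
than silently guessed. One-to-many orthology emits one record per
target ortholog — downstream set semantics deduplicate, and any other
policy would be an arbitrary loss. G–D edges join triplets on the
primary ID (the identifier that table uses), while gene2go joins on the
species-specific ID; each retained C–G row carries both.

### Filters

Organism and anatomy filters act on the tables that carry those
annotations (C–P, C–G). Disease edges carry neither, so two indirect
filters stand in: a tissue filter through a precomputed disease →
tissue-group map (diseases without a mapping default to *all* groups,
i.e. they are never excluded by tissue), and a species filter that
requires a disease edge's PubMed IDs to intersect the PubMed IDs of C–G
interactions curated for the target organism. "Cross-referencing" is
implemented as record-level PubMed set intersection — conservative and
reproducible — and a record with an empty PubMed set fails an active
intersection filter. The five presets v1–v5 toggle only the
disease-edge filters (v1: marker/mechanism only, tissue and species
filters on … v5: both evidence classes, both filters off), which is
what makes the tetramer set monotone non-decreasing from v1 to v5 at
fixed organism and tissue; the suite asserts this as a property.

The 28 tissue groups extend a 25-group foundational set with breast,
fat tissue and pluripotent stem cells. The packaged anatomy and disease
maps are synthetic stand-ins (`*_synthetic.tsv`) that reproduce the
published structure — 28 groups covering 506 anatomy terms, and the
category expansions such as *Endocrine system* → the four glands —
because the published mapping is an external artifact; both files are
replaceable via `tissue_group_map()` arguments or the YAML config.

## Grouping and clustering

`group_gpd()` partitions tetramers by (gene, phenotype, disease);
`group_pd()` by (phenotype, disease), unioning chemicals across genes.
Singleton groups are kept — fragmentation is a property of sparse
evidence worth reporting, not an artifact to hide.

Phenotype clustering uses the Lin measure over the GO DAG,
`2·IC(MICA)/(IC(a)+IC(b))`, with corpus-based information content
`IC(t) = −ln(count(t)/count(root))` after propagating each annotation
once to every ancestor (ancestor-set union, so diamond topologies do
not double-count). Numerical conventions, each covered by a test:

* natural logarithm; the IC corpus is the loaded gene2go table (the
  full annotation file in production, the generated one in tests) —
  the corpus and log base are deliberate choices, configurable by
  supplying a different annotation table;
* the root has IC 0; a pair of roots is defined to have similarity 0
  (avoiding 0/0), and a pair whose only common ancestor is the root
  scores 0;
* cross-namespace pairs score 0; terms with no propagated annotations
  have undefined IC and are excluded from similarity matrices, making
  them dissimilar to everything;
* "similarity above a threshold" is implemented as `>=`, so the
  conventional thresholds 0.5/0.75/0.9 include exact ties.

Connected components of the thresholded similarity graph define
phenotype families; groups in one family merge only if they also share
a gene and a disease (GPD mode) or a disease (PD mode), with the
constraint closed transitively inside the component — matching the
connected-component semantics used for the chemical-list route.
Chemical-list clustering thresholds the pairwise Tanimoto matrix of
member sets the same way. Both routes compose, and
`enumerate_configs()` spans the full grid: 5 presets × 2 groupings ×
(3 phenotype-only + 3 chemical-only + 9 combined) = 150 configurations.

Cluster scoring is standard one-tailed hypergeometric ORA
(`P(X ≥ k)` for `k` category members among `n` cluster members drawn
from a background of `N` containing `K`) with Benjamini–Hochberg
adjustment per batch. The default background for chemical-class ORA is
the set of chemicals with at least one tetramer in the run; for GO ORA
it is the gene universe of the annotation corpus; both are arguments.
Class tagging uses case-insensitive substring rules over names and
synonyms (bisphenol, phthalate), parent-MeSH rules (PFAS via
Fluorocarbons D005466) and explicit MeSH lists; chemicals classified as
pesticides are excluded from the pharmaceutical class.

## What the fixture generator emulates — and what it does not

`generate_fixtures()` writes the complete input surface: the 16
CTD-dialect TSVs (four populated), gene2go, gene_orthologs, gene-info,
a toy OBO ontology and the two compound tables, with `MESH:` prefixes
in place and headers in the comment-line dialect. It plants disjoint
blocks — chemicals × genes × one phenotype family × one disease per
organism — each backed by a block-level PubMed ID shared across all
four CTD edges, so the species and tissue cross-reference filters pass
by construction and the expected tetramers, groups and clusters follow
in closed form (the manifest is derived from the construction, never
from running the pipeline). Within-family Lin similarity at equal leaf
annotation counts is `ln(T/c_F) · 2 / (ln(T/c_1) + ln(T/c_2))`; the
generator evaluates it and refuses layouts that cannot separate at
threshold 0.5. Defaults: 3 blocks of 3 chemicals and 2 genes across
human/mouse/rat, 3 two-leaf phenotype families, depth-3 DAG — small
enough that the whole suite (including a literal five-table nested-loop
oracle and five-seed recovery runs) completes in seconds. Therapeutic
evidence enters as a per-block label flip (`evidence_mix`), which
removes the block from v1 but not v2–v5; noise edges draw only from
disjoint noise-chemical and noise-disease pools and therefore can never
complete a tetramer.

The generator makes no attempt at statistical realism: CTD's degree
distributions, multi-organism rows, curation noise and the real GO's
breadth are all absent. Passing tests therefore demonstrate the
*correctness of the joins, filters and similarity machinery*, not the
biological yield of the method on a live CTD snapshot — corpus-level
counts depend on the database version and are out of scope here.

## Degenerate inputs and tie-breaks

Malformed TSV rows (field count differing from the header) are counted
and reported, never silently dropped; duplicated rows collapse after
normalization. Empty tetramer sets propagate as valid empty groups,
clusters and outputs (the run manifest records a warning). MICA ties
are harmless — only the maximal IC value enters the formula. Tanimoto
of two empty sets is an error rather than a silent 0 or 1. An ontology
with a cycle is rejected at load time.

## Known limitations

* Effect direction and magnitude of C–G interactions are not modelled.
* The disease → tissue mapping is lookup-only; no automatic string
  matching of disease names to anatomy terms is attempted.
* Only `is_a` edges contribute to ancestry; `part_of` and other
  relations are ignored.
* Remote retrieval is untested plumbing; the supported path ingests
  local dump files.
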