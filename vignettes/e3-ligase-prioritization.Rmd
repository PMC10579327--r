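---
title: "Multi-evidence prioritization of E3 ligases for targeted protein degradation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-evidence prioritization of E3 ligases for targeted protein degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(e3select)
```

## The problem

Proteolysis-targeting chimeras (PROTACs) degrade a protein of interest by
recruiting it to an E3 ubiquitin ligase. Although the human genome encodes
hundreds of E3 ligases, only a handful — VHL and CRBN above all — are
routinely co-opted in degrader design. Choosing a new ligase is a
multi-criteria decision: is the gene really an E3 ligase, can it be bound
by a small molecule, is it expressed where the tumor is and absent where
toxicity would arise, does it physically contact the intended target, is it
structurally characterized, essential, and in the right cellular
compartment? `e3select` implements that decision framework as a tested
pipeline: each evidence dimension is computed by an explicit, documented
rule, and a query engine combines them into candidate searches.

## The model, dimension by dimension

### Catalog and confidence score

The catalog is the union of three curated source lists with different kinds
of evidence: a literature-parsed list with a validated/predicted flag, a
domain-signature list with a free-text function annotation, and an
E3-substrate-interaction (ESI) resource with a per-gene ESI count. Each
source contributes a sub-score of 1 or 2:

* literature list: 2 if validated in the literature, else 1 (predicted);
* function list: 2 if the annotation contains the keyword "E3", else 1;
* ESI list: 2 with more than 5 ESIs (strictly; exactly 5 scores 1), else 1.

The confidence score is the sum over the sources that list the gene, so it
ranges 1-6, and a score of 5 or 6 implies presence in all three lists. A
gene listed nowhere is not an E3 ligase and never enters the catalog.

Two matching details were genuinely open and are fixed here: the "E3"
keyword is matched case-insensitively on word boundaries, so "RING E3
ligase" scores 2 but the symbol "UBE3A" inside an annotation does not; and
duplicate records within one source keep the higher-scoring record, which
is conservative toward evidence. IAP-family members other than BIRC2 and
XIAP are dropped, since those two represent IAPs in IAP-recruiting
degraders. The co-opted list (ligases already used in published PROTACs)
and its clinical subset are configuration, not computation: the default
ships the ten symbols named in prose in the degrader literature
(VHL, CRBN, MDM2, KEAP1, DCAF16, DCAF11, XIAP, BIRC2, AHR, RNF4, with
VHL and CRBN clinical) and is explicitly user-overridable rather than
authoritative.

### Ligandability

Three evidence categories are aggregated: drugs (DrugBank/DGIdb-style
tables), bioactive small molecules (ChEMBL-style activity records kept when
pChEMBL >= 5, i.e. 10 uM or better, boundary inclusive), and covalent
electrophiles (cysteine-profiling hits; a hit in any profiled cell line
counts, since the screens report per-cell-line hits without a stated
combination rule). Ligands are deduplicated by a canonical key — ChEMBL id
when available, else a lexically normalized SMILES, else a source-qualified
native id. Lexical (whitespace/case) SMILES normalization was chosen over
chemistry-aware canonicalization to keep the core dependency-free; a
`canonicalizer` hook accepts a proper canonicalizer where one is available.
DGIdb-style interaction rows are accepted regardless of interaction type,
with column filtering left to the caller, since no type filter is specified
for the source.

The tier label is a strict precedence: `E3drug` with any drug evidence,
else `E3chem` with any active small molecule, else `E3cova` with any
covalent hit, else `E3dark`.

### Expression selectivity

Four dataset classes are classified tissue by tissue:

* **Bulk transcriptomes** (tumor TCGA-like, normal GTEx-like): the tissue
  level is the median of log2(TPM+1) over the tissue's samples; "High"
  means strictly above 4. Inputs are assumed pre-normalized, as in
  uniformly recomputed compendia; normalization and batch correction are
  out of scope.
* **Protein staining** (HPA-pathology-like): a (gene, cancer type) is
  "High" when at least 20% of samples stain medium-or-high. The source
  wording mixes "over 20 percent" and ">= 20%"; the inclusive reading is
  the default, with `strict = TRUE` available. "Median-high" staining is
  interpreted as the {medium, high} levels of the four-level staining
  vocabulary; the mapping is an argument.
* **Single-cell normal atlas** (Tabula-like): a tissue is "High" when the
  percentage of non-zero cells strictly exceeds 12.75 and the mean over the
  non-zero cells strictly exceeds 2.325. These thresholds are not
  arbitrary: they are 75% of a reference pattern known to be clinically
  safe — VHL in platelets, expressed in 17% of cells at a non-zero mean of
  3.1 — scaled down to be more stringent
  (`derive_sc_thresholds(17, 3.1, 0.75)`). The mean is computed over
  non-zero cells only; the reference pattern is itself quoted as a
  non-zero-cell mean, which is what fixes this otherwise open reading.
* **Low in the majority of normal tissues**: at least 70% (inclusive) of
  the dataset's tissues called Low, with the denominator being the tissues
  actually present in the loaded dataset, not a fixed atlas size.

A ligase is **tumor-selective** when it is High in at least one tumor type
in *both* tumor datasets and Low-majority in *both* normal datasets. All
reported percentages are rounded half away from zero at one decimal
(`round_half_up`), the convention used for every printed ratio.

For tumor single-cell datasets with malignant/immune/other annotation,
`sc_tumor_composition()` reports per group the expressing-cell count, the
within-group expressing percentage, and the group's share among all
expressing cells; shares sum to 100 within rounding.

### Protein-protein interactions

Six source dialects are read with per-source retention rules applied before
merging: non-human rows are always dropped; STRING-like combined scores
must strictly exceed 700; predicted ESIs must strictly exceed confidence
0.7; literature-curated ESIs and curated/assayed sources are kept
unconditionally. Edges whose detection method matches a configurable
vocabulary (yeast two-hybrid, affinity purification-MS, 3D structures,
low-throughput experiments) are flagged as physical associations; the
vocabulary is configuration because sources spell methods in PSI-MI-style
free text.

Merging treats pairs as unordered, unions provenance, ORs the physical
flag, and removes self-loops (not addressed by the source rules; a flag
retains them). The merged edge count therefore counts unique unordered
ligase-involving pairs. Derived statistics: the target space of a ligase
set (partners of any member, excluding the set itself by default), the
percent increase between two target-space sizes, and the per-target number
of interacting E3 ligases with its median — targets with zero interacting
E3s enter the median denominator only when an explicit target universe
(a degrader-tractability list) is supplied, matching the "tractable
target" phrasing of that statistic.

### Essentiality, location, structures, interfaces

* **Essentiality**: a gene is essential when the mean dependency
  probability across cell lines is strictly above 0.5. The sources compute
  lineage means while the headline statistic uses the overall mean across
  cell lines; both are provided (`essentiality_table()` returns the overall
  call with a per-lineage table as an attribute), and the overall mean is
  the headline call. The two readings coincide on equal-size lineages,
  and the overall mean is exactly the lineage-size-weighted mean of
  lineage means.
* **Location**: high-confidence annotations from three sources are
  unioned; COMPARTMENTS-style annotations qualify only with score strictly
  above 3, while GO/UniProt-style rows are assumed pre-filtered to a
  high-confidence evidence vocabulary upstream (the precise evidence codes
  are configuration). Favorable locations are cytoplasm (terms matching
  "cytoplasm"/"cytosol") and nucleus ("nucleus"), matched by
  case-insensitive substring, with exclusivity labels (cytoplasm-only /
  nucleus-only / both / neither).
* **Structures**: the count of distinct experimental structure ids; genes
  with none fall back to the predicted-structure archive, recorded as an
  availability flag only — no coordinate files are parsed.
* **Interfaces**: counted as distinct (partner, source) pairs by default,
  since interface provenance (co-crystal, homology model, high-confidence
  prediction) is reported separately in the source; `collapse_partners`
  counts distinct partners instead. Residue ranges are 1-based inclusive
  and queryable per position.

### The search engine

`general_search()` applies the conjunction of the enabled filters of a
`candidate_query()`. Every printed threshold keeps its printed strictness:
confidence "> 3" and PPIs "> 100" are strict, "less than 30% of normal
tissues High" is strict, "at least 1 tumor type" is inclusive. Inclusive
variants (`strict = FALSE`) exist for sensitivity analysis. The result
ordering — confidence descending, unique-ligand count descending, then
symbol — is a deterministic convention of this package; the original
interface returns an unordered table. `search_by_target()` restricts to
ligases with a merged edge to the target, optionally requires a High call
in a given cancer type, and appends ascending PPI degree as a specificity
tiebreaker, so among otherwise equal candidates the most target-dedicated
ligase leads. The `case1_query()` preset encodes the worked-example search
(confidence > 3, any ligand, >= 1 tumor type High in the bulk tumor
dataset, < 30% of bulk normal tissues High, > 100 PPIs); its tumor
condition deliberately uses the bulk tumor dataset only, exactly as the
criteria are worded.

Partner enrichment uses the upper-tail hypergeometric probability
P(X >= k) with Benjamini-Hochberg adjustment across the tested terms and a
0.05 significance level on the adjusted p. The default universe is every
protein appearing in the merged edge set, overridable per call.

## The synthetic-data generator

`generate_bundle()` emits a complete input bundle — all source tables in
the dialects the readers expect — plus a truth manifest recording every
planted derived quantity, computed from the plan rather than by running the
pipeline. This makes a full pipeline run over a bundle an end-to-end
oracle test, and it is how the package is tested without any external
downloads.

Key generator choices:

* **Guaranteed classification.** Bulk values are log-normal around a
  planted median, multiplicatively shifted so the median order statistic
  is *exact*; planted High medians lie in [4.5, 7.5] and Low in [0.5, 3.5],
  keeping at least 0.5 of margin around the boundary at 4. Single-cell
  tissues plant an exact non-zero cell count (High fractions at least 14%
  versus the 12.75% rule) and rescale non-zero magnitudes to an exact mean
  (High means at least 2.9 versus the 2.325 rule). Staining fractions and
  essentiality means keep comparable margins. Boundary behaviour is
  exercised separately by `make_boundary_fixtures()`, which places
  observations exactly on each printed threshold.
* **Exact preset recovery.** `plant_case1_passers(config, k)` plants `k`
  ligases satisfying every preset criterion and forces each remaining
  ligase to violate at least one (low confidence, no ligand, no tumor-High
  type, too many normal-High tissues, or at most 100 partners); one
  near-passer always sits at confidence exactly 3 to exercise the strict
  filter end to end.
* **Stream isolation.** Each table derives its own random stream from the
  master seed and the table name, so adding a table never perturbs the
  others; identical seeds give byte-identical bundles (verified by MD5 in
  `checksums.txt`).
* **Decoys.** The bundle includes records that must be filtered out:
  sub-threshold STRING scores (including exactly 700), predicted ESIs at
  and below 0.7, non-human interaction rows, self-loops, inactive
  bioactivity records, low-confidence location annotations, duplicate
  within-source catalog records, and cross-source duplicate ligands.

What the generator does **not** emulate: correlation structure between
dimensions beyond what planted specs require, realistic expression
distributions (dropout patterns, library-size effects), symbol ambiguity
beyond a simple alias table, or any real biology of specific genes.
Passing the planted-truth tests therefore demonstrates that the rules are
implemented exactly as specified, not that the rules themselves generalize
to real atlases.

## Problem sizes and runtime

The default synthetic study uses 200 ligases, 1000 candidate targets, 10
tumor types and 10 normal tissues with 20 bulk samples each, 12 staining
samples per tumor type, ~5000 normal single-cells, a 600-cell tumor
single-cell dataset, and 20 screen cell lines in 2 lineages — sizes chosen
so a full generate-build-search cycle completes in well under a minute on
one CPU while every code path (all six PPI dialects, all four expression
datasets, all annotation tables) is exercised. The test suite runs this
cycle across three seeds with 0, 5, and 20 planted preset passers.

## Known limitations

* The co-opted and clinical ligase lists are shipped defaults, not a
  maintained registry.
* Symbol harmonization is a lookup table; no live HGNC resolution.
* Real-data exports must be reshaped into the documented simplified
  dialects (column maps in `?load_source_edges`); native BioGRID-tab3 or
  MITAB parsing is deliberately out of scope.
* Deep-learning drug-target prediction, structure prediction itself, and
  immunohistochemistry image processing are out of scope; only their
  tabular outputs are consumed.
* The tumor-type-to-normal-tissue matching used for side-effect views is a
  two-column configuration table, never computed.
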