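---
title: "Mining adverse outcome pathway networks from abstracts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining adverse outcome pathway networks from abstracts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aopminer)
```

## The problem

Adverse Outcome Pathways (AOPs) structure toxicological knowledge as
causal chains — stressor → molecular initiating event → key events →
adverse outcome. Assembling the evidence for such chains means reading a
large, fast-growing literature. `aopminer` automates the first pass: it
scans an abstract corpus for co-mentions of curated stressor and
biological-event terms, scores each co-mention statistically, annotates
the events with database knowledge, and emits an undirected network that
an expert can then curate into directed key-event relationships. The
package deliberately stops short of inferring direction or causality:
co-occurrence in an abstract is evidence of *association*, and the
expert owns the rest.

## Text standardization

Dictionary terms, abstract text and annotation keys all pass through one
normalization path:

1. **Tokenization.** Lowercase; tokens are maximal runs of letters and
   digits, so hyphens and slashes split ("TP53-mediated" → `tp53`,
   `mediated`). Digits and non-Latin letters are preserved inside tokens,
   keeping gene symbols intact.
2. **Stop-word removal.** A fixed English function-word list ships with
   the package (`inst/extdata/stopwords_en.txt`, overridable via
   `stopword_file`). Removal happens *before* stemming so the list lookup
   is exact; as a guard, any stem that coincides with a stemmed stopword
   is also dropped, so no output stem can ever equal a stopword's stem.
3. **Stemming.** The classic Porter algorithm, implemented in the package
   (`porter_stem()`) and frozen against the algorithm's published example
   vocabulary in the tests. Inside the normalization pipeline the stemmer
   is iterated to a fixed point. Single-pass Porter is not idempotent
   ("degeneration" → "degener" → "degen"), and we want normalization to
   be: re-normalizing already-normalized text must be the identity, which
   makes cached or re-exported stem sequences safe inputs. Because the
   same fixed-point path is used for dictionaries, corpora and annotation
   keys alike, the choice cannot desynchronize matching.
4. **Synonyms.** Each dictionary term expands to its label plus synonyms;
   variants that collapse to the same stem set are deduplicated with the
   label kept first.

Sentence segmentation is rule-based (`.`, `!`, `?` followed by
whitespace). This is deliberately model-free: a trained sentence splitter
would add a heavy dependency and nondeterminism for marginal gain on
abstract-length text.

## Matching regimes

A term variant with `k` distinct stems matches a stem set when `j` of its
stems are present and:

* **partial**: `j/k ≥ 3/4` — implemented as the integer comparison
  `4j ≥ 3k`, never floating point, so the boundary is exact for every
  `k` (for `k = 4`, exactly 3 stems suffice);
* **exact**: `j = k`, the restrictive variant that trades recall for
  precision.

Every exact match is a partial match, a property the tests verify by
brute force for all `k ≤ 8`. Repeated stems in a phrase count once —
set semantics, consistent with the normalization pipeline.

Matching scope defaults to the whole abstract (title + body); a stricter
per-sentence scope is available (`scope = "sentence"`). Stressors and
events are matched by identical rules.

## Link extraction and scoring

Term pairs of the requested kinds (stressor–event, event–event) are
linked by the set of abstracts in which both were detected; pairs with no
shared abstract produce no link. Links are undirected and
category-pure — a stressor never appears in an event–event link.

Against a closed-world background of the `N` analyzed abstracts, each
link's 2×2 table (both / A only / B only / neither) is tested with the
one-sided Fisher exact test for enrichment, `P(X ≥ n_both)` under the
hypergeometric null. One-sided because co-occurrence mining asks only
whether two terms appear together *more* than chance; depletion is not
evidence of a pathway. `N` = corpus size is the only defensible
closed-world choice — the corpus the user supplies defines the universe
of discourse. A table with zero co-occurrence yields `p = 1` exactly.

The computation uses the hypergeometric tail (`stats::phyper`); the test
suite checks it against exhaustive enumeration of the hypergeometric mass
for *every* table with `N ≤ 40` (within 1e-10) and against
`fisher.test(alternative = "greater")` on random tables.

Multiplicity: optional Benjamini–Hochberg adjustment, computed separately
within each link kind, since stressor–event and event–event searches are
different test families. Ties are broken by a stable radix sort for
determinism. When BH is on, the confidence rule (below) reads the
adjusted p-value.

## Confidence categories

Each link gets one of four categories from its support count and
p-value. Defaults: `alpha = 0.05`, `count_moderate = 5`,
`count_high = 20`:

* **Very High** — significant and count ≥ 20;
* **High** — significant and count ≥ 5;
* **Moderate** — significant with smaller support, or non-significant
  but count ≥ 20 (frequency alone is weak evidence);
* **Low** — otherwise.

All three parameters are configuration, surface in the run metadata, and
this particular binning is this package's own default — published
web-server implementations of co-occurrence confidence use unpublished
bins, and no claim of equivalence is made. The mapping is monotone: more
support or smaller p never lowers the category (property-tested on 1,000
random pairs).

## Database annotation

Events are annotated against user-supplied TSV extracts of AOP-Wiki,
HPA, KEGG, Reactome, WikiPathways, UniProt, DISEASES and DisGeNET. The
default rule is stem-set *equality* (annotation is a lookup, not
discovery); a partial rule reuses the exact same ¾ arithmetic as the
matcher so the threshold means one thing everywhere. Gene-category terms
additionally match keys by case-insensitive raw symbol equality, because
stemming can mangle symbols ("ties" would stem, "TP53" must not).
Matches are deduplicated by (source, annotation id). No live database
retrieval and no ontology traversal: extracts are accepted as supplied,
keyed by label or symbol.

## The network

Nodes are exactly the terms incident to at least one link; edges carry
weight (= number of supporting abstracts), confidence, p-value, and the
sorted supporting record ids — the click-through "which articles support
this edge" becomes data rather than UI. Filtering keeps edges with
`weight ≥ min_count` and `confidence ≥ min_confidence`, then drops
isolated nodes; the *effective cumulative* filter is recorded in
metadata, so filtering twice equals filtering once at the stricter
thresholds (tested against a brute-force scan on random networks).

Serialization: a Cytoscape-style JSON object
(`elements` → `nodes`/`edges`, each wrapped in `data`) with keys sorted
and confidence accompanied by a display color token
(Low = orange `#E69F00`, Moderate = yellow `#F0E442`, High = light-green
`#90EE90`, Very High = dark-green `#006400`) — presentation metadata
only; the category string is normative. TSV edge and node tables are
sorted, p-values printed with 17 significant digits so re-import
reproduces the doubles exactly, and all output is byte-stable across
runs. Run metadata records every tunable (mode, scope, thresholds,
stemmer, corpus size). Wall time is logged to the console but *not*
written into `run_metadata.json`: byte-identical reruns of identical
inputs are a hard guarantee, and a timestamp would break it.

## Synthetic fixtures

`corpus_spec()` / `generate_corpus()` build corpora with *planted*,
exactly known structure: per-pair co-mention counts, solo mentions,
background abstracts, and optionally a fraction of plants in which the
second term of a pair appears with only `⌈3k/4⌉` of its `k` stems —
sitting exactly on the partial-match boundary and invisible to the exact
matcher. Validity rules make recovery provable: term variants must be
pairwise stem-disjoint, each label word must contribute its own stem, and
filler text is drawn from a fixed nonsense vocabulary checked for stem
collisions at generation time. Reduced-stem plants are only allowed for
terms with ≥ 4 stems, since `⌈3k/4⌉ = k` below that. Placement uses R's
Mersenne-Twister generator under a caller-isolated seed recorded in the
ground truth.

The reference conditions (`demo_corpus_spec()`) are 12 terms (2
stressors, 9 events, 1 gene), 200 abstracts — 16 pairs with counts
spanning 0–15 (120 abstracts), 30 solo mentions, 50 background — and,
in the partial variant, 30% reduced-stem plants for every pair whose
second term has ≥ 4 stems. These sizes give every pipeline stage
non-trivial work (zero-count pairs, count ties, both link kinds) while a
full run stays in the low seconds.

What the fixtures do *not* emulate: real abstract prose. Filler words are
structural, not linguistic — there is no ambiguity, no negation, no
anaphora, no term mentioned in passing. Passing the planted-recovery
suite therefore shows the *mechanics* (normalization, thresholds,
counting, scoring) are exact; it says nothing about linguistic precision
and recall on real PubMed text, where dictionary quality and the
¾ threshold dominate performance.

## Numerical and degenerate-case choices

* ¾ threshold: exact integer arithmetic (`4j ≥ 3k`), no floating point.
* Fisher tail at zero overlap: `p = 1` by construction, not by limit.
* All sorting uses radix order (locale-independent, byte-stable).
* TSV p-values: `%.17g`, sufficient for exact double round-trip; JSON
  uses full precision (`digits = NA`).
* Empty cases are defined, not errors: empty text → no sentences; a term
  absent from the corpus → no node; a filter removing everything → an
  empty network that still serializes and round-trips.
* Errors are reserved for contract violations: duplicate record ids,
  unknown categories or sources, terms with no content words, non-UTF-8
  bytes (rejected, never silently replaced).
* A failed run stages output in a temporary directory and leaves nothing
  behind.

## Known limitations

* Abstract-level co-occurrence has bounded precision; the sentence scope
  tightens it but no syntactic or graph-based sentence filtering is
  applied.
* No fuzzy matching: a misspelled term is missed.
* Dictionary coverage bounds recall entirely; synonym lists matter more
  than any threshold.
* The confidence bins are heuristic defaults, not calibrated
  probabilities.
* Year metadata is read and preserved but no temporal analysis is
  performed.
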