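---
title: "Curation and classification of in vivo pharmacology assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation and classification of in vivo pharmacology assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(invivoclass)
```

## The problem

Large open bioactivity databases hold hundreds of thousands of *in vivo*
assays — experiments measuring a compound's effect in a whole living animal —
but the information sits in compact free-text descriptions written by data
extractors, with no controlled vocabulary for the animal disease models or
phenotypic endpoints being studied. `invivoclass` implements a curation
pipeline that (i) identifies the disease-, phenotype- and toxicity-relevant
*in vivo* subset of a flat assay table, (ii) assigns each assay a
multi-label, three-level classification by matching a curated dictionary of
regular-expression patterns against its description, (iii) projects those
classes onto MeSH descriptor terms for interoperability, (iv) summarises
corpus coverage, and (v) validates the annotation against a curator-labelled
gold standard with confusion-matrix statistics.

## Identification: five conjunctive filters

A record belongs to the *in vivo* dataset when all of the following hold:

1. **BAO format** is "organism-based format" (`BAO_0000218`). The BioAssay
   Ontology distinguishes whole-organism experiments from cell-, tissue- or
   biochemical formats; this is the primary *in vivo* marker.
2. **Mammalian organism**: the assay organism *or* the target organism is
   classed `Mammalia` at level 2 of the organism-class hierarchy. The OR is
   deliberate: in a xenograft study a human cell line is grafted into a
   mouse, so the assay organism is Mouse while the target organism is Human.
3. **No in vitro / ex vivo mention** in the description, via the
   case-insensitive pattern `in[ -]?vitro|ex[ -]?vivo`.
4. **Not an ADMET assay** (`assay_type != 'A'`): pharmacokinetic
   measurements are not disease or phenotype models.
5. **Literature source** (`src_id == 1`): deposited screening datasets carry
   their own annotation and are excluded. The admitted source set is
   configurable (`filter_options(src_ids = ...)`) but defaults to `{1}`.

Each failing clause is recorded as a reason code in the decision table, so
acceptance is fully auditable. Two deliberate edge policies:

* A record with an **empty description** is *not* rejected by clause 3 — a
  regex applied to missing text is vacuously false — but is flagged
  `MISSING_DESCRIPTION`, since it can never be annotated downstream.
* **Organism labels compare exactly** (`"Mammalia"`, case-sensitive) by
  default because the database stores the literal label; a configuration
  switch enables case-insensitive comparison for sloppier exports.
* **Duplicate assay identifiers** collapse to their first row with a
  warning, mirroring SELECT DISTINCT semantics in the relational original.

## Annotation: a regex pattern dictionary

Each dictionary entry is one level-3 assay class — a specific reference
animal model (e.g. *Tail Flick / Radiant Heat Method*, *Paw Edema Test*,
*CCl4-induced liver fibrosis*) or a general phenotype endpoint (*general
analgesic activity*, *drug-induced liver injury*) — with its level-2 group
and level-1 broad category, its `source` (the Hock/Vogel reference works
`Hock_2016`, `Vogel_2008`, `Vogel_2013` for animal models; `phenotype` for
endpoint terms), one or more regex patterns, MeSH descriptor labels, and any
inducer or positive-control compounds (carrageenan induces paw oedema;
morphine is a positive control in the Tail Flick test).

Matching rules, chosen for fidelity to how such dictionaries are written:

* Patterns match **exactly as written** — case variation is encoded inside
  the pattern (`[Tt]ail\W?[Ff]lick` matches "tail flick" and "Tail-Flick").
  A per-entry `i` flag allows case-insensitive matching for simple phenotype
  terms; it is off for every seed entry.
* Annotation is **multi-label**: all matching entries are kept, with no
  precedence or suppression. A description mentioning a tail-flick test and
  analgesic activity legitimately carries both the reference-model and the
  phenotype class.
* Within one entry, only the **first matching pattern** (lowest index) is
  recorded: the mapping table links assays to classes, not to patterns.
* Every hit stores the **matched substring** for provenance, and hit files
  are sorted by (assay, class) so outputs are reproducible byte for byte.

Pattern lists are pipe-separated in the dictionary file, so individual
patterns may not contain a top-level `|`; the same alternation is expressed
as multiple patterns, which also keeps each pattern individually auditable.

The packaged seed dictionary (33 entries) covers every class appearing in
the package's worked examples; production dictionaries with hundreds of
models load through the same `read_dictionary_file()` path and validation
(patterns must compile, identifiers must be unique, headings non-empty).
Only the tail-flick pattern is carried over verbatim from published
curation; all other patterns are written for this package and marked
`provenance=repo` in the file.

## MeSH mapping

MeSH terms attach to classes, never directly to assays; an assay's MeSH
annotation is the deduplicated union over its hit classes. Labels are stored
uppercase and preserved byte-for-byte — no normalisation — because they act
as join keys into external vocabularies. A separate, repo-curated crosswalk
maps each seed term to its top-level MeSH tree categories (a term may sit in
several: *seizures* is both a nervous-system disease, C10, and a
sign/symptom, C23). The crosswalk covers seed-dictionary terms only; larger
dictionaries should ship their own table.

## Reporting

`coverage_summary()` counts, over all identified assays: annotated at all,
annotated by a reference animal model, by a phenotype endpoint, and by both.
All percentages use the **total identified corpus** as the base — this is
the only base under which the published corpus figures (66.5% annotated;
38% model, 51% phenotype, 23% both) are arithmetically consistent, which we
verified from the published counts. Full precision is kept internally;
display rounding (one decimal for overall coverage, nearest integer for the
three shares) is applied only by `format_coverage()`.

`breakdown()` tallies distinct (assay, label) pairs per axis — level-1
headings or MeSH tree codes — and merges labels below a threshold (defaults:
2% for level 1, 3% for MeSH) into an "Other" row, recording which labels
were grouped. An assay with classes under two level-1 headings counts once
under each; whether to count assays or pairs is genuinely open, and we count
distinct pairs because it keeps the two axes consistent with each other and
with multi-term MeSH expansion.

## Evaluation

Validation scores the *binary* decision — pipeline annotated vs curator
assigned any experiment or phenotype phrase — in a 2x2 confusion matrix,
with sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP)
and F1 = 2TP/(2TP+FP+FN). Per-class agreement is out of scope: curator
phrases are free text and do not map one-to-one onto dictionary classes,
so the phrase columns are carried for manual inspection instead. Gold rows
flagged `excluded` (assays that turned out not to be in vivo) are removed
before counting. A statistic whose denominator is zero is reported as
missing (`NA`), never as 0. Gold assays without a prediction row count as
predicted-negative with a warning; a strict mode errors instead.

## The synthetic corpus generator

Because real corpora cannot be shipped, `generate_corpus()` builds corpora
whose expected outcome is known by construction: descriptions come from
parameterised templates (species, dose, route, timing vary) that either
embed exactly one seed-dictionary trigger combination — chosen so the set of
firing classes, and hence the model/phenotype/both status, is fixed by the
template — or are decoys reusing pharmacology vocabulary with no trigger.
Contaminants plant known failing filter clauses at configurable rates, with
at least one failure forced per contaminant.

Defaults mirror the study corpus: 66.5% of in vivo assays annotatable, with
the model/phenotype/both mix split in the 38/51/23 proportions (used as
relative weights among annotated assays, since the printed corpus-level
figures are rounded and do not sum exactly to the one-decimal total); 70%
of records in vivo, the rest contaminants. `generate_gold()` derives curator
labels from the truth with an exact, seeded number of planted disagreements:
`flip_fp` truth-positive assays become curator-negative (false positives for
a truth-recovering pipeline) and `flip_fn` truth-negative assays become
curator-positive (false negatives). This orientation is what reproduces the
published validation matrix (315/63/36/74 over 488 scored of 500, 12
excluded) by construction.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: the vocabulary, syntax and length variance of real
extractor-written descriptions; trigger phrases occurring in negated or
irrelevant contexts; partially-matching near-miss phrases; and the editorial
judgement of which published models are uniquely identifiable from text at
all. Exact-recovery results on synthetic corpora demonstrate mechanical
correctness of the matching machinery, not real-world recall.

Everything is deterministic for a fixed seed (Mersenne-Twister with
post-3.6 "Rejection" sampling, named so fixtures stay stable across R
versions); the caller's RNG state is saved and restored.

## Numerical and format choices

* TSV, UTF-8, no quoting; embedded tabs rejected at read and write time.
  Semicolon joins multi-valued cells, pipe joins pattern lists; values may
  not contain their delimiter (validated on write).
* Logical columns serialise as 0/1; reading is tolerant of `true/false`.
* Outputs contain no timestamps, so pipeline reruns on identical inputs are
  byte-identical; the run manifest (version, configuration hash, row
  counts) is the single volatile file.
* Simulation sizes used throughout the tests — corpora of 200–1,000 records,
  a 500-row gold reproduction — are the package's chosen desk-scale working
  points: large enough to exercise every template, contaminant mode and
  clause combination, small enough to keep the full suite fast.

## Known limitations

* Pattern matching is literal: no fuzzy matching, negation handling, or
  learning from text. A description saying "no tail flick response was
  measured" still annotates Tail Flick.
* The seed dictionary is a small, worked-example-complete subset; coverage
  of a production corpus requires the full external dictionary.
* MeSH terms are labels, not descriptor IDs; downstream joins assume the
  2018 label forms.
* Evaluation is binary by design; it cannot detect a correct "annotated"
  decision made for the wrong class.

## A short end-to-end run

```{r example, eval = FALSE}
dict <- seed_dictionary()
corpus <- generate_corpus(corpus_spec(500, seed = 7))
res <- identify_corpus(corpus$records)
ann <- annotate_corpus(res$accepted, dict)
coverage_summary(ann)
head(mesh_corpus(ann, dict))
gold <- generate_gold(corpus$truth, flip_fp = 10, flip_fn = 15, seed = 7)
classification_stats(confusion_matrix(ann$summary, gold))
```
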