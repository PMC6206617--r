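# invivoclass

Curation, classification and evaluation of *in vivo* pharmacology assays.

Open bioactivity databases contain large numbers of *in vivo* assays —
experiments measuring a compound's effect in a whole living animal — whose
scientific content (which animal disease model? which phenotypic endpoint?)
lives only in compact free-text descriptions. `invivoclass` is for curators
and computational chemists who need to carve the disease-, phenotype- and
toxicity-relevant *in vivo* subset out of flat assay tables and organise it
by animal model, endpoint and MeSH disease term, reproducibly and audibly.

The pipeline has five stages:

1. **Identification** — five conjunctive filters on assay metadata:
   BioAssay Ontology format `BAO_0000218` ("organism-based format");
   assay *or* target organism classed `Mammalia` (the OR admits xenograft
   assays); no case-insensitive match of `in[ -]?vitro|ex[ -]?vivo` in the
   description; assay type not `'A'` (ADMET); literature source
   (`src_id = 1`). Every rejection carries machine-readable reason codes.
2. **Annotation** — a curated dictionary maps each level-3 assay class
   (level 1 broad category ⊃ level 2 group ⊃ level 3 specific model or
   endpoint) to regex patterns matched against the description, e.g.
   `[Tt]ail\W?[Ff]lick` for the Tail Flick reference animal model.
   Multi-label: all matching classes are kept, flagged by source —
   reference animal model (Hock/Vogel reference works) vs phenotype
   endpoint term.
3. **MeSH mapping** — each assay inherits the deduplicated union of its
   classes' MeSH descriptor labels, plus a term → MeSH-tree-category
   crosswalk for breakdowns.
4. **Reporting** — corpus coverage (annotated / by model / by endpoint / by
   both, as percentages of all identified assays) and frequency breakdowns
   with low-frequency "Other" grouping (< 2% for level-1 headings, < 3% for
   MeSH tree categories, configurable).
5. **Evaluation** — a 2×2 confusion matrix of the binary pipeline-annotated
   vs curator-labelled decision, with sensitivity TP/(TP+FN), specificity
   TN/(TN+FP), precision TP/(TP+FP), F1 = 2TP/(2TP+FP+FN); excluded gold
   rows (assays found not to be in vivo) are never scored.

A deterministic synthetic-corpus generator with planted ground truth
(`generate_corpus()`, `generate_gold()`) makes the whole pipeline testable
without any database connection.

## Worked example

Ten worked-example assay descriptions ship with the package. The tail-flick
description hits two classes — the Radiant Heat Method reference model and
the general analgesic-activity endpoint:

```r
library(invivoclass)
dict <- seed_dictionary()
annotate_description("Analgesic activity in tail flick test, oral administration", dict)
#> # A tibble: 2 × 3
#>   assay_class_id matched_text pattern_index
#>   <chr>          <chr>                <int>
#> 1 AC_RADHEAT     tail flick               1
#> 2 AC_ANALG       Analgesi                 1
```

Running identification and annotation over the ten examples reproduces
their known outcome mix (2 model-only, 2 endpoint-only, 4 both,
2 unannotatable):

```r
ann <- annotate_corpus(identify_corpus(example_assays())$accepted, dict)
coverage_summary(ann)
#> In vivo assay corpus: 10 assays
#>   annotated:        8 (80.0%)
#>   unannotated:      2 (20.0%)
#>   by reference animal model:      6 (60%)
#>   by phenotype endpoint:          6 (60%)
#>   by both:                        4 (40%)
```

Evaluation statistics from a validation confusion matrix:

```r
classification_stats(confusion_cells(tp = 315, fn = 63, fp = 36, tn = 74))
#> Classification statistics
#>   sensitivity: 0.83
#>   specificity: 0.67
#>   precision:   0.90
#>   F1 score:    0.86
```

Meaning: of the curator-positive assays, 83% were also annotated by the
pipeline; of the pipeline's annotations, 90% were confirmed by a curator.

A thin command-line front end (`inst/cli/invivoclass.R`) exposes the stages
as subcommands (`identify`, `annotate`, `mesh`, `report`, `evaluate`,
`simulate`, `run`), all reading and writing the package's TSV schemas.

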