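#' Pipeline configuration
#'
#' Collects the file paths and tuning knobs for one end-to-end run:
#' identification -> annotation -> MeSH mapping -> reporting (-> evaluation
#' when a gold file is configured).
#'
#' @param assays_file Assay-record TSV (required).
#' @param dictionary_file Classification-dictionary TSV; `NULL` uses the
#'   packaged [seed_dictionary()].
#' @param gold_file Optional curator gold-standard TSV; enables evaluation.
#' @param tree_codes_file Optional MeSH tree-code crosswalk TSV; `NULL` uses
#'   the packaged [mesh_tree_codes()].
#' @param out_dir Output directory (created if absent).
#' @param bao_id,mammal_label,src_ids Identification options, see
#'   [filter_options()].
#' @param level1_threshold,mesh_threshold "Other"-grouping cutoffs in percent
#'   for the level-1 and MeSH breakdowns (defaults 2 and 3).
#' @param strict_missing Passed to [confusion_matrix()].
#' @return A list of class `invivo_config`.
#' @export
pipeline_config <- function(assays_file,
                            dictionary_file = NULL,
                            gold_file = NULL,
                            tree_codes_file = NULL,
                            out_dir = ".",
                            bao_id = "BAO_0000218",
                            mammal_label = "Mammalia",
                            src_ids = 1L,
                            level1_threshold = 2,
                            mesh_threshold = 3,
                            strict_missing = FALSE) {
  stopifnot(level1_threshold >= 0, level1_threshold <= 100,
            mesh_threshold >= 0, mesh_threshold <= 100)
  structure(
    list(assays_file = assays_file, dictionary_file = dictionary_file,
         gold_file = gold_file, tree_codes_file = tree_codes_file,
         out_dir = out_dir,
         bao_id = bao_id, mammal_label = mammal_label,
         src_ids = as.integer(src_ids),
         level1_threshold = level1_threshold,
         mesh_threshold = mesh_threshold,
         strict_missing = isTRUE(strict_missing)),
    class = "invivo_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level YAML keys mirror the [pipeline_config()] arguments.
#'
#' @param path YAML file.
#' @return An `invivo_config` object.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), allowed)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

breakdown_block <- function(b) {
  list(rows = lapply(seq_len(nrow(b)), function(i) {
    list(label = b$label[i], count = b$count[i], percentage = b$percentage[i])
  }),
  threshold_pct = attr(b, "threshold_pct"),
  grouped_labels = as.list(attr(b, "grouped_labels")))
}

#' Run the full curation pipeline
#'
#' Executes identification, annotation, MeSH mapping and reporting (and
#' evaluation when a gold file is configured), writing every stage output
#' plus a JSON run manifest into `out_dir`. Output data files contain no
#' timestamps, so repeated runs on identical inputs are byte-identical.
#'
#' Files written: `accepted_assays.tsv`, `decisions.tsv`, `mapping.tsv`,
#' `summary.tsv`, `mesh.tsv`, `report.json`, `evaluation.json` (with gold),
#' `manifest.json`.
#'
#' @param config An [pipeline_config()] object.
#' @param quiet Suppress the one-line-per-stage log messages.
#' @return Invisibly, a list with the in-memory stage results (`identified`,
#'   `annotation`, `mesh`, `coverage`, `breakdown_level1`, `breakdown_mesh`,
#'   `evaluation` or `NULL`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "invivo_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  assays <- stage("read", read_table(config$assays_file, "assays"))
  dictionary <- stage("read", {
    if (is.null(config$dictionary_file)) seed_dictionary()
    else read_dictionary_file(config$dictionary_file)
  })
  tree_codes <- stage("read", {
    if (is.null(config$tree_codes_file)) mesh_tree_codes()
    else read_tree_codes_file(config$tree_codes_file)
  })

  opts <- filter_options(bao_id = config$bao_id,
                         mammal_label = config$mammal_label,
                         src_ids = config$src_ids)
  identified <- stage("identify", identify_corpus(assays, opts))
  say("identify: %d of %d assays accepted",
      nrow(identified$accepted), nrow(assays))
  write_table(identified$accepted,
              file.path(config$out_dir, "accepted_assays.tsv"), "assays")
  write_table(identified$decisions,
              file.path(config$out_dir, "decisions.tsv"), "decisions")

  annotation <- stage("annotate",
                      annotate_corpus(identified$accepted, dictionary))
  say("annotate: %d hits on %d of %d assays", nrow(annotation$hits),
      sum(annotation$summary$annotated), nrow(annotation$summary))
  write_table(annotation$hits[, c("assay_id", "assay_class_id",
                                  "matched_text", "pattern_index")],
              file.path(config$out_dir, "mapping.tsv"), "mapping")
  write_table(annotation$summary,
              file.path(config$out_dir, "summary.tsv"), "summary")

  mesh <- stage("mesh", mesh_corpus(annotation, dictionary))
  say("mesh: %d assays carry MeSH terms", sum(nzchar(mesh$mesh_terms)))
  write_table(mesh, file.path(config$out_dir, "mesh.tsv"), "mesh")

  coverage <- stage("report", {
    if (nrow(annotation$summary) > 0L) coverage_summary(annotation)
    else NULL
  })
  b_l1 <- stage("report", breakdown(level1_pairs(annotation, dictionary),
                                    config$level1_threshold))
  b_mesh <- stage("report", breakdown(
    suppressWarnings(mesh_tree_pairs(mesh, tree_codes)),
    config$mesh_threshold))
  report <- list(
    coverage = if (is.null(coverage)) NULL else
      c(coverage[c("n_total", "n_annotated", "n_unannotated", "n_model",
                   "n_phenotype", "n_both")],
        as.list(format_coverage(coverage))),
    breakdown_level1 = breakdown_block(b_l1),
    breakdown_mesh_tree = breakdown_block(b_mesh)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  say("report: written (level-1 rows: %d, MeSH rows: %d)",
      nrow(b_l1), nrow(b_mesh))

  evaluation <- NULL
  if (!is.null(config$gold_file)) {
    evaluation <- stage("evaluate", {
      gold <- read_table(config$gold_file, "gold")
      cm <- confusion_matrix(annotation$summary, gold,
                             strict_missing = config$strict_missing)
      list(matrix = cm, stats = classification_stats(cm))
    })
    jsonlite::write_json(
      list(matrix = evaluation$matrix[c("tp", "fn", "fp", "tn", "n_scored",
                                        "n_excluded")],
           stats = lapply(unclass(evaluation$stats),
                          function(v) if (is.na(v)) NULL else v)),
      file.path(config$out_dir, "evaluation.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    say("evaluate: TP=%d FN=%d FP=%d TN=%d (%d scored, %d excluded)",
        evaluation$matrix$tp, evaluation$matrix$fn, evaluation$matrix$fp,
        evaluation$matrix$tn, evaluation$matrix$n_scored,
        evaluation$matrix$n_excluded)
  } else {
    say("evaluate: skipped (no gold file configured)")
  }

  manifest <- list(
    package = "invivoclass",
    version = as.character(utils::packageVersion("invivoclass")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    counts = list(
      n_input = nrow(assays),
      n_accepted = nrow(identified$accepted),
      n_annotated = sum(annotation$summary$annotated),
      n_hits = nrow(annotation$hits),
      n_mesh_assays = nrow(mesh)
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  invisible(list(identified = identified, annotation = annotation,
                 mesh = mesh, coverage = coverage,
                 breakdown_level1 = b_l1, breakdown_mesh = b_mesh,
                 evaluation = evaluation, manifest = manifest))
}
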