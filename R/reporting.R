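#' Corpus coverage statistics and frequency breakdowns
#'
#' Reporting summarises an annotated corpus the way the dataset release
#' figures do: an overall coverage block (how many identified assays carry any
#' annotation, a reference-animal-model annotation, a phenotype-endpoint
#' annotation, or both — all as percentages of the total identified corpus),
#' and per-axis frequency breakdowns (level-1 assay-classification headings;
#' top-level MeSH tree categories) in which low-frequency labels are grouped
#' into an "Other" row below a configurable percentage threshold (2% for
#' level-1 headings, 3% for MeSH categories by default).
#'
#' Percentages are returned at full precision; [format_coverage()] applies the
#' display rounding (one decimal for overall coverage, nearest integer for the
#' model/phenotype/both shares).
#'
#' @name reporting
NULL

#' Coverage statistics from raw counts
#'
#' @param n_total Total number of identified in vivo assays (percentage base).
#' @param n_annotated Assays with at least one annotation hit.
#' @param n_model Assays with at least one reference-animal-model hit.
#' @param n_phenotype Assays with at least one phenotype-endpoint hit.
#' @param n_both Assays with both kinds of hit.
#' @return A list of class `invivo_coverage` with the counts, `n_unannotated`,
#'   and full-precision percentages `pct_annotated`, `pct_unannotated`,
#'   `pct_model`, `pct_phenotype`, `pct_both` (base `n_total`).
#' @export
coverage_stats <- function(n_total, n_annotated, n_model, n_phenotype,
                           n_both) {
  if (n_total <= 0L) {
    stop("n_total must be positive: percentages are undefined on an empty corpus",
         call. = FALSE)
  }
  stopifnot(n_annotated <= n_total,
            n_both <= min(n_model, n_phenotype),
            n_annotated <= n_model + n_phenotype || n_annotated == 0)
  structure(
    list(
      n_total = n_total,
      n_annotated = n_annotated,
      n_unannotated = n_total - n_annotated,
      n_model = n_model,
      n_phenotype = n_phenotype,
      n_both = n_both,
      pct_annotated = 100 * n_annotated / n_total,
      pct_unannotated = 100 * (n_total - n_annotated) / n_total,
      pct_model = 100 * n_model / n_total,
      pct_phenotype = 100 * n_phenotype / n_total,
      pct_both = 100 * n_both / n_total
    ),
    class = "invivo_coverage"
  )
}

#' Coverage statistics of an annotated corpus
#'
#' Tallies the per-assay annotation flags of an annotation summary.
#'
#' @param annotation An `invivo_annotation` object or its `summary` tibble.
#' @param n_total Percentage base; defaults to the number of rows in the
#'   summary, and must be at least that (the summary may cover only the
#'   annotated subset of a larger identified corpus).
#' @return An `invivo_coverage` object (see [coverage_stats()]).
#' @export
coverage_summary <- function(annotation, n_total = NULL) {
  s <- if (inherits(annotation, "invivo_annotation")) annotation$summary
       else tibble::as_tibble(annotation)
  if (is.null(n_total)) n_total <- nrow(s)
  if (n_total < nrow(s)) {
    stop("n_total is smaller than the number of assays in the annotation table",
         call. = FALSE)
  }
  coverage_stats(
    n_total = n_total,
    n_annotated = sum(s$annotated),
    n_model = sum(s$has_model_annotation),
    n_phenotype = sum(s$has_phenotype_annotation),
    n_both = sum(s$has_model_annotation & s$has_phenotype_annotation)
  )
}

#' Display rounding for coverage statistics
#'
#' Overall annotated/unannotated shares are shown to one decimal place; the
#' model / phenotype / both shares to the nearest integer, matching the
#' release-figure style.
#'
#' @param cov An `invivo_coverage` object.
#' @return Named numeric vector of rounded display percentages.
#' @export
format_coverage <- function(cov) {
  stopifnot(inherits(cov, "invivo_coverage"))
  c(pct_annotated = round(cov$pct_annotated, 1),
    pct_unannotated = round(cov$pct_unannotated, 1),
    pct_model = round(cov$pct_model),
    pct_phenotype = round(cov$pct_phenotype),
    pct_both = round(cov$pct_both))
}

#' @export
print.invivo_coverage <- function(x, ...) {
  f <- format_coverage(x)
  cat(sprintf("In vivo assay corpus: %d assays\n", x$n_total))
  cat(sprintf("  annotated:   %6d (%.1f%%)\n", x$n_annotated, f["pct_annotated"]))
  cat(sprintf("  unannotated: %6d (%.1f%%)\n", x$n_unannotated, f["pct_unannotated"]))
  cat(sprintf("  by reference animal model: %6d (%d%%)\n", x$n_model, f["pct_model"]))
  cat(sprintf("  by phenotype endpoint:     %6d (%d%%)\n", x$n_phenotype, f["pct_phenotype"]))
  cat(sprintf("  by both:                   %6d (%d%%)\n", x$n_both, f["pct_both"]))
  invisible(x)
}

#' Frequency breakdown with low-frequency "Other" grouping
#'
#' Counts distinct (assay, label) pairs — an assay contributes one count per
#' distinct label it maps to, so an assay with classes under two level-1
#' headings is counted under both. Labels whose share falls below
#' `threshold_pct` are merged into a single `"Other"` row; the labels grouped
#' there are recorded in the `grouped_labels` attribute.
#'
#' @param pairs Tibble with columns `assay_id` and `label` (duplicated pairs
#'   are collapsed). Use [level1_pairs()] or [mesh_tree_pairs()] to build it.
#' @param threshold_pct Grouping cutoff in percent, in `[0, 100]`. `0`
#'   disables grouping.
#' @param other_label Label of the aggregated row.
#' @return Tibble of class `invivo_breakdown` with columns `label`, `count`,
#'   `percentage` (full precision, base = total distinct pairs), sorted by
#'   decreasing count with the "Other" row last. Attributes: `threshold_pct`,
#'   `grouped_labels`.
#' @export
breakdown <- function(pairs, threshold_pct, other_label = "Other") {
  stopifnot(is.numeric(threshold_pct), length(threshold_pct) == 1L,
            threshold_pct >= 0, threshold_pct <= 100)
  pairs <- dplyr::distinct(
    tibble::as_tibble(pairs)[, c("assay_id", "label")])
  total <- nrow(pairs)
  if (total == 0L) {
    out <- tibble::tibble(label = character(0), count = integer(0),
                          percentage = numeric(0))
    return(structure(out, class = c("invivo_breakdown", class(out)),
                     threshold_pct = threshold_pct,
                     grouped_labels = character(0)))
  }
  tab <- pairs |>
    dplyr::count(.data$label, name = "count") |>
    dplyr::mutate(percentage = 100 * .data$count / total) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$label)
  low <- tab$percentage < threshold_pct
  grouped <- character(0)
  if (threshold_pct > 0 && any(low)) {
    grouped <- tab$label[low]
    other <- tibble::tibble(label = other_label,
                            count = sum(tab$count[low]),
                            percentage = sum(tab$percentage[low]))
    tab <- dplyr::bind_rows(tab[!low, , drop = FALSE], other)
  }
  structure(tab, class = c("invivo_breakdown", class(tab)),
            threshold_pct = threshold_pct, grouped_labels = grouped)
}

#' (assay, level-1 heading) pairs for a level-1 breakdown
#'
#' @param annotation An `invivo_annotation` object.
#' @param dictionary The dictionary used for annotation.
#' @return Tibble `assay_id`, `label` (the hit class's level-1 heading).
#' @export
level1_pairs <- function(annotation, dictionary) {
  stopifnot(inherits(annotation, "invivo_annotation"),
            inherits(dictionary, "invivo_dictionary"))
  hits <- annotation$hits
  tibble::tibble(
    assay_id = hits$assay_id,
    label = dictionary$level1[match(hits$assay_class_id,
                                    dictionary$assay_class_id)]
  )
}

#' (assay, MeSH tree code) pairs for a MeSH breakdown
#'
#' Expands each assay's MeSH terms through the term-to-tree-code crosswalk;
#' one term may contribute several codes (and several terms the same code —
#' pairs are deduplicated downstream by [breakdown()]). Terms absent from the
#' crosswalk are dropped with a warning.
#'
#' @param mesh_assignments Tibble from [mesh_corpus()].
#' @param tree_codes Crosswalk tibble (`mesh_term`, `tree_codes` list column),
#'   default [mesh_tree_codes()].
#' @return Tibble `assay_id`, `label` (tree code).
#' @export
mesh_tree_pairs <- function(mesh_assignments, tree_codes = mesh_tree_codes()) {
  long <- mesh_assignments |>
    dplyr::mutate(mesh_term = strsplit(.data$mesh_terms, ";", fixed = TRUE)) |>
    tidyr::unnest("mesh_term") |>
    dplyr::filter(nzchar(.data$mesh_term))
  idx <- match(long$mesh_term, tree_codes$mesh_term)
  if (anyNA(idx)) {
    warning("MeSH term(s) missing from the tree-code crosswalk: ",
            paste(unique(long$mesh_term[is.na(idx)]), collapse = ", "),
            call. = FALSE)
  }
  keep <- !is.na(idx)
  tibble::tibble(
    assay_id = rep(long$assay_id[keep],
                   lengths(tree_codes$tree_codes[idx[keep]])),
    label = unlist(tree_codes$tree_codes[idx[keep]])
  )
}
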