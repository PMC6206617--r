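#' MeSH descriptor mapping
#'
#' Each assay class in the dictionary may carry Medical Subject Heading (MeSH)
#' descriptor labels (stored uppercase, e.g. `INFLAMMATION`). An assay's MeSH
#' annotation is the deduplicated union of the terms of every class it was
#' annotated with — classes are the only route to MeSH terms. Labels are kept
#' byte-for-byte as stored in the dictionary; a separate term-to-tree-code
#' crosswalk (see [mesh_tree_codes()]) supplies the high-level MeSH tree
#' categories (e.g. `C04` Neoplasms) used by frequency breakdowns.
#'
#' @name mesh_mapping
NULL

#' MeSH terms for one assay's annotation hits
#'
#' @param hits Tibble of annotation hits for one assay (needs an
#'   `assay_class_id` column; typically from [annotate_description()]).
#' @param dictionary A compiled `invivo_dictionary`.
#' @return Character vector: the sorted, deduplicated union of the MeSH terms
#'   of all hit classes. Empty when there are no hits or no hit class carries
#'   terms.
#' @examples
#' dict <- seed_dictionary()
#' hits <- annotate_description(
#'   "Antiinflammatory activity as reduction of carrageenan-induced paw volume",
#'   dict)
#' mesh_for_assay(hits, dict)
#' @export
mesh_for_assay <- function(hits, dictionary) {
  stopifnot(inherits(dictionary, "invivo_dictionary"))
  ids <- unique(hits$assay_class_id)
  unknown <- setdiff(ids, dictionary$assay_class_id)
  if (length(unknown) > 0L) {
    stop("assay_class_id not in dictionary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  idx <- match(ids, dictionary$assay_class_id)
  sort(as.character(unique(unlist(dictionary$mesh_terms[idx]))))
}

#' MeSH assignments for an annotated corpus
#'
#' @param annotation An `invivo_annotation` object from [annotate_corpus()].
#' @param dictionary The dictionary used for annotation.
#' @return Tibble with one row per *annotated* assay, ordered by `assay_id`:
#'   `assay_id`, `mesh_terms` (semicolon-joined union), and
#'   `contributing_class_ids` (semicolon-joined). Assays whose classes carry
#'   no MeSH terms appear with an empty `mesh_terms` cell.
#' @export
mesh_corpus <- function(annotation, dictionary) {
  stopifnot(inherits(annotation, "invivo_annotation"))
  hits <- annotation$hits
  if (nrow(hits) == 0L) {
    return(tibble::tibble(assay_id = character(0),
                          mesh_terms = character(0),
                          contributing_class_ids = character(0)))
  }
  hits |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::summarise(
      mesh_terms = paste(mesh_for_assay(dplyr::pick("assay_class_id"),
                                        dictionary), collapse = ";"),
      contributing_class_ids = paste(sort(unique(.data$assay_class_id)),
                                     collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$assay_id)
}

#' The MeSH term-to-tree-code crosswalk shipped with the package
#'
#' A curated crosswalk from the seed dictionary's MeSH descriptor labels to
#' their top-level MeSH tree categories (e.g. `SEIZURES` sits in both `C10`
#' Nervous System Diseases and `C23` Pathological Conditions, Signs and
#' Symptoms). One term may map to several codes; breakdowns count each
#' (assay, code) pair. Covers seed-dictionary terms only — supply a fuller
#' table via [read_tree_codes_file()] for external dictionaries.
#'
#' @return Tibble with columns `mesh_term` and `tree_codes` (list column).
#' @export
mesh_tree_codes <- function() {
  path <- system.file("extdata", "mesh_tree_codes.tsv",
                      package = "invivoclass", mustWork = TRUE)
  read_tree_codes_file(path)
}
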