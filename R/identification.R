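#' Identification of in vivo pharmacology assays
#'
#' The in vivo assay dataset is carved out of a flat table of assay records by
#' five conjunctive filter clauses, mirroring the SQL used to extract the
#' dataset from a relational bioactivity database:
#'
#' 1. the BioAssay Ontology format is "organism-based format" (`BAO_0000218`);
#' 2. the assay organism *or* the target organism is classed `Mammalia` at
#'    level 2 of the organism-class hierarchy (the OR admits xenograft assays,
#'    where a human cell line is grafted into a mouse);
#' 3. the free-text description does not mention an in vitro or ex vivo
#'    experiment (pattern `in[ -]?vitro|ex[ -]?vivo`, case-insensitive);
#' 4. the assay type is not `'A'` (ADMET / pharmacokinetic assays);
#' 5. the record originates from extracted scientific literature
#'    (`src_id == 1`).
#'
#' Records with an empty description are *not* rejected by clause 3 (a regex
#' on missing text is vacuously false) but are flagged with a
#' `MISSING_DESCRIPTION` warning code because they cannot be annotated
#' downstream.
#'
#' @name identification
NULL

#: rejection-reason codes, in clause order
FILTER_REASONS <- c(
  "NOT_ORGANISM_FORMAT", "NOT_MAMMAL", "DESCRIPTION_EXCLUSION",
  "ADMET_TYPE", "NOT_LITERATURE", "MISSING_DESCRIPTION"
)

#' Does a description refer to an in vitro or ex vivo experiment?
#'
#' Applies the exclusion pattern `in[ -]?vitro|ex[ -]?vivo` case-insensitively
#' anywhere in the text. Vectorised over `text`.
#'
#' @param text Character vector of assay descriptions. `NA` and empty strings
#'   never match.
#' @return Logical vector, `TRUE` where the exclusion pattern matches.
#' @examples
#' description_exclusion_matches("Compound was evaluated in vitro for binding")
#' description_exclusion_matches("In vivo antimalarial activity in mice")
#' @export
description_exclusion_matches <- function(text) {
  stopifnot(is.character(text) || all(is.na(text)))
  out <- grepl("in[ -]?vitro|ex[ -]?vivo", text,
               ignore.case = TRUE, perl = TRUE)
  out[is.na(text)] <- FALSE
  out
}

#' Filter options for in vivo assay identification
#'
#' @param bao_id BioAssay Ontology identifier accepted as "organism-based
#'   format". Default `"BAO_0000218"`.
#' @param mammal_label Organism-class level-2 label accepted as mammalian.
#'   Default `"Mammalia"`.
#' @param case_insensitive_organism Compare organism labels case-insensitively?
#'   Default `FALSE`: the database stores the literal label.
#' @param src_ids Integer vector of admitted source codes. Default `1`
#'   (extracted scientific literature); deposited datasets carry other codes.
#' @return A list of class `invivo_filter_options`.
#' @export
filter_options <- function(bao_id = "BAO_0000218",
                           mammal_label = "Mammalia",
                           case_insensitive_organism = FALSE,
                           src_ids = 1L) {
  stopifnot(length(bao_id) == 1L, nzchar(bao_id),
            length(mammal_label) == 1L, nzchar(mammal_label),
            length(src_ids) >= 1L)
  structure(
    list(bao_id = bao_id, mammal_label = mammal_label,
         case_insensitive_organism = isTRUE(case_insensitive_organism),
         src_ids = as.integer(src_ids)),
    class = "invivo_filter_options"
  )
}

# level-2 organism label comparison; absent labels (NA/"") never match
organism_matches <- function(label, options) {
  label <- ifelse(is.na(label), "", label)
  if (options$case_insensitive_organism) {
    tolower(label) == tolower(options$mammal_label)
  } else {
    label == options$mammal_label
  }
}

#' Decide whether one assay record belongs to the in vivo dataset
#'
#' Evaluates all five filter clauses on a single record and returns the
#' decision together with every rejection-reason code that applies, so the
#' outcome is auditable clause by clause.
#'
#' @param record A one-row data frame (or list) with fields `assay_id`,
#'   `description`, `assay_type`, `bao_format`, `assay_organism_l2`,
#'   `target_organism_l2`, `src_id`. Empty string or `NA` encodes an absent
#'   value.
#' @param options A [filter_options()] object.
#' @return A list with `assay_id`, `accepted` (logical) and `reasons`
#'   (character vector of codes; `MISSING_DESCRIPTION` is a warning that does
#'   not by itself reject).
#' @export
is_in_vivo_candidate <- function(record, options = filter_options()) {
  record <- as.list(record)
  if (is.null(record$assay_id) || is.na(record$assay_id) ||
      !nzchar(record$assay_id)) {
    stop("assay record has a missing or empty `assay_id`", call. = FALSE)
  }
  desc <- record$description %||% NA_character_
  reasons <- character(0)
  bao <- record$bao_format %||% NA_character_
  if (is.na(bao) || bao != options$bao_id) {
    reasons <- c(reasons, "NOT_ORGANISM_FORMAT")
  }
  if (!(organism_matches(record$assay_organism_l2 %||% NA_character_, options) ||
        organism_matches(record$target_organism_l2 %||% NA_character_, options))) {
    reasons <- c(reasons, "NOT_MAMMAL")
  }
  if (isTRUE(description_exclusion_matches(desc))) {
    reasons <- c(reasons, "DESCRIPTION_EXCLUSION")
  }
  if (identical(as.character(record$assay_type %||% NA_character_), "A")) {
    reasons <- c(reasons, "ADMET_TYPE")
  }
  src <- suppressWarnings(as.integer(record$src_id %||% NA_integer_))
  if (is.na(src) || !(src %in% options$src_ids)) {
    reasons <- c(reasons, "NOT_LITERATURE")
  }
  if (is.na(desc) || !nzchar(trimws(desc))) {
    reasons <- c(reasons, "MISSING_DESCRIPTION")
  }
  accepted <- length(setdiff(reasons, "MISSING_DESCRIPTION")) == 0L
  list(assay_id = record$assay_id, accepted = accepted, reasons = reasons)
}

#' Identify the in vivo assay subset of a corpus
#'
#' Applies [is_in_vivo_candidate()] to every record. Duplicate `assay_id`s
#' (the SQL emits DISTINCT identifiers) collapse to their first occurrence
#' with a warning; input order is preserved.
#'
#' @param records Tibble of assay records (see [assay_schema()]).
#' @param options A [filter_options()] object.
#' @return A list with `accepted` (tibble of accepted records, input order,
#'   one row per distinct `assay_id`) and `decisions` (tibble `assay_id`,
#'   `accepted`, `reasons` — reason codes semicolon-joined, one row per
#'   distinct input `assay_id`).
#' @examples
#' corpus <- example_assays()
#' res <- identify_corpus(corpus)
#' res$decisions
#' @export
identify_corpus <- function(records, options = filter_options()) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    return(list(
      accepted = records,
      decisions = tibble::tibble(assay_id = character(0),
                                 accepted = logical(0),
                                 reasons = character(0))
    ))
  }
  dup <- duplicated(records$assay_id)
  if (any(dup)) {
    warning(sprintf("%d duplicate assay_id(s) collapsed to first occurrence",
                    sum(dup)), call. = FALSE)
    records <- records[!dup, , drop = FALSE]
  }
  decisions <- purrr::map(seq_len(nrow(records)), function(i) {
    d <- is_in_vivo_candidate(records[i, ], options)
    tibble::tibble(assay_id = d$assay_id, accepted = d$accepted,
                   reasons = paste(d$reasons, collapse = ";"))
  })
  decisions <- dplyr::bind_rows(decisions)
  list(
    accepted = records[decisions$accepted, , drop = FALSE],
    decisions = decisions
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
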