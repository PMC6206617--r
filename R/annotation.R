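#' Pattern-dictionary annotation of assay descriptions
#'
#' Annotation is rule based: a curated dictionary maps each three-level assay
#' class (level 1 broad category, level 2 group, level 3 specific model or
#' endpoint) to one or more regular-expression patterns that uniquely identify
#' it inside a free-text assay description. Two kinds of class are
#' distinguished by their `source`:
#'
#' * **reference animal models** described in the Hock/Vogel reference works
#'   (`Hock_2016`, `Vogel_2008`, `Vogel_2013`), e.g. the Tail Flick test
#'   recognised by `[Tt]ail\W?[Ff]lick`;
#' * **phenotype endpoints** (`phenotype`), common disease/phenotype terms
#'   such as "analgesia" or "hepatotoxicity".
#'
#' Annotation is multi-label: a description may hit any number of classes, and
#' all hits are kept. Patterns are matched exactly as written (case variation
#' is encoded inside the pattern, e.g. `[Tt]ail`); a per-entry `pattern_flags`
#' column may set `i` to match a simple phenotype term case-insensitively.
#'
#' @name annotation
NULL

MODEL_SOURCES <- c("Hock_2016", "Vogel_2008", "Vogel_2013")
DICT_SOURCES <- c(MODEL_SOURCES, "phenotype")

check_regex <- function(pattern, ignore_case = FALSE) {
  ok <- tryCatch(
    {
      grepl(pattern, "", perl = TRUE, ignore.case = ignore_case)
      TRUE
    },
    error = function(e) conditionMessage(e),
    warning = function(w) conditionMessage(w)
  )
  ok
}

#' Compile a classification dictionary
#'
#' Validates and compiles a tabular classification dictionary into the form
#' used by the annotators. Every pattern must compile as a regular expression;
#' `assay_class_id` must be unique; the three level headings must be
#' non-empty. Entry order is preserved.
#'
#' @param rows Tibble with columns `assay_class_id`, `level1`, `level2`,
#'   `level3`, `source`, `patterns` (character, pipe-separated, or a list
#'   column of character vectors), and optionally `pattern_flags` (`""` or
#'   `"i"`), `mesh_terms`, `inducer_compounds`, `control_compounds`
#'   (semicolon-separated or list columns) and `provenance`.
#' @return A tibble of class `invivo_dictionary` with list columns `patterns`
#'   and `mesh_terms` etc., plus a logical `is_model` column (`TRUE` for
#'   Hock/Vogel reference-animal-model sources).
#' @seealso [seed_dictionary()] for the dictionary shipped with the package,
#'   [read_dictionary_file()] for loading an external one.
#' @export
load_dictionary <- function(rows) {
  rows <- tibble::as_tibble(rows)
  required <- c("assay_class_id", "level1", "level2", "level3", "source",
                "patterns")
  missing <- setdiff(required, names(rows))
  if (length(missing) > 0L) {
    stop("dictionary is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- unique(rows$assay_class_id[duplicated(rows$assay_class_id)])
  if (length(dup) > 0L) {
    stop("duplicate assay_class_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("level1", "level2", "level3")) {
    bad <- is.na(rows[[col]]) | !nzchar(trimws(rows[[col]]))
    if (any(bad)) {
      stop(sprintf("empty `%s` heading for assay_class_id %s", col,
                   paste(rows$assay_class_id[bad], collapse = ", ")),
           call. = FALSE)
    }
  }
  # normalise the source enumeration (tables occasionally print "Phenotype")
  src <- DICT_SOURCES[match(tolower(rows$source), tolower(DICT_SOURCES))]
  if (anyNA(src)) {
    stop("unknown source label(s): ",
         paste(unique(rows$source[is.na(src)]), collapse = ", "),
         call. = FALSE)
  }
  rows$source <- src
  rows$patterns <- split_multi(rows$patterns, "|", fixed = TRUE)
  if (!"pattern_flags" %in% names(rows)) rows$pattern_flags <- ""
  rows$pattern_flags[is.na(rows$pattern_flags)] <- ""
  for (col in c("mesh_terms", "inducer_compounds", "control_compounds")) {
    if (!col %in% names(rows)) rows[[col]] <- ""
    rows[[col]] <- split_multi(rows[[col]], ";")
  }
  if (!"provenance" %in% names(rows)) rows$provenance <- "repo"
  for (i in seq_len(nrow(rows))) {
    pats <- rows$patterns[[i]]
    if (length(pats) == 0L) {
      stop("assay_class_id ", rows$assay_class_id[i], " has no pattern",
           call. = FALSE)
    }
    ic <- grepl("i", rows$pattern_flags[i], fixed = TRUE)
    for (j in seq_along(pats)) {
      ok <- check_regex(pats[j], ic)
      if (!isTRUE(ok)) {
        stop(sprintf("invalid regex for assay_class_id %s, pattern %d (%s): %s",
                     rows$assay_class_id[i], j, pats[j], ok), call. = FALSE)
      }
    }
  }
  rows$is_model <- rows$source %in% MODEL_SOURCES
  class(rows) <- c("invivo_dictionary", class(rows))
  rows
}

# split pipe-/semicolon-joined cells into list columns; "" -> character(0)
split_multi <- function(x, sep, fixed = FALSE) {
  if (is.list(x)) return(lapply(x, as.character))
  x <- ifelse(is.na(x), "", x)
  lapply(strsplit(x, sep, fixed = fixed), function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

#' The seed classification dictionary shipped with the package
#'
#' Covers every assay class printed in the source publication's worked
#' examples (reference animal models such as the Tail Flick / Radiant Heat
#' Method, Paw Edema Test or CCl4-induced liver fibrosis, and phenotype
#' endpoints such as general analgesic or antimalarial activity), together
#' with their MeSH descriptor terms and, where applicable, inducer and
#' positive-control compounds. Full production dictionaries are loaded with
#' [read_dictionary_file()].
#'
#' @return A compiled `invivo_dictionary`.
#' @export
seed_dictionary <- function() {
  path <- system.file("extdata", "assay_classification_seed.tsv",
                      package = "invivoclass", mustWork = TRUE)
  read_dictionary_file(path)
}

annotate_one <- function(description, dictionary) {
  if (is.na(description) || !nzchar(description)) {
    return(tibble::tibble(assay_class_id = character(0),
                          matched_text = character(0),
                          pattern_index = integer(0)))
  }
  hits <- vector("list", nrow(dictionary))
  n <- 0L
  for (i in seq_len(nrow(dictionary))) {
    pats <- dictionary$patterns[[i]]
    ic <- grepl("i", dictionary$pattern_flags[i], fixed = TRUE)
    for (j in seq_along(pats)) {
      m <- regexpr(pats[j], description, perl = TRUE, ignore.case = ic)
      if (m[1] != -1L) {
        n <- n + 1L
        hits[[n]] <- tibble::tibble(
          assay_class_id = dictionary$assay_class_id[i],
          matched_text = substr(description, m[1],
                                m[1] + attr(m, "match.length") - 1L),
          pattern_index = j
        )
        break  # one hit per entry: first pattern that fires
      }
    }
  }
  if (n == 0L) {
    return(tibble::tibble(assay_class_id = character(0),
                          matched_text = character(0),
                          pattern_index = integer(0)))
  }
  dplyr::bind_rows(hits[seq_len(n)])
}

#' Annotate a single assay description
#'
#' Runs every dictionary pattern against the description. An entry contributes
#' at most one hit (its first matching pattern, lowest index, leftmost match);
#' all matching entries are reported (multi-label).
#'
#' @param description Free-text assay description (length-1 character).
#' @param dictionary A compiled `invivo_dictionary` (see [load_dictionary()]).
#' @return Tibble of hits with columns `assay_class_id`, `matched_text` (the
#'   exact matching substring), `pattern_index`. Zero rows when nothing
#'   matches (including the empty description).
#' @examples
#' dict <- seed_dictionary()
#' annotate_description(
#'   "Analgesic activity in tail flick test, oral administration", dict)
#' @export
annotate_description <- function(description, dictionary) {
  stopifnot(inherits(dictionary, "invivo_dictionary"),
            length(description) == 1L)
  annotate_one(as.character(description), dictionary)
}

#' Annotate an identified in vivo assay corpus
#'
#' Applies the dictionary to every record's description and derives the
#' per-assay annotation flags used throughout reporting and evaluation:
#' `has_model_annotation` (at least one hit on a Hock/Vogel reference animal
#' model), `has_phenotype_annotation` (at least one hit on a phenotype
#' endpoint) and `annotated` (either).
#'
#' @param assays Tibble of assay records that already passed identification
#'   (membership is not re-checked).
#' @param dictionary A compiled `invivo_dictionary`.
#' @return A list of class `invivo_annotation` with
#'   * `hits`: tibble `assay_id`, `assay_class_id`, `matched_text`,
#'     `pattern_index`, sorted by (`assay_id`, `assay_class_id`);
#'   * `summary`: one row per input assay — `assay_id`, `annotated`,
#'     `has_model_annotation`, `has_phenotype_annotation`, `class_ids`
#'     (semicolon-joined), in input order.
#' @export
annotate_corpus <- function(assays, dictionary) {
  stopifnot(inherits(dictionary, "invivo_dictionary"))
  assays <- tibble::as_tibble(assays)
  hit_list <- purrr::map(seq_len(nrow(assays)), function(i) {
    h <- annotate_one(assays$description[i], dictionary)
    if (nrow(h) > 0L) h$assay_id <- assays$assay_id[i]
    h
  })
  hits <- dplyr::bind_rows(hit_list)
  if (nrow(hits) == 0L) {
    hits <- tibble::tibble(assay_id = character(0),
                           assay_class_id = character(0),
                           matched_text = character(0),
                           pattern_index = integer(0))
  } else {
    hits <- dplyr::arrange(
      dplyr::select(hits, "assay_id", "assay_class_id", "matched_text",
                    "pattern_index"),
      .data$assay_id, .data$assay_class_id)
  }
  is_model <- stats::setNames(dictionary$is_model, dictionary$assay_class_id)
  summary <- purrr::map(seq_len(nrow(assays)), function(i) {
    h <- hit_list[[i]]
    model <- nrow(h) > 0L && any(is_model[h$assay_class_id])
    pheno <- nrow(h) > 0L && any(!is_model[h$assay_class_id])
    tibble::tibble(
      assay_id = assays$assay_id[i],
      annotated = nrow(h) > 0L,
      has_model_annotation = model,
      has_phenotype_annotation = pheno,
      class_ids = paste(sort(h$assay_class_id), collapse = ";")
    )
  })
  summary <- dplyr::bind_rows(summary)
  if (nrow(assays) == 0L) {
    summary <- tibble::tibble(assay_id = character(0), annotated = logical(0),
                              has_model_annotation = logical(0),
                              has_phenotype_annotation = logical(0),
                              class_ids = character(0))
  }
  structure(list(hits = hits, summary = summary), class = "invivo_annotation")
}
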