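#' Flat-file schemas and readers/writers
#'
#' All pipeline files are UTF-8, tab-delimited, header-first, unquoted TSV —
#' descriptions frequently contain commas, so TSV is the primary dialect.
#' Multi-valued cells are semicolon-joined (MeSH terms, compounds, class ids,
#' reason codes) except regex pattern lists, which are pipe-joined (patterns
#' themselves may not contain a literal `|`; use multiple patterns instead of
#' top-level alternation). The empty string encodes an absent value. Embedded
#' tabs in any value are rejected at read and write time.
#'
#' @name io
NULL

# column typing per schema; unknown extra columns are preserved as character
SCHEMAS <- list(
  assays = list(
    required = c("assay_id", "description", "assay_type", "bao_format",
                 "assay_organism_l2", "target_organism_l2", "src_id"),
    integer = "src_id", logical = character(0)
  ),
  dictionary = list(
    required = c("assay_class_id", "level1", "level2", "level3", "source",
                 "patterns"),
    integer = character(0), logical = character(0)
  ),
  decisions = list(
    required = c("assay_id", "accepted", "reasons"),
    integer = character(0), logical = "accepted"
  ),
  summary = list(
    required = c("assay_id", "annotated", "has_model_annotation",
                 "has_phenotype_annotation", "class_ids"),
    integer = character(0),
    logical = c("annotated", "has_model_annotation",
                "has_phenotype_annotation")
  ),
  mapping = list(
    required = c("assay_id", "assay_class_id", "matched_text"),
    integer = "pattern_index", logical = character(0)
  ),
  mesh = list(
    required = c("assay_id", "mesh_terms", "contributing_class_ids"),
    integer = character(0), logical = character(0)
  ),
  gold = list(
    required = c("assay_id", "curator_positive"),
    integer = character(0), logical = c("curator_positive", "excluded")
  ),
  tree_codes = list(
    required = c("mesh_term", "tree_codes"),
    integer = character(0), logical = character(0)
  ),
  truth = list(
    required = c("assay_id", "accepted", "reasons", "class_ids", "annotated",
                 "has_model_annotation", "has_phenotype_annotation"),
    integer = character(0),
    logical = c("accepted", "annotated", "has_model_annotation",
                "has_phenotype_annotation")
  )
)

#' Names of the file schemas understood by [read_table()]
#' @return Character vector of schema names.
#' @export
schema_names <- function() names(SCHEMAS)

#' Required columns of the assay-record schema
#'
#' The flat assay table carries the columns the identification filters need,
#' pre-joined from their relational origin: `assay_id` (assay identifier),
#' `description` (free text), `assay_type` (single-character code; `A` =
#' ADMET), `bao_format` (BioAssay Ontology format id), `assay_organism_l2` /
#' `target_organism_l2` (organism-class level-2 labels for the assay and
#' target organism), `src_id` (integer source code; 1 = literature).
#' @return Character vector of column names.
#' @export
assay_schema <- function() SCHEMAS$assays$required

#' Read a pipeline TSV
#'
#' @param path File path.
#' @param schema One of [schema_names()].
#' @return Tibble with the schema's typed columns; extra columns are kept as
#'   character; row order preserved. Errors name any missing required column;
#'   a row whose field count disagrees with the header is reported with its
#'   line number.
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(SCHEMAS))
  sch <- SCHEMAS[[schema]]
  lines <- readr::read_lines(path)
  if (length(lines) == 0L) {
    stop("empty file (no header): ", path, call. = FALSE)
  }
  n_fields <- lengths(strsplit(paste0(lines, "\t."), "\t", fixed = TRUE)) - 1L
  bad <- which(n_fields != n_fields[1])
  if (length(bad) > 0L) {
    stop(sprintf("malformed row in %s: line %d has %d fields, header has %d",
                 path, bad[1], n_fields[bad[1]], n_fields[1]), call. = FALSE)
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()),
    na = character(), quote = "", progress = FALSE)
  missing <- setdiff(sch$required, names(tab))
  if (length(missing) > 0L) {
    stop(sprintf("%s file %s is missing required column(s): %s",
                 schema, path, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (col in intersect(sch$integer, names(tab))) {
    tab[[col]] <- as.integer(tab[[col]])
  }
  for (col in intersect(sch$logical, names(tab))) {
    tab[[col]] <- parse_logical01(tab[[col]], col, path)
  }
  tab
}

parse_logical01 <- function(x, col, path) {
  out <- dplyr::case_match(tolower(x),
                           c("1", "true") ~ TRUE,
                           c("0", "false", "") ~ FALSE,
                           .default = NA)
  if (anyNA(out)) {
    stop(sprintf("column `%s` in %s must be 0/1: got \"%s\"",
                 col, path, x[which(is.na(out))[1]]), call. = FALSE)
  }
  out
}

#' Write a pipeline TSV
#'
#' Logical columns are written as 0/1; list columns are joined with the
#' schema's delimiter. Values containing a tab (or, for multi-valued cells,
#' their join delimiter) are rejected so files stay escape-free.
#'
#' @param records Tibble to write.
#' @param path Output path.
#' @param schema One of [schema_names()].
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, schema) {
  schema <- match.arg(schema, names(SCHEMAS))
  sch <- SCHEMAS[[schema]]
  records <- tibble::as_tibble(records)
  missing <- setdiff(sch$required, names(records))
  if (length(missing) > 0L) {
    stop(sprintf("cannot write %s file: missing column(s) %s",
                 schema, paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- records
  for (col in names(out)) {
    if (is.list(out[[col]])) {
      sep <- if (col == "patterns") "|" else ";"
      joined <- vapply(out[[col]], function(v) {
        v <- as.character(v)
        if (any(grepl(sep, v, fixed = TRUE))) {
          stop(sprintf("value in multi-valued column `%s` contains its delimiter \"%s\"",
                       col, sep), call. = FALSE)
        }
        paste(v, collapse = sep)
      }, character(1))
      out[[col]] <- joined
    } else if (is.logical(out[[col]])) {
      out[[col]] <- as.integer(out[[col]])
    }
  }
  chr <- vapply(out, is.character, logical(1))
  if (any(vapply(out[chr], function(v) any(grepl("\t", v, fixed = TRUE)),
                 logical(1)))) {
    stop("values may not contain embedded tab characters", call. = FALSE)
  }
  readr::write_tsv(out, path, na = "", quote = "none", progress = FALSE)
  invisible(path)
}

#' Read and compile a classification dictionary file
#' @param path Dictionary TSV (see [load_dictionary()] for columns).
#' @return A compiled `invivo_dictionary`.
#' @export
read_dictionary_file <- function(path) {
  load_dictionary(read_table(path, "dictionary"))
}

#' Read a MeSH term-to-tree-code crosswalk file
#' @param path TSV with columns `mesh_term`, `tree_codes` (semicolon-joined).
#' @return Tibble with `tree_codes` as a list column.
#' @export
read_tree_codes_file <- function(path) {
  tab <- read_table(path, "tree_codes")
  tab$tree_codes <- split_multi(tab$tree_codes, ";")
  tab
}

#' The ten worked-example assay records shipped with the package
#'
#' A reconstruction of the worked examples used throughout the documentation:
#' ten literature assay descriptions spanning the four annotation outcomes
#' (model-only, phenotype-only, both, unannotated). Assay metadata columns
#' are filled with values consistent with dataset membership (organism-based
#' BAO format, mammalian organism, literature source).
#'
#' @return Assay-record tibble of 10 rows.
#' @export
example_assays <- function() {
  read_table(system.file("extdata", "example_assays.tsv",
                         package = "invivoclass", mustWork = TRUE),
             "assays")
}

#' The curator gold-standard exemplars shipped with the package
#'
#' Thirteen curator-labelled assays, one or more per confusion-matrix
#' quadrant, with the curator phrase columns kept for provenance.
#'
#' @return Gold tibble (`assay_id`, `curator_positive`, `excluded`, plus
#'   phrase columns).
#' @export
example_gold <- function() {
  read_table(system.file("extdata", "example_gold.tsv",
                         package = "invivoclass", mustWork = TRUE),
             "gold")
}
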