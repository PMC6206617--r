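# shared builders for small in-code fixtures

# a record passing all five identification clauses unless overridden
passing_record <- function(assay_id = "A1",
                           description = "Analgesic activity in tail flick test, oral administration",
                           assay_type = "F",
                           bao_format = "BAO_0000218",
                           assay_organism_l2 = "Mammalia",
                           target_organism_l2 = "",
                           src_id = 1L) {
  tibble::tibble(assay_id = assay_id, description = description,
                 assay_type = assay_type, bao_format = bao_format,
                 assay_organism_l2 = assay_organism_l2,
                 target_organism_l2 = target_organism_l2, src_id = src_id)
}

# minimal two-entry dictionary: one reference animal model, one phenotype term
mini_dictionary <- function() {
  load_dictionary(tibble::tibble(
    assay_class_id = c("M1", "P1"),
    level1 = c("Nervous System", "Nervous System"),
    level2 = c("Analgesia", "Analgesia"),
    level3 = c("Tail Flick", "General Analgesia"),
    source = c("Hock_2016", "phenotype"),
    patterns = c("[Tt]ail\\W?[Ff]lick", "[Aa]nalgesi"),
    mesh_terms = c("PAIN", "PAIN;ANALGESIA")
  ))
}

# independent five-clause re-evaluation used as the identification oracle;
# deliberately written with different primitives than the implementation
oracle_decision <- function(row, bao = "BAO_0000218", mammal = "Mammalia") {
  desc <- row$description
  has_desc <- !is.na(desc) && nzchar(trimws(desc))
  excl <- has_desc &&
    stringr::str_detect(tolower(desc), "in[ -]?vitro|ex[ -]?vivo")
  pass <- identical(row$bao_format, bao) &&
    (identical(row$assay_organism_l2, mammal) ||
       identical(row$target_organism_l2, mammal)) &&
    !excl &&
    !identical(row$assay_type, "A") &&
    isTRUE(row$src_id == 1L)
  pass
}

# brute-force annotation oracle: apply every pattern of every entry with
# stringr and collect the set of matching class ids
oracle_classes <- function(description, dictionary) {
  if (is.na(description) || !nzchar(description)) return(character(0))
  hit <- vapply(seq_len(nrow(dictionary)), function(i) {
    ic <- grepl("i", dictionary$pattern_flags[i], fixed = TRUE)
    any(vapply(dictionary$patterns[[i]], function(p) {
      stringr::str_detect(description, stringr::regex(p, ignore_case = ic))
    }, logical(1)))
  }, logical(1))
  sort(dictionary$assay_class_id[hit])
}

table1_corpus <- function() example_assays()

validation_corpus <- function() {
  read_table(system.file("extdata", "example_validation_assays.tsv",
                         package = "invivoclass", mustWork = TRUE),
             "assays")
}
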