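test_that("the seed dictionary loads cleanly and keeps the source enumeration", {
  dict <- seed_dictionary()
  expect_s3_class(dict, "invivo_dictionary")
  expect_gt(nrow(dict), 25)
  expect_true(all(dict$source %in%
                    c("Hock_2016", "Vogel_2008", "Vogel_2013", "phenotype")))
  expect_identical(dict$is_model, dict$source != "phenotype")
  expect_false(any(duplicated(dict$assay_class_id)))
  # every worked-example level-3 class is present
  expect_true(all(c(
    "Paw Edema Test", "Writhing Test for Analgesic Activity",
    "Radiant Heat Method", "Renal Hypertension",
    "Adjuvant Arthritis in Rats", "General Airway Models",
    "General Antimalarial Activity",
    "General Analgesic Nociceptic and Allodynic Activity",
    "Carbon tetrachloride CCl4 Induced Liver Fibrosis in Rats",
    "General Models of Drug Induced Liver Injury",
    "General Leukemia", "L1210 Experimental Leukemia", "Neoplasms",
    "Experimental Colitis Inflammatory Gut Disease",
    "Lewis Lung Carcinoma") %in% dict$level3))
})

test_that("dictionary validation rejects bad regexes, duplicates and empty headings", {
  row <- function(...) {
    tibble::tibble(assay_class_id = "AC_001", level1 = "L1", level2 = "L2",
                   level3 = "L3", source = "phenotype", patterns = "ok", ...)
  }
  bad <- row(); bad$patterns <- "([Tt]ail"
  expect_error(load_dictionary(bad), "AC_001")
  dup <- dplyr::bind_rows(row(), row())
  expect_error(load_dictionary(dup), "duplicate")
  empty <- row(); empty$level2 <- " "
  expect_error(load_dictionary(empty), "level2")
  nosrc <- row(); nosrc$source <- "Smith_2001"
  expect_error(load_dictionary(nosrc), "source")
  expect_error(load_dictionary(row()[, -6]), "patterns")
})

test_that("annotate_description hits the printed worked examples", {
  dict <- seed_dictionary()
  l3 <- function(hits) sort(dict$level3[match(hits$assay_class_id,
                                              dict$assay_class_id)])
  h1 <- annotate_description(
    "Analgesic activity in tail flick test, oral administration", dict)
  expect_setequal(
    l3(h1),
    c("Radiant Heat Method",
      "General Analgesic Nociceptic and Allodynic Activity"))

  # hyphenated tail-flick: the \W? consumes the hyphen
  h2 <- annotate_description(
    paste("Compound was administered subcutaneously and was evaluated for",
          "opioid antagonist activity (versus morphine) by tail-flick (TF)",
          "antagonism test"), dict)
  expect_true("Radiant Heat Method" %in% l3(h2))
  expect_true(any(h2$matched_text == "tail-flick"))

  h3 <- annotate_description(
    paste("Compound was evaluated for the time from injection to peak",
          "inhibition of the twitch response at 0.4 mg/kg dose"), dict)
  expect_equal(nrow(h3), 0)
  expect_equal(nrow(annotate_description("", dict)), 0)
})

test_that("one entry contributes at most one hit, keeping the first matching pattern", {
  dict <- load_dictionary(tibble::tibble(
    assay_class_id = "X", level1 = "a", level2 = "b", level3 = "c",
    source = "phenotype", patterns = "alpha|beta"))
  h <- annotate_description("beta then alpha then beta", dict)
  expect_equal(nrow(h), 1)
  expect_equal(h$pattern_index, 1L)   # lowest pattern index wins
  expect_equal(h$matched_text, "alpha")
})

test_that("per-entry ignore-case flag applies only where set", {
  dict <- load_dictionary(tibble::tibble(
    assay_class_id = c("CS", "CI"), level1 = "a", level2 = "b", level3 = "c",
    source = "phenotype", patterns = c("hepatotox", "hepatotox"),
    pattern_flags = c("", "i")))
  h <- annotate_description("HEPATOTOXICITY study", dict)
  expect_equal(h$assay_class_id, "CI")
})

test_that("annotate_corpus reproduces the worked-example key distribution", {
  dict <- seed_dictionary()
  ann <- annotate_corpus(table1_corpus(), dict)
  s <- ann$summary
  key <- dplyr::case_when(
    s$has_model_annotation & !s$has_phenotype_annotation ~ 1L,
    !s$has_model_annotation & s$has_phenotype_annotation ~ 2L,
    s$has_model_annotation & s$has_phenotype_annotation ~ 3L,
    TRUE ~ 4L)
  expect_equal(as.vector(table(key)), c(2L, 2L, 4L, 2L))
  expect_identical(s$annotated,
                   s$has_model_annotation | s$has_phenotype_annotation)
  # deterministic / idempotent
  expect_identical(unclass(annotate_corpus(table1_corpus(), dict)),
                   unclass(ann))
})

test_that("every hit's matched text is a substring of its description", {
  dict <- seed_dictionary()
  out <- generate_corpus(corpus_spec(300, seed = 11L))
  acc <- identify_corpus(out$records)$accepted
  ann <- annotate_corpus(acc, dict)
  desc <- setNames(acc$description, acc$assay_id)
  expect_true(all(mapply(grepl, ann$hits$matched_text,
                         desc[ann$hits$assay_id], fixed = TRUE)))
  # hit ordering is reproducible
  expect_identical(ann$hits,
                   dplyr::arrange(ann$hits, assay_id, assay_class_id))
})

test_that("annotation agrees with a brute-force pattern-scan oracle", {
  dict <- seed_dictionary()
  out <- generate_corpus(corpus_spec(250, seed = 5L))
  acc <- identify_corpus(out$records)$accepted
  ann <- annotate_corpus(acc, dict)
  got <- setNames(strsplit(ann$summary$class_ids, ";", fixed = TRUE),
                  ann$summary$assay_id)
  for (i in seq_len(nrow(acc))) {
    expect_equal(sort(got[[acc$assay_id[i]]]),
                 oracle_classes(acc$description[i], dict))
  }
})

test_that("dictionary growth is monotone in the hit set", {
  dict_rows <- tibble::tibble(
    assay_class_id = c("A", "B"), level1 = "l", level2 = "l", level3 = "l",
    source = "phenotype", patterns = c("writhing", "carrageenan"))
  small <- load_dictionary(dict_rows[1, ])
  big <- load_dictionary(dict_rows)
  desc <- "writhing response after carrageenan injection"
  h_small <- annotate_description(desc, small)
  h_big <- annotate_description(desc, big)
  expect_true(all(h_small$assay_class_id %in% h_big$assay_class_id))
  expect_gt(nrow(h_big), nrow(h_small))
})
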