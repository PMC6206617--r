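test_that("the in vitro / ex vivo exclusion pattern matches as printed", {
  expect_true(description_exclusion_matches(
    "Compound was evaluated in vitro for binding"))
  expect_false(description_exclusion_matches(
    "In vivo antimalarial activity in mice"))
  expect_false(description_exclusion_matches(""))
  # hyphenated and case variants forced by the pattern
  expect_true(description_exclusion_matches("ex-vivo tissue preparation"))
  expect_true(description_exclusion_matches("Measured In-Vitro in hepatocytes"))
  expect_true(description_exclusion_matches("EX VIVO perfused heart"))
  expect_false(description_exclusion_matches(NA_character_))
  # vectorised
  expect_equal(description_exclusion_matches(c("in vitro", "in vivo")),
               c(TRUE, FALSE))
})

test_that("each filter clause rejects with its own reason code", {
  base <- passing_record()
  ok <- is_in_vivo_candidate(base)
  expect_true(ok$accepted)
  expect_length(ok$reasons, 0)

  admet <- is_in_vivo_candidate(dplyr::mutate(base, assay_type = "A"))
  expect_false(admet$accepted)
  expect_equal(admet$reasons, "ADMET_TYPE")

  insect <- is_in_vivo_candidate(
    dplyr::mutate(base, assay_organism_l2 = "Insecta",
                  target_organism_l2 = ""))
  expect_false(insect$accepted)
  expect_equal(insect$reasons, "NOT_MAMMAL")

  # xenograft pattern: assay organism absent, target organism mammalian
  xeno <- is_in_vivo_candidate(
    dplyr::mutate(base, assay_organism_l2 = "",
                  target_organism_l2 = "Mammalia"))
  expect_true(xeno$accepted)

  wrong_bao <- is_in_vivo_candidate(dplyr::mutate(base, bao_format = "BAO_0000219"))
  expect_equal(wrong_bao$reasons, "NOT_ORGANISM_FORMAT")

  deposited <- is_in_vivo_candidate(dplyr::mutate(base, src_id = 7L))
  expect_equal(deposited$reasons, "NOT_LITERATURE")

  invitro <- is_in_vivo_candidate(
    dplyr::mutate(base, description = "Activity measured ex vivo in aorta"))
  expect_equal(invitro$reasons, "DESCRIPTION_EXCLUSION")

  expect_error(is_in_vivo_candidate(dplyr::mutate(base, assay_id = "")),
               "assay_id")
})

test_that("a missing description warns but does not reject", {
  d <- is_in_vivo_candidate(passing_record(description = ""))
  expect_true(d$accepted)
  expect_equal(d$reasons, "MISSING_DESCRIPTION")
  d2 <- is_in_vivo_candidate(passing_record(description = NA_character_))
  expect_true(d2$accepted)
})

test_that("acceptance is the exact conjunction of the five clauses (2^5 enumeration)", {
  breakers <- list(
    NOT_ORGANISM_FORMAT = function(r) dplyr::mutate(r, bao_format = "BAO_0000019"),
    NOT_MAMMAL = function(r) dplyr::mutate(r, assay_organism_l2 = "Aves",
                                           target_organism_l2 = ""),
    DESCRIPTION_EXCLUSION = function(r)
      dplyr::mutate(r, description = paste(r$description, "also ex vivo")),
    ADMET_TYPE = function(r) dplyr::mutate(r, assay_type = "A"),
    NOT_LITERATURE = function(r) dplyr::mutate(r, src_id = 15L)
  )
  for (mask in 0:31) {
    fails <- names(breakers)[bitwAnd(mask, 2^(0:4)) != 0]
    rec <- passing_record()
    for (f in fails) rec <- breakers[[f]](rec)
    d <- is_in_vivo_candidate(rec)
    expect_identical(d$accepted, length(fails) == 0L)
    expect_setequal(d$reasons, fails)
  }
})

test_that("organism label comparison is exact by default, optionally case-insensitive", {
  rec <- passing_record(assay_organism_l2 = "mammalia", target_organism_l2 = "")
  expect_false(is_in_vivo_candidate(rec)$accepted)
  expect_true(is_in_vivo_candidate(
    rec, filter_options(case_insensitive_organism = TRUE))$accepted)
})

test_that("identify_corpus preserves order, collapses duplicates and is idempotent", {
  expect_equal(nrow(identify_corpus(passing_record()[0, ])$accepted), 0)

  recs <- dplyr::bind_rows(
    passing_record("A1"),
    passing_record("A2", assay_type = "A"),
    passing_record("A3"),
    passing_record("A1", description = "a duplicate row"),
    passing_record("A4", bao_format = "BAO_0000219")
  )
  expect_warning(res <- identify_corpus(recs), "duplicate")
  expect_equal(res$accepted$assay_id, c("A1", "A3"))
  expect_equal(nrow(res$decisions), 4)  # one per distinct id
  # first-occurrence row kept for A1
  expect_equal(res$accepted$description[1],
               passing_record("A1")$description)
  # idempotence
  again <- identify_corpus(res$accepted)
  expect_identical(again$accepted, res$accepted)
  expect_true(all(again$decisions$accepted))
})

test_that("identify_corpus agrees with a brute-force clause oracle on 1,000 synthetic records", {
  out <- generate_corpus(corpus_spec(1000, seed = 42L))
  res <- identify_corpus(out$records)
  oracle <- vapply(seq_len(nrow(out$records)),
                   function(i) oracle_decision(out$records[i, ]), logical(1))
  expect_identical(res$decisions$accepted, oracle)
  # and with the generator's planted truth
  expect_identical(res$decisions$accepted, out$truth$accepted)
  # per-record decisions independent of corpus context: spot-check a shuffle
  idx <- sample(seq_len(nrow(out$records)))
  res2 <- identify_corpus(out$records[idx, ])
  m <- match(res$decisions$assay_id, res2$decisions$assay_id)
  expect_identical(res$decisions$accepted, res2$decisions$accepted[m])
  expect_identical(res$decisions$reasons, res2$decisions$reasons[m])
})
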