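#' Deterministic synthetic assay corpora with planted ground truth
#'
#' Real bioactivity-database corpora cannot be redistributed, so every stage
#' of the pipeline is exercised on synthetic corpora whose expected outcome is
#' known *by construction*. Descriptions are built from parameterised
#' templates (species, dose, route, timing vary) that either embed a
#' seed-dictionary trigger phrase ("tail flick", "carrageenan-induced paw",
#' "CCl4-induced ... hepatic injury", "forced swimming test", "L1210
#' leukemia") or are decoys that reuse pharmacology vocabulary without any
#' trigger. Non-in-vivo contaminants are planted with known failing filter
#' clauses (in vitro phrases, ADMET type, non-mammalian organisms,
#' non-literature sources, non-organism BAO format).
#'
#' The generator is fully deterministic for a fixed seed (Mersenne-Twister,
#' R >= 3.6 "Rejection" sampling; the caller's RNG state is restored on
#' exit).
#'
#' @name synthetic_data
NULL

SPECIES <- c("rat", "mouse", "guinea pig", "rabbit", "dog")
ROUTES <- c("oral", "intravenous", "subcutaneous", "intraperitoneal")
DOSES <- c(1, 3, 5, 10, 20, 30, 50, 100)

# each planted template lists the seed-dictionary classes its description
# must hit (the ground truth); decoys hit nothing
planted_templates <- function() {
  list(
    model = list(
      list(text = "Adjuvant arthritic %s activity determined with respect to reference agent at a dose of %d mg/kg",
           args = c("species", "dose"), classes = c("AC_ADJARTH")),
      list(text = "Blood pressure response in renal hypertensive %ss after %s administration",
           args = c("species", "route"), classes = c("AC_RENHYP")),
      list(text = "Latency measured in tail flick test in %ss at %d mg/kg, %s",
           args = c("species", "dose", "route"), classes = c("AC_RADHEAT")),
      list(text = "Survival of %ss implanted with L1210 cells at %d mg/kg per day",
           args = c("species", "dose"), classes = c("AC_L1210")),
      list(text = "Reduction in immobility time in %ss by forced swimming test at %d mg/kg, %s",
           args = c("species", "dose", "route"), classes = c("AC_SWIM")),
      list(text = "Inhibition of carrageenan-induced paw volume increase in %ss at %d mg/kg",
           args = c("species", "dose"), classes = c("AC_PAW"))
    ),
    phenotype = list(
      list(text = "Antimalarial activity in %ss against chloroquine-resistant parasites after %s administration",
           args = c("species", "route"), classes = c("AC_MALARIA")),
      list(text = "Compound was evaluated for receptor induced airway obstruction in %s at %d hr after %s administration",
           args = c("species", "dose", "route"), classes = c("AC_AIRWAY")),
      list(text = "Anticonvulsant activity against electrically induced seizures in %ss at %d mg/kg",
           args = c("species", "dose"), classes = c("AC_EPIL")),
      list(text = "Antitumor activity in %ss bearing solid tumor measured as T/C value at %d mg/kg",
           args = c("species", "dose"), classes = c("AC_NEOPL")),
      list(text = "Analgesic activity in %ss by hot plate method at %d mg/kg",
           args = c("species", "dose"), classes = c("AC_ANALG")),
      list(text = "Antidepressant-like activity in %ss assessed as behavioural change at %d mg/kg, %s",
           args = c("species", "dose", "route"), classes = c("AC_ANTIDEP"))
    ),
    both = list(
      list(text = "Analgesic activity in tail flick test in %ss, %s administration",
           args = c("species", "route"), classes = c("AC_RADHEAT", "AC_ANALG")),
      list(text = "Antioxidant activity against CCl4-induced oxidative hepatic injury in %ss at %d mg/kg",
           args = c("species", "dose"), classes = c("AC_CCL4", "AC_DILI")),
      list(text = "Antidepressant activity in %ss assessed as reduction in immobility time by forced swimming test",
           args = c("species"), classes = c("AC_SWIM", "AC_ANTIDEP")),
      list(text = "Antitumor activity against L1210 leukemia in %ss measured as T/C value at %d mg/kg",
           args = c("species", "dose"),
           classes = c("AC_L1210", "AC_LEUK", "AC_NEOPL")),
      list(text = "Antiinflammatory activity in %ss assessed as reduction of carrageenan-induced paw volume at %d mg/kg",
           args = c("species", "dose"), classes = c("AC_PAW", "AC_ANTIINFL"))
    ),
    decoy = list(
      list(text = "Binding specificity of the compound in %s striatum at %d min after intravenous injection",
           args = c("species", "dose"), classes = character(0)),
      list(text = "Compound was evaluated for the time from injection to peak inhibition of the twitch response at %d mg/kg dose",
           args = c("dose"), classes = character(0)),
      list(text = "Change in rectal temperature in %ss at a dose of %d umol/kg by subcutaneous administration",
           args = c("species", "dose"), classes = character(0)),
      list(text = "Ratio of mean response of treated to control %ss at a dose of %d mg/kg",
           args = c("species", "dose"), classes = character(0)),
      list(text = "Effect on spontaneous locomotor performance in %ss after %s dosing at %d mg/kg",
           args = c("species", "route", "dose"), classes = character(0)),
      list(text = "Duration of loss of righting response in %ss at %d mg/kg given by %s route",
           args = c("species", "dose", "route"), classes = character(0))
    )
  )
}

render_template <- function(tpl) {
  vals <- lapply(tpl$args, function(a) {
    switch(a,
           species = sample(SPECIES, 1L),
           route = sample(ROUTES, 1L),
           dose = sample(DOSES, 1L))
  })
  do.call(sprintf, c(list(tpl$text), vals))
}

#' Specification of a synthetic corpus
#'
#' Default proportions mirror the study corpus: two thirds (66.5%) of
#' identified in vivo assays carry an annotation, split between
#' reference-animal-model (38%), phenotype-endpoint (51%) and both (23%)
#' shares of the corpus (the three shares act as relative weights for the
#' model-only / phenotype-only / both mix among annotated assays).
#'
#' @param n_assays Number of records to generate.
#' @param fraction_in_vivo Proportion passing all identification clauses.
#' @param fraction_annotatable Proportion of in vivo assays containing a
#'   planted trigger phrase.
#' @param fraction_model,fraction_phenotype,fraction_both Corpus-level shares
#'   of model-, phenotype- and dual-annotated assays;
#'   `fraction_both <= min(fraction_model, fraction_phenotype)`.
#' @param contaminant_rates Named numeric rates in `[0,1]` for the failure
#'   modes planted in non-in-vivo records: `in_vitro` (exclusion phrase in the
#'   description), `admet` (assay type `'A'`), `non_mammal`,
#'   `non_literature`, `non_organism_format`. A contaminant failing no
#'   sampled clause is forced to fail the BAO-format clause.
#' @param seed RNG seed.
#' @return A list of class `invivo_corpus_spec`.
#' @export
corpus_spec <- function(n_assays,
                        fraction_in_vivo = 0.7,
                        fraction_annotatable = 0.665,
                        fraction_model = 0.38,
                        fraction_phenotype = 0.51,
                        fraction_both = 0.23,
                        contaminant_rates = c(in_vitro = 0.4, admet = 0.3,
                                              non_mammal = 0.3,
                                              non_literature = 0.2,
                                              non_organism_format = 0.3),
                        seed = 1L) {
  fr <- c(fraction_in_vivo, fraction_annotatable, fraction_model,
          fraction_phenotype, fraction_both, contaminant_rates)
  if (any(fr < 0 | fr > 1)) {
    stop("all fractions and rates must lie in [0, 1]", call. = FALSE)
  }
  if (fraction_both > min(fraction_model, fraction_phenotype)) {
    stop("fraction_both may not exceed fraction_model or fraction_phenotype",
         call. = FALSE)
  }
  needed <- c("in_vitro", "admet", "non_mammal", "non_literature",
              "non_organism_format")
  rates <- contaminant_rates[needed]
  if (anyNA(rates)) {
    stop("contaminant_rates must name: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_assays = as.integer(n_assays),
         fraction_in_vivo = fraction_in_vivo,
         fraction_annotatable = fraction_annotatable,
         fraction_model = fraction_model,
         fraction_phenotype = fraction_phenotype,
         fraction_both = fraction_both,
         contaminant_rates = rates,
         seed = as.integer(seed)),
    class = "invivo_corpus_spec"
  )
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  force(code)
}

#' Generate a synthetic assay corpus with ground truth
#'
#' @param spec An [corpus_spec()] object.
#' @return A list with
#'   * `records`: assay-record tibble (identification input schema);
#'   * `truth`: per-record ground truth — `assay_id`, `accepted`, `reasons`
#'     (expected rejection codes, semicolon-joined, clause order),
#'     `class_ids` (expected annotation classes, semicolon-joined, sorted),
#'     `annotated`, `has_model_annotation`, `has_phenotype_annotation`.
#' @examples
#' out <- generate_corpus(corpus_spec(50, seed = 7))
#' table(out$truth$accepted)
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "invivo_corpus_spec"))
  with_seed(spec$seed, {
    tpls <- planted_templates()
    n <- spec$n_assays
    n_iv <- round(n * spec$fraction_in_vivo)
    n_out <- n - n_iv
    n_annot <- round(n_iv * spec$fraction_annotatable)
    w <- c(model = max(spec$fraction_model - spec$fraction_both, 0),
           phenotype = max(spec$fraction_phenotype - spec$fraction_both, 0),
           both = spec$fraction_both)
    if (n_annot > 0 && sum(w) == 0) {
      stop("annotatable assays requested but all source fractions are zero",
           call. = FALSE)
    }
    n_model <- if (n_annot > 0) round(n_annot * w["model"] / sum(w)) else 0L
    n_both <- if (n_annot > 0) round(n_annot * w["both"] / sum(w)) else 0L
    n_phen <- n_annot - n_model - n_both
    kinds <- c(rep("model", n_model), rep("phenotype", n_phen),
               rep("both", n_both), rep("decoy", n_iv - n_annot),
               rep("contaminant", n_out))
    kinds <- sample(kinds)
    dict <- seed_dictionary()
    is_model <- stats::setNames(dict$is_model, dict$assay_class_id)
    rows <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      id <- sprintf("SYN%06d", i)
      kind <- kinds[i]
      if (kind == "contaminant") {
        fail <- stats::runif(5) < spec$contaminant_rates
        names(fail) <- names(spec$contaminant_rates)
        if (!any(fail)) fail["non_organism_format"] <- TRUE
        tpl <- sample(tpls$decoy, 1L)[[1]]
        desc <- render_template(tpl)
        if (fail["in_vitro"]) {
          desc <- paste0(desc, "; activity confirmed ",
                         sample(c("in vitro", "in-vitro", "ex vivo", "ex-vivo"), 1L),
                         " in tissue preparation")
        }
        rows[[i]] <- tibble::tibble(
          assay_id = id, description = desc,
          assay_type = if (fail["admet"]) "A" else sample(c("B", "F"), 1L),
          bao_format = if (fail["non_organism_format"]) "BAO_0000219"
                       else "BAO_0000218",
          assay_organism_l2 = if (fail["non_mammal"])
                                sample(c("Insecta", "Bacteria", "Aves"), 1L)
                              else "Mammalia",
          target_organism_l2 = if (fail["non_mammal"]) "" else
                                 sample(c("Mammalia", ""), 1L),
          src_id = if (fail["non_literature"]) sample(c(7L, 9L, 15L), 1L)
                   else 1L
        )
        reasons <- c(
          if (fail["non_organism_format"]) "NOT_ORGANISM_FORMAT",
          if (fail["non_mammal"]) "NOT_MAMMAL",
          if (fail["in_vitro"]) "DESCRIPTION_EXCLUSION",
          if (fail["admet"]) "ADMET_TYPE",
          if (fail["non_literature"]) "NOT_LITERATURE"
        )
        truth[[i]] <- tibble::tibble(
          assay_id = id, accepted = FALSE,
          reasons = paste(reasons, collapse = ";"),
          class_ids = "", annotated = FALSE,
          has_model_annotation = FALSE, has_phenotype_annotation = FALSE
        )
      } else {
        tpl <- sample(tpls[[kind]], 1L)[[1]]
        desc <- render_template(tpl)
        rows[[i]] <- tibble::tibble(
          assay_id = id, description = desc,
          assay_type = sample(c("B", "F"), 1L),
          bao_format = "BAO_0000218",
          assay_organism_l2 = "Mammalia",
          target_organism_l2 = sample(c("Mammalia", ""), 1L),
          src_id = 1L
        )
        cls <- sort(tpl$classes)
        truth[[i]] <- tibble::tibble(
          assay_id = id, accepted = TRUE,
          reasons = "",
          class_ids = paste(cls, collapse = ";"),
          annotated = length(cls) > 0L,
          has_model_annotation = length(cls) > 0L && any(is_model[cls]),
          has_phenotype_annotation = length(cls) > 0L && any(!is_model[cls])
        )
      }
    }
    list(records = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth))
  })
}

#' Derive a curator gold standard from generator truth
#'
#' The gold labels equal the planted truth except for a controlled number of
#' disagreements: `flip_fp` truth-positive (annotatable) assays are marked
#' curator-negative and `flip_fn` truth-negative assays curator-positive —
#' so a pipeline that recovers the planted truth exactly scores exactly
#' FP = `flip_fp` (annotated by the pipeline, no curator phrase) and
#' FN = `flip_fn` (curator phrase, no pipeline annotation) against this gold
#' set. Non-in-vivo records become `excluded` gold rows (curator-listed
#' assays that are not scored).
#'
#' @param truth Truth tibble from [generate_corpus()].
#' @param flip_fp,flip_fn Number of rows to flip; must not exceed the
#'   available truth-positive / truth-negative rows.
#' @param seed RNG seed for the deterministic choice of flipped rows.
#' @param include_excluded Emit `excluded = TRUE` rows for non-accepted
#'   records (default) or drop them.
#' @return Gold tibble: `assay_id`, `curator_positive`, `excluded`.
#' @export
generate_gold <- function(truth, flip_fp = 0L, flip_fn = 0L, seed = 1L,
                          include_excluded = TRUE) {
  truth <- tibble::as_tibble(truth)
  with_seed(seed, {
    gold <- tibble::tibble(
      assay_id = truth$assay_id,
      curator_positive = truth$annotated,
      excluded = !truth$accepted
    )
    neg <- which(truth$accepted & !truth$annotated)
    pos <- which(truth$accepted & truth$annotated)
    if (flip_fp > length(pos)) {
      stop(sprintf("flip_fp = %d exceeds the %d truth-positive rows",
                   flip_fp, length(pos)), call. = FALSE)
    }
    if (flip_fn > length(neg)) {
      stop(sprintf("flip_fn = %d exceeds the %d truth-negative rows",
                   flip_fn, length(neg)), call. = FALSE)
    }
    if (flip_fp > 0L) {
      gold$curator_positive[sample(pos, flip_fp)] <- FALSE
    }
    if (flip_fn > 0L) {
      gold$curator_positive[sample(neg, flip_fn)] <- TRUE
    }
    if (!include_excluded) gold <- gold[!gold$excluded, , drop = FALSE]
    gold
  })
}
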