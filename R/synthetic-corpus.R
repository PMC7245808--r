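# Deterministic synthetic ICSR corpus generator with gold labels.
#
# Gold labels are assigned by template semantics, never by detector
# behaviour, so detector imperfection is measurable: designed-miss
# templates exist on the positive side (word gap beyond the proximity
# window; error wording confined to an "analysis results" section; the
# word "syringe" absent altogether; a product brand outside the pattern
# cascade's dictionary) and designed false-positive drivers on the
# negative side (nurse drawing from a vial, prefilled syringe products,
# negated errors, inhaled-insulin trials, plain device complaints).

.pos_templates <- c("pos_mix", "pos_withdrew", "pos_taking",
                    "pos_flextouch", "pos_longgap", "pos_analysis_only",
                    "pos_nosyringe")
.neg_templates <- c("neg_plain", "neg_device", "neg_vial", "neg_prefilled",
                    "neg_negated", "neg_inhaled")

# positive templates the default proximity pipeline cannot retrieve, by
# construction
.cpr_miss_templates <- c("pos_longgap", "pos_analysis_only", "pos_nosyringe")
.i2e_miss_templates <- c("pos_flextouch", "pos_nosyringe")

#' Configuration of the synthetic corpus generator
#'
#' Defaults encode the study conditions the generator emulates: a 1.7\%
#' EIPPCS prevalence among reports surviving the device/medication-error
#' HLGT pre-filter context, narrative phrasing seeded by real published
#' example narratives, false-positive drivers, and preferred-term coding
#' correlated with narrative content plus coding noise.
#'
#' @param n_records number of reports to generate.
#' @param prevalence proportion of gold EIPPCS cases (default 0.017); the
#'   planted positive count is `round_half_up(prevalence * n_records)`.
#' @param seed integer seed; generation is fully reproducible from it and
#'   leaves the global RNG untouched.
#' @param template_weights named non-negative weights over the positive
#'   template families (normalised internally).
#' @param distractor_weights named non-negative weights over the negative
#'   template families.
#' @param coding_noise probability that a record's PT set is replaced by
#'   off-signal terms (default 0.05) -- for positives this creates the
#'   "coded with a PT outside the twelve" miss mode of the PT-filter
#'   method.
#' @param section_layout probability that a record gains a benign
#'   "analysis results" section (default 0.15); the analysis-only positive
#'   template always has one.
#' @return a list of class `"generator_config"`.
#' @export
generator_config <- function(n_records,
                             prevalence = 0.017,
                             seed = 1L,
                             template_weights = c(
                               pos_mix = 0.22, pos_withdrew = 0.23,
                               pos_taking = 0.20, pos_flextouch = 0.10,
                               pos_longgap = 0.10, pos_analysis_only = 0.10,
                               pos_nosyringe = 0.05),
                             distractor_weights = c(
                               neg_plain = 0.80, neg_device = 0.08,
                               neg_vial = 0.05, neg_prefilled = 0.03,
                               neg_negated = 0.02, neg_inhaled = 0.02),
                             coding_noise = 0.05,
                             section_layout = 0.15) {
  check_that(n_records >= 1, "n_records must be positive")
  check_that(prevalence >= 0 && prevalence <= 1,
             "prevalence must be in [0, 1]",
             class = "icsrminer_validation_error")
  check_that(setequal(names(template_weights), .pos_templates) &&
               all(template_weights >= 0) && sum(template_weights) > 0,
             "template_weights must cover the positive template families")
  check_that(setequal(names(distractor_weights), .neg_templates) &&
               all(distractor_weights >= 0) && sum(distractor_weights) > 0,
             "distractor_weights must cover the negative template families")
  check_that(coding_noise >= 0 && coding_noise <= 1,
             "coding_noise must be a proportion")
  if (prevalence > 0 && round_half_up(prevalence * n_records) == 0) {
    warn("prevalence rounds to zero positives at this corpus size")
  }
  structure(list(n_records = as.integer(n_records), prevalence = prevalence,
                 seed = as.integer(seed),
                 template_weights = template_weights[.pos_templates],
                 distractor_weights = distractor_weights[.neg_templates],
                 coding_noise = coding_noise,
                 section_layout = section_layout),
            class = "generator_config")
}

# fictional pen/cartridge brands; "Flexitra" is the brand deliberately
# absent from the pattern cascade's product dictionary
.brands <- c("Pentora", "Glargix", "Rapidex")
.brand_flextouch_like <- "Flexitra"

# ---- narrative builders ------------------------------------------------
# Each builder returns list(sections = tibble(name, text),
#                           products = chr, base_pts = chr)

.build_narrative <- function(template, draw) {
  brand <- draw$brand
  main <- switch(
    template,
    pos_mix = paste0(
      "It was reported that the patient had been using ", brand,
      " and ", draw$brand2, " for the last ", draw$years, " years. ",
      "It was reported that ", brand, " and ", draw$brand2,
      " was intentionally mixed in the one syringe to minimise injections."),
    pos_withdrew = paste0(
      "A ", draw$person, " reported that he mistakenly withdrew insulin ",
      "out of the ", brand, " with a regular syringe and then injected ",
      "it back into the pen."),
    pos_taking = paste0(
      "The patient experienced a ", brand, " pen with air inside and a ",
      "bubble. Insulin was not coming out of the pen. For this reason ",
      "the consumer is taking insulin with a syringe."),
    pos_flextouch = paste0(
      "The patient mistakenly withdrew insulin out of the ",
      .brand_flextouch_like, " with a regular syringe and injected it ",
      "back into the device."),
    pos_longgap = paste0(
      "The patient extracted every unit of insulin remaining in the ",
      "broken ", brand, " device after the plunger jammed repeatedly ",
      "and only then filled an ordinary syringe."),
    pos_analysis_only = paste0(
      "The patient reported that the ", brand, " pen stopped working ",
      "and the device was returned for evaluation."),
    pos_nosyringe = paste0(
      "The patient drew the remaining insulin out of the ", brand,
      " cartridge with a needle and injected it into an old device."),
    neg_plain = paste0(
      "The patient reported ", draw$ae, " after starting treatment with ",
      "the ", brand, " pen. The event resolved during follow up."),
    neg_device = paste0(
      "The patient reported that the ", brand, " pen was not working ",
      "properly and the dose button was stuck. The device was replaced ",
      "by the company."),
    neg_vial = paste0(
      "A woman reported elevated blood glucose changes while using the ",
      brand, " pen prior to the visit. The nurse drew up the correct ",
      "dose with a syringe from a conventional vial and administered ",
      "the injection."),
    neg_prefilled = paste0(
      "The patient switched from the ", brand, " pen to prefilled ",
      "insulin syringes supplied by the pharmacy and continued to use ",
      "prefilled insulin syringes daily."),
    neg_negated = paste0(
      "The physician asked whether the patient had withdrawn insulin ",
      "from the ", brand, " cartridge with a syringe but the patient ",
      "denied this at the visit."),
    neg_inhaled = paste0(
      "The subject was enrolled in an inhaled insulin clinical trial ",
      "and reported persistent cough after each inhalation. A syringe ",
      "was never handled by the subject."),
    abort(paste0("unknown template: ", template))
  )
  sections <- tibble(name = "narrative", text = main)
  if (template == "pos_analysis_only") {
    sections <- bind_rows(sections, tibble(
      name = "analysis results",
      text = paste0("Analysis confirmed that insulin had been withdrawn ",
                    "from the cartridge with a syringe.")))
  } else if (draw$add_analysis) {
    sections <- bind_rows(sections, tibble(
      name = "analysis results",
      text = paste0("The returned device was examined and performed ",
                    "within specifications.")))
  }
  products <- if (template == "pos_flextouch") .brand_flextouch_like
  else if (template == "pos_mix") c(brand, draw$brand2)
  else brand
  list(sections = sections, products = products)
}

# PT names drawn consistently with template family
.draw_pt_names <- function(template, runif1, composite) {
  tp_pool <- c("Wrong technique in product usage process" = 0.45,
               "Drug administered in wrong device" = 0.20,
               "Intentional product misuse" = 0.15,
               "Intentional device misuse" = 0.12,
               "Wrong device used" = 0.08)
  pick <- function(pool) {
    names(pool)[findInterval(runif1(), cumsum(pool / sum(pool))) + 1]
  }
  if (startsWith(template, "pos")) {
    first <- pick(tp_pool)
    if (composite) unique(c(first, pick(tp_pool))) else first
  } else {
    switch(template,
      neg_plain = pick(c("Headache" = 0.35, "Nausea" = 0.25,
                         "Dizziness" = 0.2, "Hyperglycaemia" = 0.2)),
      neg_device = pick(c("Device malfunction" = 0.55,
                          "Device failure" = 0.45)),
      neg_vial = pick(c("Device malfunction" = 0.40, "Device failure" = 0.25,
                        "Product use issue" = 0.15, "Device use issue" = 0.10,
                        "Wrong technique in product usage process" = 0.10)),
      neg_prefilled = pick(c("Product use issue" = 0.6,
                             "Medication error" = 0.4)),
      neg_negated = pick(c("Wrong technique in product usage process" = 0.5,
                           "Medication error" = 0.5)),
      neg_inhaled = pick(c("Cough" = 0.5, "Device use issue" = 0.5))
    )
  }
}

#' Generate a labelled synthetic ICSR corpus
#'
#' Plants exactly `round_half_up(prevalence * n_records)` gold-positive
#' records.  Template counts within each family follow the configured
#' weights by largest-remainder apportionment (deterministic), record
#' order is a seeded permutation, and every stochastic choice (brands,
#' filler variants, PT coding, coding noise, extra sections, source tags)
#' is drawn from a seed-isolated RNG, so the same configuration always
#' yields a byte-identical corpus.
#'
#' @param config a [generator_config()].
#' @return object of class `"labelled_corpus"`: list with elements
#'   `records` (corpus tibble), `annotations` (`id`, `label`) and
#'   `provenance` (`id`, `template`).
#' @export
generate_corpus <- function(config) {
  check_that(inherits(config, "generator_config"),
             "config must come from generator_config()")
  n <- config$n_records
  n_pos <- as.integer(round_half_up(config$prevalence * n))
  n_neg <- n - n_pos
  pos_counts <- apportion(config$template_weights, n_pos)
  neg_counts <- apportion(config$distractor_weights, n_neg)
  templates <- c(rep(.pos_templates, pos_counts),
                 rep(.neg_templates, neg_counts))
  hierarchy <- mock_hierarchy()
  code_of <- setNames(hierarchy$pt_code, norm_term(hierarchy$pt_name))
  off_signal <- c("Medication error", "Needle issue")

  withr::with_seed(config$seed, {
    templates <- sample(templates)
    ids <- sprintf("ICSR%06d", seq_len(n))
    recs <- purrr::map(seq_len(n), function(i) {
      tmpl <- templates[i]
      draw <- list(
        brand = sample(.brands, 1),
        brand2 = sample(.brands, 1),
        years = sample(2:9, 1),
        person = sample(c("man", "patient", "consumer"), 1),
        ae = sample(c("headache", "nausea", "dizziness",
                      "raised readings"), 1),
        add_analysis = stats::runif(1) < config$section_layout
      )
      if (draw$brand2 == draw$brand) {
        draw$brand2 <- setdiff(.brands, draw$brand)[1]
      }
      nar <- .build_narrative(tmpl, draw)
      composite <- stats::runif(1) < 0.10
      pt_names <- .draw_pt_names(tmpl, function() stats::runif(1),
                                 composite)
      if (stats::runif(1) < config$coding_noise) {
        pt_names <- sample(off_signal, 1)
      }
      source <- if (tmpl == "neg_inhaled") "clinical_trial" else {
        c("spontaneous", "solicited", "literature", "clinical_trial",
          "unknown")[findInterval(stats::runif(1),
                                  cumsum(c(0.6, 0.15, 0.05, 0.15, 0.05))) + 1]
      }
      list(sections = nar$sections, products = nar$products,
           pt_codes = unname(code_of[norm_term(pt_names)]),
           source = source)
    })
    corpus <- icsr_corpus(
      id = ids,
      sections = purrr::map(recs, "sections"),
      pt_codes = purrr::map(recs, "pt_codes"),
      products = purrr::map(recs, "products"),
      source = purrr::map_chr(recs, "source")
    )
    annotations <- tibble(
      id = ids,
      label = ifelse(startsWith(templates, "pos"), "EIPPCS", "non_EIPPCS")
    )
    provenance <- tibble(id = ids, template = templates)
    structure(list(records = corpus, annotations = annotations,
                   provenance = provenance, config = config),
              class = "labelled_corpus")
  })
}

#' @export
print.labelled_corpus <- function(x, ...) {
  n_pos <- sum(x$annotations$label == "EIPPCS")
  cat(sprintf("<labelled_corpus: %d records, %d gold EIPPCS (%.2f%%)>\n",
              nrow(x$records), n_pos, 100 * n_pos / nrow(x$records)))
  invisible(x)
}

#' Tidy a labelled corpus into one row per record
#'
#' @param x a `labelled_corpus`.
#' @param ... unused.
#' @return the records tibble joined with gold label and template id.
#' @export
tidy.labelled_corpus <- function(x, ...) {
  x$records |>
    left_join(x$annotations, by = "id") |>
    left_join(x$provenance, by = "id")
}

#' Count records per generator template
#'
#' @param labelled a `labelled_corpus`.
#' @return tibble `template`, `n`; counts sum to the corpus size.
#' @export
template_census <- function(labelled) {
  check_that(inherits(labelled, "labelled_corpus"),
             "labelled must be a labelled_corpus")
  labelled$provenance |> count(.data$template, name = "n")
}

#' Designed-miss fraction of the planted positives
#'
#' Fraction of gold-positive records drawn from templates the default
#' proximity pipeline (`method = "cpr"`) or pattern cascade
#' (`method = "i2e"`) cannot retrieve by construction.  With the
#' deterministic default pipelines, measured recall on the generated
#' corpus equals exactly one minus this fraction.
#'
#' @param labelled a `labelled_corpus`.
#' @param method `"cpr"` or `"i2e"`.
#' @return a proportion.
#' @export
designed_miss_fraction <- function(labelled, method = c("cpr", "i2e")) {
  method <- match.arg(method)
  miss <- switch(method, cpr = .cpr_miss_templates,
                 i2e = .i2e_miss_templates)
  pos <- labelled$provenance$template[labelled$annotations$label == "EIPPCS"]
  check_that(length(pos) > 0, "corpus has no planted positives")
  mean(pos %in% miss)
}
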