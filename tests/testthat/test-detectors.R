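test_that("keyword+PT cascade needs both filters to pass", {
  h <- mini_hierarchy()
  corpus <- mini_corpus(
    c("withdrew insulin with a syringe",   # keyword + error PT
      "pen stopped working entirely",      # no keyword
      "patient reused old syringes"),      # keyword, headache-coded
    pt_codes = list("P002", "P001", "P003")
  )
  res <- run_ssa(corpus, h)
  expect_equal(retrieved_ids(res), "R1")
  tr <- tidy(res)
  expect_equal(tr$decision[tr$id == "R2"], "exclude")
  expect_equal(tr$rule_id[tr$id == "R2"], "ssa_rule_1")
  expect_equal(tr$decision[tr$id == "R3"], c("pass", "exclude"))

  # prefix match covers plurals; exact-token mode does not
  res_exact <- run_ssa(corpus, h, keyword_match = "exact")
  expect_false("R3" %in% unique(tidy(res_exact)$id[
    tidy(res_exact)$rule_id == "ssa_rule_2"]))

  # retrieved set is always a subset of the records with the anchor token
  has_kw <- corpus$id[vapply(corpus$sections, function(s) {
    any(grepl("syringe", s$text, ignore.case = TRUE))
  }, TRUE)]
  expect_true(all(retrieved_ids(res) %in% has_kw))
})

test_that("proximity pipeline retrieves the canonical error phrasings", {
  corpus <- mini_corpus(c(
    "He mistakenly withdrew insulin out of the FlexPen with a regular syringe.",
    "Patient was given prefilled insulin syringes by the pharmacy.",
    "Patient did not withdraw insulin with a syringe.",
    "The subject joined an inhaled insulin trial and used a syringe after taking part."
  ))
  res <- run_cpr(corpus)
  expect_equal(retrieved_ids(res), "R1")
  tr <- tidy(res)
  last <- function(id) utils::tail(tr[tr$id == id, ], 1)
  expect_equal(last("R2")$rule_id, "cpr_rule_4")   # prefilled filter
  expect_equal(last("R3")$rule_id, "cpr_rule_3")   # negation filter
  expect_equal(last("R4")$rule_id, "cpr_rule_4")   # trial exclusion
  expect_equal(last("R1")$decision, "include")
})

test_that("text confined to an excluded section cannot drive retrieval", {
  pos_text <- "Insulin was withdrawn from the cartridge with a syringe."
  corpus <- icsr_corpus(
    id = c("A", "B"),
    sections = list(
      tibble::tibble(name = c("narrative", "analysis results"),
                     text = c("The pen was returned.", pos_text)),
      tibble::tibble(name = "narrative", text = pos_text)
    )
  )
  res <- run_cpr(corpus)
  expect_equal(retrieved_ids(res), "B")
  tr <- tidy(res)
  expect_equal(utils::tail(tr$rule_id[tr$id == "A"], 1), "cpr_rule_2")

  # invariance to arbitrary edits confined to excluded sections
  corpus2 <- corpus
  corpus2$sections[[1]]$text[2] <- "Completely different analysis text."
  res2 <- run_cpr(corpus2)
  expect_identical(retrieved_ids(res), retrieved_ids(res2))
  expect_identical(tidy(res), tidy(res2))
})

test_that("pattern cascade needs every include rule and no exclusion", {
  corpus <- mini_corpus(
    c("Insulin was injected using a syringe from the Pentora pen.",
      "Patient withdrew insulin from the Flexitra with a syringe.",
      "Insulin was inhaled during the trial syringe use described."),
    products = list("Pentora", "Flexitra", character())
  )
  res <- run_i2e(corpus)
  expect_equal(retrieved_ids(res), "R1")
  tr <- tidy(res)
  # product coverage miss: all include rules but the product one pass
  r2 <- tr[tr$id == "R2", ]
  expect_equal(r2$decision[r2$rule_id == "i2e_rule_3"], "exclude")
  expect_equal(r2$decision[r2$rule_id == "i2e_rule_1"], "pass")
  # exclusion vocabulary fires
  r3 <- tr[tr$id == "R3", ]
  expect_equal(r3$decision[r3$rule_id == "i2e_rule_4"], "exclude")
  # retrieved trace ends in an include decision
  expect_equal(utils::tail(tr$decision[tr$id == "R1"], 1), "include")
})

test_that("rulesets validate their invariants", {
  expect_error(rule_set(), class = "icsrminer_validation_error")
  lex <- lexicon("syringe", "anchor", role = "anchor")
  r <- pattern_rule("r1", "require_phrase_in_sentence", lex)
  expect_error(rule_set(r, r), class = "icsrminer_validation_error")
  only_excl <- pattern_rule("e1", "exclude_phrase", lex)
  expect_error(rule_set(only_excl), class = "icsrminer_validation_error")
  expect_s3_class(rule_set(r, only_excl), "rule_set")
})

test_that("product mentions count from narrative text or the product field", {
  lex <- default_lexicons()
  corpus <- icsr_corpus(
    id = c("A", "B", "C"),
    sections = list(
      one_section("Insulin was injected using a syringe yesterday."),
      one_section("Insulin was injected using a syringe yesterday."),
      one_section("Insulin was injected using a syringe from the Pentora.")
    ),
    products = list("Glargix FlexCart", character(), character())
  )
  res <- run_i2e(corpus)
  expect_setequal(retrieved_ids(res), c("A", "C"))
})

test_that("detectors are deterministic and monotone in the positive lexicon", {
  lab <- generate_corpus(generator_config(150, seed = 9))
  a <- run_cpr(lab$records)
  b <- run_cpr(lab$records)
  expect_identical(retrieved_ids(a), retrieved_ids(b))
  expect_identical(tidy(a), tidy(b))

  lex <- default_lexicons()
  bigger <- lex
  bigger$positive <- lexicon(c(bigger$positive$phrase, "filled", "reused"),
                             "eippcs_plus")
  r_small <- run_cpr(lab$records, lex)
  r_big <- run_cpr(lab$records, bigger)
  expect_true(all(retrieved_ids(r_small) %in% retrieved_ids(r_big)))
})

test_that("method results expose tidy/glance summaries", {
  corpus <- mini_corpus("Patient withdrew insulin with a syringe.")
  res <- run_cpr(corpus)
  g <- glance(res)
  expect_equal(g$retrieved_total, 1)
  expect_equal(g$n_corpus, 1)
  expect_named(tidy(res), c("id", "step", "rule_id", "decision"))
  expect_output(print(res), "1 of 1")
})
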