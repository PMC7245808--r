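# The three EIPPCS detection methods.  Each consumes a corpus and emits a
# method_result: the retrieved id set plus a per-record decision trace
# recording, rule by rule, why a record was kept or dropped.  The traces
# feed the miss-cause bookkeeping of the evaluation module.

new_method_result <- function(method, retrieved, trace, n_corpus) {
  structure(
    list(method = method,
         retrieved = retrieved,
         trace = trace,
         n_corpus = n_corpus),
    class = "method_result"
  )
}

#' @export
print.method_result <- function(x, ...) {
  cat(sprintf("<method_result '%s': %d of %d records retrieved>\n",
              x$method, length(x$retrieved), x$n_corpus))
  invisible(x)
}

#' Tidy a detector result into its decision trace
#'
#' @param x a `method_result`.
#' @param ... unused.
#' @return tibble with columns `id`, `step`, `rule_id`, `decision`
#'   (`"pass"`, `"exclude"` or `"include"`); every retrieved record's trace
#'   ends in an `include` decision.
#' @export
tidy.method_result <- function(x, ...) {
  x$trace
}

#' One-row summary of a detector result
#'
#' @param x a `method_result`.
#' @param ... unused.
#' @return tibble with `method`, `retrieved_total`, `n_corpus`.
#' @export
glance.method_result <- function(x, ...) {
  tibble(method = x$method, retrieved_total = length(x$retrieved),
         n_corpus = x$n_corpus)
}

#' Retrieved record ids of a detector result
#' @param result a `method_result`.
#' @return character vector of ids.
#' @export
retrieved_ids <- function(result) {
  result$retrieved
}

# build a trace tibble from a per-record list of (rule_id, decision) steps
.build_trace <- function(steps_by_id) {
  lens <- purrr::map_int(steps_by_id, ~ length(.x$rule_id))
  tibble(
    id = rep(names(steps_by_id), lens),
    step = sequence(lens),
    rule_id = unlist(purrr::map(steps_by_id, "rule_id"), use.names = FALSE),
    decision = unlist(purrr::map(steps_by_id, "decision"),
                      use.names = FALSE)
  )
}

# ---- SSA ---------------------------------------------------------------

#' Run the safety-surveillance (keyword + PT) method
#'
#' Two-filter cascade: (1) the record's narrative (all sections) must
#' contain a token whose folded form starts with the keyword -- the default
#' prefix match on `"syringe"` also covers "syringes"; (2) the record must
#' carry at least one of the filter preferred terms (by name, via the
#' hierarchy).  The trace records both filter outcomes per record.
#'
#' @param corpus a corpus tibble.
#' @param hierarchy hierarchy tibble.
#' @param pt_names PT-name filter set (default: the packaged twelve).
#' @param keyword narrative keyword (default `"syringe"`).
#' @param keyword_match `"prefix"` (default) or `"exact"` token matching.
#' @return a `method_result` named `"SSA"`.
#' @export
run_ssa <- function(corpus, hierarchy, pt_names = default_pt_names(),
                    keyword = "syringe", keyword_match = c("prefix", "exact")) {
  keyword_match <- match.arg(keyword_match)
  validate_corpus(corpus)
  kw <- fold_text(keyword)
  toks <- tokenize_corpus(corpus)
  w <- toks[toks$is_word, ]
  hit <- if (keyword_match == "prefix") {
    startsWith(w$folded, kw)
  } else {
    w$folded == kw
  }
  kw_ids <- unique(w$id[hit])
  pt_ids <- pt_filter(corpus, hierarchy, pt_names)$id

  steps <- purrr::map(corpus$id, function(id) {
    k <- id %in% kw_ids
    if (!k) {
      return(list(rule_id = "ssa_rule_1", decision = "exclude"))
    }
    p <- id %in% pt_ids
    list(rule_id = c("ssa_rule_1", "ssa_rule_2"),
         decision = c("pass", if (p) "include" else "exclude"))
  })
  names(steps) <- corpus$id
  trace <- .build_trace(steps)
  retrieved <- corpus$id[corpus$id %in% kw_ids & corpus$id %in% pt_ids]
  new_method_result("SSA", retrieved, trace, nrow(corpus))
}

# ---- CPR ---------------------------------------------------------------

#' Run the dictionary-tagging proximity method
#'
#' Named-entity-style pipeline, per record:
#' \enumerate{
#'   \item \strong{cpr_rule_1} -- isolate relevant narrative sections
#'     (sections whose name matches `exclude_sections`, by default
#'     "analysis", are dropped; text confined to them cannot drive
#'     detection).
#'   \item \strong{cpr_rule_2} -- tag the anchor keyword ("syringe(s)") in
#'     the retained text; no anchor, no retrieval.
#'   \item \strong{cpr_rule_3} -- negation filter: a negation cue in the
#'     same sentence as an anchor or EIPPCS-dictionary span disqualifies
#'     the record (the narrative states the error did \emph{not} happen).
#'   \item \strong{cpr_rule_4} -- context exclusions: inhaled-insulin-trial
#'     vocabulary anywhere in retained text, or "prefilled" within
#'     `prefilled_window` word tokens before an anchor in the same sentence
#'     (prefilled syringes are a product, not the error).
#'   \item \strong{cpr_rule_5} -- proximity rule: retrieve iff some anchor
#'     span and some EIPPCS-dictionary span lie in the same sentence at
#'     most `max_gap` word tokens apart.
#' }
#'
#' @param corpus a corpus tibble.
#' @param lexicons named list with elements `anchor`, `positive`,
#'   `negation`, `exclusion` (and optionally `product_cpr`, tagged for
#'   bookkeeping); default [default_lexicons()].
#' @param max_gap maximum word gap between anchor and cue (default 8).
#' @param exclude_sections section-name patterns dropped before tagging.
#' @param prefilled_window how many word tokens before an anchor to scan
#'   for "prefilled" (default 2, covering "prefilled syringes" and
#'   "prefilled insulin syringes").
#' @return a `method_result` named `"CPR"`.
#' @export
run_cpr <- function(corpus, lexicons = default_lexicons(), max_gap = 8L,
                    exclude_sections = "analysis", prefilled_window = 2L) {
  validate_corpus(corpus)
  toks <- tokenize_corpus(corpus, exclude_sections = exclude_sections)
  anchor <- tag_spans(toks, lexicons$anchor)
  positive <- tag_spans(toks, lexicons$positive)
  negation <- tag_spans(toks, lexicons$negation)
  exclusion <- tag_spans(toks, lexicons$exclusion)

  sent_key <- function(d) paste(d$id, d$section, d$sentence_index, sep = "\r")

  anchor_ids <- unique(anchor$id)
  # negation cue sharing a sentence with an anchor or positive span
  neg_keys <- sent_key(negation)
  neg_hit_ids <- unique(c(
    anchor$id[sent_key(anchor) %in% neg_keys],
    positive$id[sent_key(positive) %in% neg_keys]
  ))
  excl_ids <- unique(exclusion$id)

  # "prefilled" within the window before an anchor, same sentence
  w <- toks[toks$is_word, ]
  pre <- w[w$folded == "prefilled",
           c("id", "section", "sentence_index", "word_index")]
  prefilled_ids <- character()
  if (nrow(pre) > 0 && nrow(anchor) > 0) {
    j <- inner_join(anchor, pre, by = c("id", "section", "sentence_index"),
                    relationship = "many-to-many")
    fired <- j$word_index < j$token_start &
      j$word_index >= j$token_start - prefilled_window
    prefilled_ids <- unique(j$id[fired])
  }

  pairs <- proximity_match(anchor, positive, max_gap = max_gap)
  pair_ids <- unique(pairs$id)

  steps <- purrr::map(corpus$id, function(id) {
    rules <- "cpr_rule_1"
    dec <- "pass"
    if (!id %in% anchor_ids) {
      return(list(rule_id = c(rules, "cpr_rule_2"),
                  decision = c(dec, "exclude")))
    }
    rules <- c(rules, "cpr_rule_2"); dec <- c(dec, "pass")
    if (id %in% neg_hit_ids) {
      return(list(rule_id = c(rules, "cpr_rule_3"),
                  decision = c(dec, "exclude")))
    }
    rules <- c(rules, "cpr_rule_3"); dec <- c(dec, "pass")
    if (id %in% excl_ids || id %in% prefilled_ids) {
      return(list(rule_id = c(rules, "cpr_rule_4"),
                  decision = c(dec, "exclude")))
    }
    rules <- c(rules, "cpr_rule_4"); dec <- c(dec, "pass")
    ok <- id %in% pair_ids
    list(rule_id = c(rules, "cpr_rule_5"),
         decision = c(dec, if (ok) "include" else "exclude"))
  })
  names(steps) <- corpus$id
  trace <- .build_trace(steps)
  retrieved <- corpus$id[corpus$id %in% pair_ids &
                           !corpus$id %in% neg_hit_ids &
                           !corpus$id %in% excl_ids &
                           !corpus$id %in% prefilled_ids]
  new_method_result("CPR", retrieved, trace, nrow(corpus))
}

# ---- pattern rules / I2E-style cascade ---------------------------------

.rule_kinds <- c("require_phrase_in_sentence", "require_cooccurrence",
                 "require_product_mention", "exclude_phrase",
                 "exclude_section")

#' Define a linguistic pattern rule
#'
#' Building block of a sentence-scope rule cascade.  Kinds:
#' `require_phrase_in_sentence` (a lexicon phrase occurs somewhere),
#' `require_cooccurrence` (two lexicons hit the same sentence, optionally
#' within `max_gap` words), `require_product_mention` (a product-lexicon
#' phrase occurs in the text or in the record's structured product list),
#' `exclude_phrase` (any hit disqualifies the record), `exclude_section`
#' (drop matching sections before the other rules run).
#'
#' @param rule_id unique rule identifier within a ruleset.
#' @param kind one of the kinds above.
#' @param lexicon a `lexicon` object (first/only lexicon of the rule), or
#'   for `exclude_section` a character vector of section-name patterns.
#' @param lexicon2 second `lexicon` for `require_cooccurrence`.
#' @param max_gap optional word-gap bound for `require_cooccurrence`
#'   (`NULL` = same sentence suffices).
#' @return an object of class `"pattern_rule"`.
#' @export
pattern_rule <- function(rule_id, kind, lexicon = NULL, lexicon2 = NULL,
                         max_gap = NULL) {
  kind <- match.arg(kind, .rule_kinds)
  if (kind == "require_cooccurrence") {
    check_that(inherits(lexicon, "lexicon") && inherits(lexicon2, "lexicon"),
               "require_cooccurrence needs two lexicons")
  } else if (kind == "exclude_section") {
    check_that(is.character(lexicon) && length(lexicon) > 0,
               "exclude_section needs section-name patterns")
  } else {
    check_that(inherits(lexicon, "lexicon"),
               paste0(kind, " needs a lexicon"))
  }
  structure(list(rule_id = rule_id, kind = kind, lexicon = lexicon,
                 lexicon2 = lexicon2, max_gap = max_gap),
            class = "pattern_rule")
}

#' Assemble pattern rules into a ruleset
#'
#' Combination policy: a record is retrieved iff every include-kind rule
#' passes and no exclude-kind rule fires.  A ruleset must contain at least
#' one include-kind rule and unique rule ids.
#'
#' @param ... `pattern_rule` objects (or a single list of them).
#' @return an object of class `"rule_set"`.
#' @export
rule_set <- function(...) {
  rules <- list(...)
  if (length(rules) == 1 && !inherits(rules[[1]], "pattern_rule")) {
    rules <- rules[[1]]
  }
  check_that(length(rules) > 0 &&
               all(purrr::map_lgl(rules, inherits, "pattern_rule")),
             "rule_set needs pattern_rule objects",
             class = "icsrminer_validation_error")
  ids <- purrr::map_chr(rules, "rule_id")
  check_that(!any(duplicated(ids)), "rule ids must be unique",
             class = "icsrminer_validation_error")
  kinds <- purrr::map_chr(rules, "kind")
  check_that(any(kinds %in% c("require_phrase_in_sentence",
                              "require_cooccurrence",
                              "require_product_mention")),
             "a ruleset needs at least one include-kind rule",
             class = "icsrminer_validation_error")
  structure(rules, class = "rule_set")
}

#' The default sentence-pattern ruleset
#'
#' Reconstruction of the commercial-engine query described for this error:
#' an action verb (inject, administer, use, withdraw, extract, draw, mix,
#' take, and inflections) in the same sentence as the syringe anchor; the
#' anchor present; an insulin product mentioned (brands or device-class
#' words; the FlexTouch-like brands are deliberately absent from the
#' product lexicon, which reproduces the documented product-coverage miss);
#' and inhaled-insulin-trial vocabulary excluded.
#'
#' @param lexicons named lexicon list, see [default_lexicons()].
#' @return a `rule_set`.
#' @export
default_i2e_ruleset <- function(lexicons = default_lexicons()) {
  rule_set(
    pattern_rule("i2e_rule_1", "require_cooccurrence",
                 lexicon = lexicons$anchor, lexicon2 = lexicons$verbs),
    pattern_rule("i2e_rule_2", "require_phrase_in_sentence",
                 lexicon = lexicons$anchor),
    pattern_rule("i2e_rule_3", "require_product_mention",
                 lexicon = lexicons$product_i2e),
    pattern_rule("i2e_rule_4", "exclude_phrase",
                 lexicon = lexicons$exclusion)
  )
}

# evaluate one rule -> character vector of ids satisfying/firing it
.eval_rule <- function(rule, toks, corpus) {
  switch(
    rule$kind,
    require_phrase_in_sentence = unique(tag_spans(toks, rule$lexicon)$id),
    exclude_phrase = unique(tag_spans(toks, rule$lexicon)$id),
    require_cooccurrence = {
      a <- tag_spans(toks, rule$lexicon)
      b <- tag_spans(toks, rule$lexicon2)
      if (is.null(rule$max_gap)) {
        k <- function(d) paste(d$id, d$section, d$sentence_index, sep = "\r")
        unique(a$id[k(a) %in% k(b)])
      } else {
        unique(proximity_match(a, b, max_gap = rule$max_gap)$id)
      }
    },
    require_product_mention = {
      text_ids <- unique(tag_spans(toks, rule$lexicon)$id)
      phr <- rule$lexicon$phrase
      field_ids <- corpus$id[purrr::map_lgl(corpus$products, function(p) {
        if (length(p) == 0) return(FALSE)
        any(purrr::map_lgl(p, function(one) {
          wt <- paste0(" ", paste(tokenize_words(one), collapse = " "), " ")
          any(stringi::stri_detect_fixed(wt, paste0(" ", phr, " ")))
        }))
      })]
      unique(c(text_ids, field_ids))
    },
    abort(paste0("unhandled rule kind: ", rule$kind))
  )
}

#' Run a sentence-pattern rule cascade
#'
#' Evaluates every rule of the ruleset at sentence scope over the record
#' narratives (raw by default; `exclude_section` rules drop sections before
#' the others run) and retrieves the records on which all include rules
#' pass and no exclude rule fires.  The trace lists each rule's decision
#' for every record.
#'
#' @param corpus a corpus tibble.
#' @param ruleset a `rule_set`; default [default_i2e_ruleset()].
#' @return a `method_result` named `"I2E"`.
#' @export
run_i2e <- function(corpus, ruleset = default_i2e_ruleset()) {
  check_that(inherits(ruleset, "rule_set"),
             "ruleset must be a rule_set object",
             class = "icsrminer_validation_error")
  validate_corpus(corpus)
  excl_sections <- unlist(purrr::map(
    purrr::keep(ruleset, ~ .x$kind == "exclude_section"), "lexicon"))
  toks <- tokenize_corpus(corpus, exclude_sections = excl_sections %||%
                            character())
  rules <- purrr::discard(ruleset, ~ .x$kind == "exclude_section")
  is_exclude <- purrr::map_lgl(rules, ~ .x$kind == "exclude_phrase")
  hit_ids <- purrr::map(rules, .eval_rule, toks = toks, corpus = corpus)

  verdict <- purrr::map_lgl(corpus$id, function(id) {
    inc_ok <- all(purrr::map_lgl(which(!is_exclude),
                                 ~ id %in% hit_ids[[.x]]))
    exc_ok <- !any(purrr::map_lgl(which(is_exclude),
                                  ~ id %in% hit_ids[[.x]]))
    inc_ok && exc_ok
  })
  retrieved <- corpus$id[verdict]

  steps <- purrr::map(seq_len(nrow(corpus)), function(i) {
    id <- corpus$id[i]
    dec <- purrr::map_chr(seq_along(rules), function(r) {
      hit <- id %in% hit_ids[[r]]
      if (is_exclude[r]) {
        if (hit) "exclude" else "pass"
      } else {
        if (hit) "pass" else "exclude"
      }
    })
    rid <- purrr::map_chr(rules, "rule_id")
    if (verdict[i]) {
      rid <- c(rid, "final")
      dec <- c(dec, "include")
    }
    list(rule_id = rid, decision = dec)
  })
  names(steps) <- corpus$id
  trace <- .build_trace(steps)
  new_method_result("I2E", retrieved, trace, nrow(corpus))
}
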