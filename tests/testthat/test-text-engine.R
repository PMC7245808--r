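test_that("sentence segmentation follows the terminator + capital rule", {
  s <- segment_sentences("He used a syringe. She did not.")
  expect_equal(max(s$sentence_index), 1)
  expect_equal(nrow(segment_sentences("")), 0)

  # abbreviation allowlist guards false splits
  s <- segment_sentences("Insulin pens (e.g. Pentora) are prefilled. Use once.")
  expect_equal(max(s$sentence_index), 1)

  # no uppercase/digit after terminator -> no split
  s <- segment_sentences("dose was 4 iu. then repeated")
  expect_equal(max(s$sentence_index), 0)
})

test_that("parentheses become separate punctuation tokens in one sentence", {
  s <- segment_sentences("Mixed in one syringe (to minimise injections)")
  expect_equal(max(s$sentence_index), 0)
  expect_equal(sum(!s$is_word), 2)
  expect_equal(s$surface[!s$is_word], c("(", ")"))
  expect_equal(s$folded[s$is_word],
               c("mixed", "in", "one", "syringe", "to", "minimise",
                 "injections"))
  # word_index numbers word tokens only
  expect_equal(s$word_index[s$is_word], 0:6)
})

test_that("token offsets reconstruct the non-whitespace content in order", {
  txt <- "She drew up 10 IU. Re-injected it (slowly)!  Done."
  s <- segment_sentences(txt)
  expect_true(all(diff(s$char_start) > 0))
  expect_true(all(s$char_end > s$char_start))
  rebuilt <- paste(s$surface, collapse = "")
  expect_equal(rebuilt, gsub("\\s+", "", txt))
  # offsets index into the original string
  expect_equal(substr(txt, s$char_start[2] + 1, s$char_end[2]), "drew")
})

test_that("tagging is case-insensitive and takes the longest match", {
  toks <- token_table("patient DREW UP insulin")
  lex <- lexicon(c("drew up"), "cues")
  spans <- tag_spans(toks, lex)
  expect_equal(nrow(spans), 1)
  expect_equal(spans$token_start, 1)
  expect_equal(spans$token_end, 3)

  toks <- token_table("an insulin syringe")
  lex <- lexicon(c("insulin", "insulin syringe"), "cues")
  spans <- tag_spans(toks, lex)
  expect_equal(spans$phrase, "insulin syringe")
})

test_that("tagging is invariant under case changes of the input", {
  txt <- "Patient Mixed Insulin In One Syringe."
  lex <- lexicon(c("mixed", "syringe", "one syringe"), "cues")
  a <- tag_spans(token_table(tolower(txt)), lex)
  b <- tag_spans(token_table(toupper(txt)), lex)
  expect_equal(a[c("token_start", "token_end", "phrase")],
               b[c("token_start", "token_end", "phrase")])
})

test_that("tagging agrees with the brute-force oracle", {
  set.seed(101)
  for (i in 1:60) {
    case <- random_tag_case()
    lex <- lexicon(case$phrases, "rand")
    toks <- token_table(case$sentences)
    got <- tag_spans(toks, lex)
    for (si in seq_along(case$sentences) - 1L) {
      words <- toks$folded[toks$sentence_index == si]
      want <- oracle_scan(words, lex$tokens)
      g <- got[got$sentence_index == si, ]
      expect_equal(g$token_start, want$token_start)
      expect_equal(g$token_end, want$token_end)
      expect_equal(g$phrase, want$phrase)
    }
  }
})

test_that("proximity pairs obey the same-sentence and word-gap rules", {
  # anchor at [7,8), positive at [0,1): 6 intervening words
  toks <- token_table("drew a b c d e f syringe")
  anchor <- tag_spans(toks, lexicon("syringe", "anchor"))
  pos <- tag_spans(toks, lexicon("drew", "pos"))
  expect_equal(anchor$token_start, 7)
  expect_equal(nrow(proximity_match(anchor, pos, max_gap = 8)), 1)
  expect_equal(proximity_match(anchor, pos, max_gap = 6)$gap, 6)
  expect_equal(nrow(proximity_match(anchor, pos, max_gap = 5)), 0)

  # adjacency counts as gap 0 ("equal or less than")
  toks <- token_table("drew syringe")
  a <- tag_spans(toks, lexicon("syringe", "anchor"))
  p <- tag_spans(toks, lexicon("drew", "pos"))
  expect_equal(nrow(proximity_match(a, p, max_gap = 0)), 1)

  # different sentences never pair
  toks <- token_table(c("patient drew insulin", "a syringe was found"))
  a <- tag_spans(toks, lexicon("syringe", "anchor"))
  p <- tag_spans(toks, lexicon("drew", "pos"))
  expect_equal(nrow(proximity_match(a, p, max_gap = 100)), 0)
})

test_that("proximity matching is monotone in the gap and matches the oracle", {
  set.seed(202)
  for (i in 1:40) {
    case <- random_tag_case()
    toks <- token_table(case$sentences)
    a <- tag_spans(toks, lexicon(case$phrases[1], "anchor"))
    p <- tag_spans(toks, lexicon(case$phrases[-1], "pos"))
    prev <- -1
    for (g in c(0, 1, 2, 5)) {
      got <- nrow(proximity_match(a, p, max_gap = g))
      expect_equal(got, oracle_proximity(a, p, g))
      expect_gte(got, prev)
      prev <- got
    }
  }
})

test_that("section isolation matches names case-insensitively as substrings", {
  secs <- tibble::tibble(name = c("narrative", "analysis results"),
                         text = c("a", "b"))
  expect_equal(isolate_sections(secs, "analysis")$name, "narrative")
  expect_equal(isolate_sections(secs, character()), secs)
  one <- tibble::tibble(name = "Analysis Results", text = "x")
  expect_equal(nrow(isolate_sections(one, "analysis")), 0)
})
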