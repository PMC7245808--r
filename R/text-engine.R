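# Narrative pre-processing: section isolation, rule-based sentence
# segmentation, tokenization with character offsets, case-insensitive
# dictionary tagging (longest match wins) and the same-sentence word
# proximity matcher.
#
# All matching is done on case-folded tokens.  Tokens are classified as
# word tokens (letters/digits, internal hyphens and apostrophes kept) or
# punctuation tokens; dictionary phrases match over the word-token
# sequence, and word gaps are counted in word tokens only.

# abbreviations that must not terminate a sentence
.abbrev <- c("e.g.", "i.e.", "dr.", "mr.", "mrs.", "ms.", "vs.", "approx.",
             "etc.", "no.", "inc.", "st.")

.token_regex <- "[\\p{L}\\p{N}]+(?:['’-][\\p{L}\\p{N}]+)*|[^\\p{L}\\p{N}\\s]+"

# fold a phrase into its word tokens (punctuation dropped)
tokenize_words <- function(text) {
  m <- stringi::stri_extract_all_regex(fold_text(text), .token_regex)[[1]]
  if (length(m) == 1 && is.na(m)) return(character())
  m[stringi::stri_detect_regex(m, "^[\\p{L}\\p{N}]")]
}

#' Segment free text into sentences with token offsets
#'
#' Deterministic rule-based segmentation: a run of `.`, `!` or `?` followed
#' by whitespace and an upper-case letter or digit ends a sentence, unless
#' the terminator closes a known abbreviation ("e.g.", "i.e.", "Dr.", ...).
#' Each sentence is tokenised into word and punctuation tokens with 0-based
#' half-open character offsets into the input text; concatenating token
#' surfaces in order reconstructs the non-whitespace content.
#'
#' @param text a single string (one narrative section).
#' @return tibble with columns `sentence_index` (0-based), `token_index`
#'   (0-based within sentence, all tokens), `word_index` (0-based within
#'   sentence over word tokens only; `NA` for punctuation), `surface`,
#'   `folded`, `char_start`, `char_end`, `is_word`.  Empty text gives zero
#'   rows.
#' @export
#' @examples
#' segment_sentences("He used a syringe. She did not.")
segment_sentences <- function(text) {
  empty <- tibble(sentence_index = integer(), token_index = integer(),
                  word_index = integer(), surface = character(),
                  folded = character(), char_start = integer(),
                  char_end = integer(), is_word = logical())
  core <- .segment_core(text)
  if (is.null(core)) return(empty)
  as_tibble(core)
}

# vector-returning core of segment_sentences (one tibble allocation per
# corpus, not per section, keeps tokenisation cheap)
.segment_core <- function(text) {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    return(NULL)
  }

  # candidate sentence boundaries, with the abbreviation allowlist guard
  cand <- stringi::stri_locate_all_regex(
    text, "[.!?]+(?=\\s+[\\p{Lu}\\p{N}])")[[1]]
  breaks <- integer()
  if (!is.na(cand[1, 1])) {
    ends <- cand[, 2]
    last_word <- stringi::stri_extract_last_regex(
      stringi::stri_sub(text, 1, ends), "\\S+")
    # "(e.g." must still be recognised as the abbreviation "e.g."
    last_word <- stringi::stri_replace_first_regex(
      last_word, "^[^\\p{L}\\p{N}]+", "")
    breaks <- ends[!fold_text(last_word) %in% .abbrev]
  }

  loc <- stringi::stri_locate_all_regex(text, .token_regex)[[1]]
  if (is.na(loc[1, 1])) return(NULL)
  surface <- stringi::stri_sub(text, loc[, 1], loc[, 2])
  is_word <- stringi::stri_detect_regex(surface, "^[\\p{L}\\p{N}]")
  # a token starting after k boundaries belongs to sentence k
  sid_raw <- findInterval(loc[, 1] - 1L, breaks)
  sid <- match(sid_raw, unique(sid_raw))        # dense, 1-based, contiguous
  lens <- tabulate(sid)
  token_index <- sequence(lens) - 1L
  cw <- cumsum(is_word)
  sent_start <- match(unique(sid), sid)
  base <- (cw[sent_start] - is_word[sent_start])[sid]
  word_index <- ifelse(is_word, cw - base - 1L, NA_integer_)
  list(
    sentence_index = sid - 1L,
    token_index = token_index,
    word_index = as.integer(word_index),
    surface = surface,
    folded = fold_text(surface),
    char_start = as.integer(loc[, 1] - 1L),
    char_end = as.integer(loc[, 2]),
    is_word = is_word
  )
}

#' Drop excluded narrative sections
#'
#' Keeps the sections whose name does not match any exclude pattern
#' (case-insensitive substring match), in their original order.  Used to
#' remove sections describing subsequent physical/chemical analyses of
#' returned product, whose text must not drive detection.
#'
#' @param sections tibble with columns `name`, `text` (one record's
#'   sectioned narrative).
#' @param exclude_names character vector of section-name patterns; a
#'   section is dropped when its folded name contains any pattern.
#' @return the retained sections tibble (possibly zero rows).
#' @export
#' @examples
#' s <- tibble::tibble(name = c("narrative", "analysis results"),
#'                     text = c("a", "b"))
#' isolate_sections(s, "analysis")
isolate_sections <- function(sections, exclude_names = character()) {
  if (length(exclude_names) == 0 || nrow(sections) == 0) return(sections)
  pat <- fold_text(exclude_names)
  hit <- purrr::map_lgl(fold_text(sections$name), function(nm) {
    any(stringi::stri_detect_fixed(nm, pat))
  })
  sections[!hit, , drop = FALSE]
}

#' Tokenise a whole corpus into a long sentence/token table
#'
#' Runs [isolate_sections()] and [segment_sentences()] over every record
#' and stacks the result, keyed by record id and section name.  This long
#' table is the substrate for [tag_spans()] and all detectors.
#'
#' @param corpus a corpus tibble.
#' @param exclude_sections section-name patterns to drop before
#'   tokenisation (default: none).
#' @return tibble with columns `id`, `section`, plus the columns of
#'   [segment_sentences()].
#' @export
tokenize_corpus <- function(corpus, exclude_sections = character()) {
  acc <- list()
  k <- 0L
  for (i in seq_len(nrow(corpus))) {
    secs <- isolate_sections(corpus$sections[[i]], exclude_sections)
    if (nrow(secs) == 0) next
    for (j in seq_len(nrow(secs))) {
      core <- .segment_core(secs$text[j])
      if (is.null(core)) next
      core$id <- rep(corpus$id[i], length(core$surface))
      core$section <- rep(secs$name[j], length(core$surface))
      k <- k + 1L
      acc[[k]] <- core
    }
  }
  if (k == 0L) {
    return(tibble(id = character(), section = character(),
                  sentence_index = integer(), token_index = integer(),
                  word_index = integer(), surface = character(),
                  folded = character(), char_start = integer(),
                  char_end = integer(), is_word = logical()))
  }
  cols <- names(acc[[1]])
  out <- purrr::map(setNames(cols, cols), function(cl) {
    unlist(purrr::map(acc, cl), use.names = FALSE)
  })
  as_tibble(out) |>
    select("id", "section", dplyr::everything())
}

# index lexicon phrases by first token -> list of token vectors sorted by
# decreasing length (so the scan takes the longest match at a position)
.lexicon_index <- function(lex) {
  toks <- lex$tokens
  first <- purrr::map_chr(toks, 1)
  split(toks, first) |>
    purrr::map(function(g) g[order(-lengths(g))])
}

# left-to-right longest-match scan over one folded word vector.
# Returns 0-based half-open [start, end) word-index ranges; matching
# resumes after a matched span, so matches from one lexicon never overlap.
.scan_words <- function(words, index) {
  n <- length(words)
  starts <- integer(); ends <- integer(); phrases <- character()
  i <- 1L
  while (i <= n) {
    cands <- index[[words[i]]]
    advanced <- FALSE
    if (!is.null(cands)) {
      for (ph in cands) {
        L <- length(ph)
        if (i + L - 1L <= n && all(words[i:(i + L - 1L)] == ph)) {
          starts <- c(starts, i - 1L)
          ends <- c(ends, i - 1L + L)
          phrases <- c(phrases, paste(ph, collapse = " "))
          i <- i + L
          advanced <- TRUE
          break
        }
      }
    }
    if (!advanced) i <- i + 1L
  }
  list(starts = starts, ends = ends, phrases = phrases)
}

#' Tag dictionary matches in a token table
#'
#' Case-insensitive dictionary tagging over folded word tokens: all maximal
#' matches of the lexicon's phrases, longest match winning at a position,
#' with matching resuming after each matched span (no overlapping matches
#' from the same lexicon).  Punctuation tokens are transparent to phrase
#' positions only in the sense that phrases are matched over the word-token
#' subsequence of each sentence.
#'
#' @param tokens long token table from [tokenize_corpus()] (or
#'   [segment_sentences()] output augmented with `id` and `section`).
#' @param lex a `lexicon` object.
#' @return tibble of tag spans: `id`, `section`, `sentence_index`,
#'   `token_start`, `token_end` (0-based half-open *word*-index range),
#'   `lexicon`, `phrase`.
#' @export
tag_spans <- function(tokens, lex) {
  check_that(inherits(lex, "lexicon"), "lex must be a lexicon object")
  empty <- tibble(id = character(), section = character(),
                  sentence_index = integer(), token_start = integer(),
                  token_end = integer(), lexicon = character(),
                  phrase = character())
  if (nrow(tokens) == 0) return(empty)
  words <- tokens[tokens$is_word, c("id", "section", "sentence_index",
                                    "folded")]
  if (nrow(words) == 0) return(empty)
  index <- .lexicon_index(lex)
  firsts <- names(index)
  # only sentences containing some first token of the lexicon can match
  key <- paste(words$id, words$section, words$sentence_index, sep = "\r")
  hit_keys <- unique(key[words$folded %in% firsts])
  if (length(hit_keys) == 0) return(empty)
  keep <- key %in% hit_keys
  words <- words[keep, ]
  key <- key[keep]
  groups <- split(seq_len(nrow(words)), factor(key, levels = unique(key)))
  out <- purrr::map(groups, function(ix) {
    sc <- .scan_words(words$folded[ix], index)
    if (length(sc$starts) == 0) return(NULL)
    tibble(
      id = words$id[ix[1]],
      section = words$section[ix[1]],
      sentence_index = words$sentence_index[ix[1]],
      token_start = sc$starts,
      token_end = sc$ends,
      lexicon = attr(lex, "name"),
      phrase = sc$phrases
    )
  })
  out <- purrr::compact(out)
  if (length(out) == 0) return(empty)
  bind_rows(out)
}

#' Pair anchor and cue spans within a word-gap window
#'
#' Returns every (anchor, positive) span pair that lies in the same
#' sentence of the same section of the same record with at most `max_gap`
#' word tokens strictly between the spans' nearest edges.  Adjacent spans
#' have gap 0; overlapping spans also count as gap 0.  Punctuation tokens
#' are never counted: the window is "8 words", not 8 tokens.
#'
#' @param anchor_spans,positive_spans span tibbles from [tag_spans()].
#' @param max_gap non-negative integer word gap (default 8).
#' @return tibble with one row per qualifying pair: `id`, `section`,
#'   `sentence_index`, anchor span columns (`anchor_start`, `anchor_end`,
#'   `anchor_phrase`), positive span columns (`positive_start`,
#'   `positive_end`, `positive_phrase`) and `gap`.
#' @export
proximity_match <- function(anchor_spans, positive_spans, max_gap = 8L) {
  check_that(is.numeric(max_gap) && max_gap >= 0, "max_gap must be >= 0")
  a <- anchor_spans |>
    select("id", "section", "sentence_index",
           anchor_start = "token_start", anchor_end = "token_end",
           anchor_phrase = "phrase")
  p <- positive_spans |>
    select("id", "section", "sentence_index",
           positive_start = "token_start", positive_end = "token_end",
           positive_phrase = "phrase")
  pairs <- inner_join(a, p, by = c("id", "section", "sentence_index"),
                      relationship = "many-to-many")
  if (nrow(pairs) == 0) {
    pairs$gap <- integer()
    return(pairs)
  }
  pairs$gap <- pmax(
    0L,
    pmax(pairs$anchor_start, pairs$positive_start) -
      pmin(pairs$anchor_end, pairs$positive_end)
  )
  pairs[pairs$gap <= max_gap, , drop = FALSE]
}

# full retained text of each record, one string per record, sections joined
# by newlines -- used for keyword search and n-gram pooling
retained_text <- function(corpus, exclude_sections = character()) {
  purrr::map2_chr(corpus$id, corpus$sections, function(id, secs) {
    secs <- isolate_sections(secs, exclude_sections)
    paste(secs$text, collapse = "\n")
  }) |>
    setNames(corpus$id)
}
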