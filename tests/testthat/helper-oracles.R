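# Naive reference implementations used as independent oracles.  They share
# nothing with the package's scan/join implementations: the tagger
# enumerates every (position, phrase) window, then resolves
# longest-at-earliest-position with resumption; the proximity oracle loops
# over all span pairs and counts intervening word positions explicitly.

oracle_scan <- function(words, phrase_tokens) {
  cand <- list()
  for (s in seq_along(words)) {
    for (p in phrase_tokens) {
      L <- length(p)
      if (s + L - 1 <= length(words) && all(words[s:(s + L - 1)] == p)) {
        cand[[length(cand) + 1]] <- list(start = s, len = L,
                                         phrase = paste(p, collapse = " "))
      }
    }
  }
  res <- list()
  pos <- 1
  repeat {
    avail <- Filter(function(cc) cc$start >= pos, cand)
    if (length(avail) == 0) break
    minstart <- min(vapply(avail, function(cc) cc$start, 1))
    at <- Filter(function(cc) cc$start == minstart, avail)
    best <- at[[which.max(vapply(at, function(cc) cc$len, 1))]]
    res[[length(res) + 1]] <- best
    pos <- best$start + best$len
  }
  if (length(res) == 0) {
    return(data.frame(token_start = integer(), token_end = integer(),
                      phrase = character()))
  }
  data.frame(
    token_start = vapply(res, function(r) r$start - 1L, 1L),
    token_end = vapply(res, function(r) r$start - 1L + r$len, 1L),
    phrase = vapply(res, function(r) r$phrase, "")
  )
}

# spans: data frame with sentence keys and token_start/token_end
oracle_proximity <- function(anchor, positive, max_gap) {
  hits <- 0L
  pairs <- list()
  if (nrow(anchor) == 0 || nrow(positive) == 0) return(0L)
  for (i in seq_len(nrow(anchor))) {
    for (j in seq_len(nrow(positive))) {
      same <- anchor$id[i] == positive$id[j] &&
        anchor$section[i] == positive$section[j] &&
        anchor$sentence_index[i] == positive$sentence_index[j]
      if (!same) next
      a <- c(anchor$token_start[i], anchor$token_end[i])
      b <- c(positive$token_start[j], positive$token_end[j])
      between <- if (a[2] <= b[1]) {
        length(seq_len(b[1] - a[2]))     # word positions strictly between
      } else if (b[2] <= a[1]) {
        length(seq_len(a[1] - b[2]))
      } else {
        0L                                # overlap
      }
      if (between <= max_gap) hits <- hits + 1L
    }
  }
  hits
}

# small random corpus of word-token sentences plus a random lexicon
random_tag_case <- function(vocab = letters[1:10]) {
  n_sent <- sample(1:4, 1)
  sentences <- vapply(seq_len(n_sent), function(i) {
    paste(sample(vocab, sample(3:10, 1), replace = TRUE), collapse = " ")
  }, "")
  repeat {
    n_phr <- sample(2:6, 1)
    phrases <- unique(vapply(seq_len(n_phr), function(i) {
      paste(sample(vocab, sample(1:3, 1), replace = TRUE), collapse = " ")
    }, ""))
    if (length(phrases) >= 2) break
  }
  list(sentences = sentences, phrases = phrases)
}
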