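# Fixtures built in code: miniature corpora, a tiny hierarchy, and the
# published example narratives (trademark glyphs included; ingest strips
# them).

mini_hierarchy <- function() {
  tibble::tibble(
    pt_code = c("P001", "P002", "P003", "P004"),
    pt_name = c("Device malfunction", "Wrong technique in product usage process",
                "Headache", "Intentional device misuse"),
    hlgt_name = c("Device issues",
                  "Medication errors, and other product use errors and issues",
                  "Headaches",
                  "Medication errors, and other product use errors and issues")
  )
}

one_section <- function(text) {
  tibble::tibble(name = "narrative", text = text)
}

mini_corpus <- function(texts, pt_codes = NULL, ids = NULL,
                        products = NULL) {
  if (is.null(ids)) ids <- paste0("R", seq_along(texts))
  icsr_corpus(
    id = ids,
    sections = lapply(texts, one_section),
    pt_codes = pt_codes,
    products = products
  )
}

example_narratives <- function() {
  c(
    mix = paste0(
      "It was reported that the patient had been using Levemir® ",
      "PenFill® and NovoRapid® PenFill® for the last 2 years. ",
      "It was reported that Levemir® and NovoRapid® was ",
      "intentionally mixed in the one syringe (to minimise injections in ",
      "paediatrics patients)"),
    air_bubble = paste0(
      "A patient experienced a pen with air inside and a bubble. She ",
      "verified this problem as insulin was not coming out of the pen. ",
      "For this reason, the consumer is taking insulin with syringe."),
    withdrew = paste0(
      "A man reported that he mistakenly withdrew insulin out of the ",
      "NovoLog® FlexPen® with a regular syringe and then ",
      "injected it back into the FlexPen®.")
  )
}

# token tibble for a hand-built set of sentences (word tokens only),
# bypassing segmentation -- used to exercise tagging/proximity in isolation
token_table <- function(sentences, id = "r1", section = "narrative") {
  parts <- lapply(seq_along(sentences), function(si) {
    w <- strsplit(sentences[[si]], " ", fixed = TRUE)[[1]]
    tibble::tibble(
      id = id, section = section, sentence_index = si - 1L,
      token_index = seq_along(w) - 1L, word_index = seq_along(w) - 1L,
      surface = w, folded = tolower(w),
      char_start = 0L, char_end = 0L, is_word = TRUE
    )
  })
  dplyr::bind_rows(parts)
}
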