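# Domain types and file I/O: ICSR corpora (JSONL), mock MedDRA hierarchy
# (TSV), rule lexicons (plain text) and gold annotations (CSV).

icsr_sources <- c("spontaneous", "solicited", "literature", "clinical_trial",
                  "unknown")

#' Build an ICSR corpus tibble
#'
#' An ICSR corpus is a tibble with one row per individual case safety
#' report: `id` (unique string), `sections` (list-column of tibbles with
#' columns `name`, `text` -- the narrative split into named sections),
#' `pt_codes` (list-column of MedDRA preferred-term codes), `products`
#' (list-column of product-name strings) and `source` (one of
#' `"spontaneous"`, `"solicited"`, `"literature"`, `"clinical_trial"`,
#' `"unknown"`).
#'
#' @param id character vector of unique, non-empty record ids.
#' @param sections list of tibbles/data frames with columns `name`, `text`;
#'   each record needs at least one section and unique section names.
#' @param pt_codes list of character vectors (may be empty).
#' @param products list of character vectors (may be empty).
#' @param source character vector of source tags.
#' @param normalize if `TRUE` (default) apply [normalize_narrative()] to all
#'   section text.
#' @return a validated corpus tibble.
#' @export
icsr_corpus <- function(id, sections, pt_codes = NULL, products = NULL,
                        source = "unknown", normalize = TRUE) {
  n <- length(id)
  pt_codes <- pt_codes %||% rep(list(character()), n)
  products <- products %||% rep(list(character()), n)
  source <- rep_len(source, n)
  sections <- purrr::map(sections, function(s) {
    s <- as_tibble(s)
    s$name <- as.character(s$name)
    s$text <- if (normalize) normalize_narrative(as.character(s$text)) else
      as.character(s$text)
    s[, c("name", "text")]
  })
  corpus <- tibble(
    id = as.character(id),
    sections = sections,
    pt_codes = purrr::map(pt_codes, as.character),
    products = purrr::map(products, as.character),
    source = as.character(source)
  )
  validate_corpus(corpus)
  corpus
}

#' Validate an ICSR corpus tibble
#'
#' Checks the corpus invariants: unique non-empty ids, at least one
#' narrative section per record, unique section names within a record, and
#' recognised source tags.
#'
#' @param corpus a corpus tibble (see [icsr_corpus()]).
#' @return the corpus, invisibly; errors on violation.
#' @export
validate_corpus <- function(corpus) {
  need <- c("id", "sections", "pt_codes", "products", "source")
  check_that(all(need %in% names(corpus)),
             paste("corpus is missing column(s):",
                   paste(setdiff(need, names(corpus)), collapse = ", ")))
  check_that(all(nzchar(corpus$id)), "corpus ids must be non-empty")
  dup <- corpus$id[duplicated(corpus$id)]
  check_that(length(dup) == 0,
             paste0("duplicate record id(s): ",
                    paste(unique(dup), collapse = ", ")),
             class = "icsrminer_validation_error")
  purrr::walk2(corpus$id, corpus$sections, function(id, s) {
    check_that(nrow(s) >= 1, paste0("record ", id, " has no sections"))
    check_that(!any(duplicated(s$name)),
               paste0("record ", id, " has duplicate section names"))
  })
  bad <- setdiff(unique(corpus$source), icsr_sources)
  check_that(length(bad) == 0,
             paste0("unknown source tag(s): ", paste(bad, collapse = ", ")))
  invisible(corpus)
}

#' Read an ICSR corpus from a JSONL file
#'
#' One JSON object per line with keys `id`, `sections` (array of objects
#' with `name` and `text`), `pt_codes`, `products` and `source`.  Narrative
#' text is normalised on ingest (NFKC, trademark glyphs stripped).
#'
#' @param path path to a JSONL corpus file.
#' @return a corpus tibble.
#' @export
read_corpus <- function(path) {
  check_that(file.exists(path), paste0("no such corpus file: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(icsr_corpus(character(), list()))
  }
  recs <- purrr::imap(lines, function(line, i) {
    obj <- tryCatch(
      jsonlite::fromJSON(line, simplifyDataFrame = FALSE,
                         simplifyVector = FALSE),
      error = function(e) {
        abort(paste0("malformed corpus line ", i, ": ", conditionMessage(e)),
              class = "icsrminer_parse_error")
      }
    )
    check_that(!is.null(obj$id) && nzchar(obj$id),
               paste0("corpus line ", i, ": missing id"),
               class = "icsrminer_parse_error")
    check_that(length(obj$sections) >= 1,
               paste0("corpus line ", i, ": record needs >= 1 section"),
               class = "icsrminer_parse_error")
    list(
      id = as.character(obj$id),
      sections = tibble(
        name = purrr::map_chr(obj$sections, "name"),
        text = purrr::map_chr(obj$sections, "text")
      ),
      pt_codes = as.character(unlist(obj$pt_codes)),
      products = as.character(unlist(obj$products)),
      source = as.character(obj$source %||% "unknown")
    )
  })
  icsr_corpus(
    id = purrr::map_chr(recs, "id"),
    sections = purrr::map(recs, "sections"),
    pt_codes = purrr::map(recs, "pt_codes"),
    products = purrr::map(recs, "products"),
    source = purrr::map_chr(recs, "source")
  )
}

#' Write an ICSR corpus to a JSONL file
#'
#' @param corpus a corpus tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  lines <- purrr::pmap_chr(corpus, function(id, sections, pt_codes,
                                            products, source) {
    jsonlite::toJSON(
      list(
        id = jsonlite::unbox(id),
        sections = purrr::pmap(sections, function(name, text) {
          list(name = jsonlite::unbox(name), text = jsonlite::unbox(text))
        }),
        pt_codes = as.character(pt_codes),
        products = as.character(products),
        source = jsonlite::unbox(source)
      ),
      auto_unbox = FALSE
    )
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a mock MedDRA hierarchy table
#'
#' Tab-separated file with header columns `pt_code`, `pt_name`,
#' `hlgt_name`: one row per preferred term, mapping it to its high level
#' group term.  Names are trimmed; duplicate `pt_code` rows are allowed
#' only if they agree on both names.
#'
#' @param path path to the TSV file.
#' @return a tibble with columns `pt_code`, `pt_name`, `hlgt_name`.
#' @export
read_hierarchy <- function(path) {
  check_that(file.exists(path), paste0("no such hierarchy file: ", path))
  h <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("pt_code", "pt_name", "hlgt_name")
  check_that(all(need %in% names(h)),
             paste0("hierarchy file missing column(s): ",
                    paste(setdiff(need, names(h)), collapse = ", ")),
             class = "icsrminer_parse_error")
  h <- h |>
    select(dplyr::all_of(need)) |>
    mutate(across(dplyr::everything(), stringr::str_trim)) |>
    distinct()
  conflict <- h |> count(.data$pt_code) |> filter(n > 1)
  check_that(nrow(conflict) == 0,
             paste0("conflicting hierarchy rows for pt_code(s): ",
                    paste(conflict$pt_code, collapse = ", ")),
             class = "icsrminer_validation_error")
  h
}

#' Collapse a record's PT codes to HLGT names
#'
#' Maps a set of MedDRA preferred-term codes to the distinct high level
#' group terms they roll up to, via the hierarchy table.
#'
#' @param pt_codes character vector of PT codes.
#' @param hierarchy hierarchy tibble from [read_hierarchy()].
#' @param strict if `TRUE`, an unknown code is an error; default `FALSE`
#'   skips unknown codes (synthetic coding noise deliberately includes
#'   off-dictionary terms).
#' @return character vector of distinct HLGT names.
#' @export
collapse_to_hlgt <- function(pt_codes, hierarchy, strict = FALSE) {
  pt_codes <- as.character(pt_codes)
  idx <- match(pt_codes, hierarchy$pt_code)
  if (anyNA(idx) && strict) {
    abort(paste0("unknown pt_code(s): ",
                 paste(pt_codes[is.na(idx)], collapse = ", ")),
          class = "icsrminer_validation_error")
  }
  unique(hierarchy$hlgt_name[idx[!is.na(idx)]])
}

# ---- lexicons ----------------------------------------------------------

lexicon_roles <- c("positive", "product", "anchor", "negation", "exclusion")

#' Build a rule lexicon
#'
#' A lexicon is a named list of short phrases (1--6 word tokens each) with a
#' role in the detection cascades: `positive` (EIPPCS phrase dictionary),
#' `product` (insulin product names), `anchor` (the syringe keyword and its
#' surface variants), `negation` (cues like "did not") or `exclusion`
#' (inhaled-insulin-trial vocabulary).  Phrases are case-folded and
#' tokenised with the same tokenizer as narratives, and deduplicated
#' preserving first occurrence.
#'
#' @param phrases character vector of phrases.
#' @param name lexicon name.
#' @param role one of `r paste0('"', lexicon_roles, '"', collapse = ", ")`.
#' @return an object of class `"lexicon"`: a tibble with columns `phrase`
#'   (folded string) and `tokens` (list of folded word-token vectors), with
#'   attributes `name` and `role`.
#' @export
lexicon <- function(phrases, name, role = "positive") {
  role <- match.arg(role, lexicon_roles)
  phrases <- fold_text(stringr::str_squish(as.character(phrases)))
  phrases <- phrases[nzchar(phrases)]
  toks <- purrr::map(phrases, function(p) tokenize_words(p))
  keep <- !duplicated(purrr::map_chr(toks, paste, collapse = " ")) &
    lengths(toks) > 0
  phrases <- purrr::map_chr(toks[keep], paste, collapse = " ")
  toks <- toks[keep]
  check_that(length(phrases) > 0,
             paste0("lexicon '", name, "' is empty after parsing"),
             class = "icsrminer_validation_error")
  check_that(all(lengths(toks) <= 6),
             paste0("lexicon '", name, "' has phrases longer than 6 tokens"))
  out <- tibble(phrase = phrases, tokens = toks)
  structure(out, name = name, role = role,
            class = c("lexicon", class(out)))
}

#' Read a lexicon from a plain-text file
#'
#' UTF-8 text, one phrase per line; `#` starts a comment line; blank lines
#' ignored.  A file that yields no phrases is an error -- a detector with an
#' empty dictionary is meaningless.
#'
#' @param path path to the lexicon file.
#' @param name lexicon name (defaults to the file stem).
#' @param role lexicon role, see [lexicon()].
#' @return a `lexicon` object.
#' @export
read_lexicon <- function(path, name = NULL,
                         role = "positive") {
  check_that(file.exists(path), paste0("no such lexicon file: ", path))
  name <- name %||% tools::file_path_sans_ext(basename(path))
  lines <- readr::read_lines(path)
  lines <- lines[!stringr::str_starts(stringr::str_trim(lines), "#")]
  lines <- lines[nzchar(stringr::str_trim(lines))]
  check_that(length(lines) > 0,
             paste0("lexicon file '", path, "' has no phrases"),
             class = "icsrminer_validation_error")
  lexicon(lines, name = name, role = role)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon '%s' (%s): %d phrases>\n",
              attr(x, "name"), attr(x, "role"), nrow(x)))
  print(as_tibble(x), ...)
  invisible(x)
}

# ---- annotations -------------------------------------------------------

annotation_labels <- c("EIPPCS", "non_EIPPCS")

#' Read gold annotations
#'
#' CSV with header `id,label`; `label` is `EIPPCS` or `non_EIPPCS`.  Each
#' id may be labelled at most once.
#'
#' @param path path to the CSV file.
#' @return tibble with columns `id`, `label`.
#' @export
read_annotations <- function(path) {
  check_that(file.exists(path), paste0("no such annotation file: ", path))
  a <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  check_that(all(c("id", "label") %in% names(a)),
             "annotation file needs columns id, label",
             class = "icsrminer_parse_error")
  validate_annotations(a[, c("id", "label")])
}

#' Validate an annotation tibble
#' @param annotations tibble with columns `id`, `label`.
#' @return the tibble, invisibly validated and returned.
#' @export
validate_annotations <- function(annotations) {
  bad <- setdiff(unique(annotations$label), annotation_labels)
  check_that(length(bad) == 0,
             paste0("unknown label(s): ", paste(bad, collapse = ", ")),
             class = "icsrminer_validation_error")
  check_that(!any(duplicated(annotations$id)),
             "annotation ids must be labelled at most once",
             class = "icsrminer_validation_error")
  as_tibble(annotations)
}

#' Write gold annotations
#' @param annotations tibble with columns `id`, `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  readr::write_csv(annotations[, c("id", "label")], path, progress = FALSE)
  invisible(path)
}

# ---- packaged defaults -------------------------------------------------

#' Packaged default lexicons and hierarchy
#'
#' The package ships, under `extdata/`, the default rule dictionaries
#' (EIPPCS phrase dictionary, insulin product dictionaries for each text
#' mining method, anchor keyword variants, negation cues, exclusion
#' vocabulary), the two default HLGT filter names, the twelve default
#' preferred-term filter names, and a miniature synthetic MedDRA-like
#' hierarchy (`mock_meddra_hierarchy.tsv`; the licensed dictionary cannot
#' be redistributed).
#'
#' @return `default_lexicons()`: named list of `lexicon` objects with
#'   elements `anchor`, `positive`, `product_cpr`, `product_i2e`,
#'   `negation`, `exclusion`, `verbs`.
#' @export
default_lexicons <- function() {
  list(
    anchor = read_lexicon(pkg_extdata("lexicons", "anchor_syringe.txt"),
                          "anchor_syringe", role = "anchor"),
    positive = read_lexicon(pkg_extdata("lexicons", "eippcs_dictionary.txt"),
                            "eippcs_dictionary", role = "positive"),
    product_cpr = read_lexicon(pkg_extdata("lexicons", "products_cpr.txt"),
                               "products_cpr", role = "product"),
    product_i2e = read_lexicon(pkg_extdata("lexicons", "products_i2e.txt"),
                               "products_i2e", role = "product"),
    negation = read_lexicon(pkg_extdata("lexicons", "negation_cues.txt"),
                            "negation_cues", role = "negation"),
    exclusion = read_lexicon(pkg_extdata("lexicons", "exclusion_inhaled.txt"),
                             "exclusion_inhaled", role = "exclusion"),
    verbs = read_lexicon(pkg_extdata("lexicons", "action_verbs.txt"),
                         "action_verbs", role = "positive")
  )
}

#' @rdname default_lexicons
#' @return `default_hlgt_names()`: the two HLGT names used as the
#'   pre-annotation filter.
#' @export
default_hlgt_names <- function() {
  x <- readr::read_lines(pkg_extdata("lexicons", "hlgt_filter.txt"))
  x <- x[!stringr::str_starts(stringr::str_trim(x), "#")]
  x[nzchar(stringr::str_trim(x))]
}

#' @rdname default_lexicons
#' @return `default_pt_names()`: the twelve preferred-term names used as
#'   the second filter of the safety-surveillance method.
#' @export
default_pt_names <- function() {
  x <- readr::read_lines(pkg_extdata("lexicons", "pt_filter.txt"))
  x <- x[!stringr::str_starts(stringr::str_trim(x), "#")]
  x[nzchar(stringr::str_trim(x))]
}

#' @rdname default_lexicons
#' @return `mock_hierarchy()`: the packaged synthetic PT-to-HLGT table.
#' @export
mock_hierarchy <- function() {
  read_hierarchy(pkg_extdata("mock_meddra_hierarchy.tsv"))
}
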