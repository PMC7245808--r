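# MedDRA-level filtering: HLGT pre-filter used to build the annotation
# universe, the preferred-term second filter of the safety-surveillance
# method, and the random sampling step.  Term names are compared after
# case-folding and internal-whitespace collapsing; codes are bookkeeping.

#' Filter a corpus by high level group terms
#'
#' Keeps the records whose PT codes, collapsed to HLGT names via the
#' hierarchy, intersect the filter set.  The default filter is the two
#' device/medication-error HLGTs shipped with the package
#' ([default_hlgt_names()]).  Input order is preserved; the operation is
#' idempotent and monotone in the filter set.
#'
#' @param corpus a corpus tibble.
#' @param hierarchy hierarchy tibble from [read_hierarchy()].
#' @param hlgt_names character vector of HLGT names to keep (non-empty).
#' @param strict passed to [collapse_to_hlgt()]; if `TRUE` an unknown PT
#'   code raises instead of being skipped.
#' @return the filtered corpus tibble.
#' @export
hlgt_filter <- function(corpus, hierarchy, hlgt_names = default_hlgt_names(),
                        strict = FALSE) {
  check_that(length(hlgt_names) > 0, "hlgt_names must be non-empty")
  want <- norm_term(hlgt_names)
  keep <- purrr::map_lgl(corpus$pt_codes, function(codes) {
    h <- collapse_to_hlgt(codes, hierarchy, strict = strict)
    any(norm_term(h) %in% want)
  })
  corpus[keep, , drop = FALSE]
}

#' Filter a corpus by preferred-term names
#'
#' Keeps the records carrying at least one PT whose *name* (looked up from
#' the code via the hierarchy) matches the filter set case-insensitively.
#' The default set is the twelve terms of the safety-surveillance method's
#' second filter ([default_pt_names()]).
#'
#' @inheritParams hlgt_filter
#' @param pt_names character vector of PT names to keep (non-empty).
#' @return the filtered corpus tibble.
#' @export
pt_filter <- function(corpus, hierarchy, pt_names = default_pt_names(),
                      strict = FALSE) {
  check_that(length(pt_names) > 0, "pt_names must be non-empty")
  want <- norm_term(pt_names)
  keep <- purrr::map_lgl(corpus$pt_codes, function(codes) {
    idx <- match(as.character(codes), hierarchy$pt_code)
    if (anyNA(idx) && strict) {
      abort("unknown pt_code in record",
            class = "icsrminer_validation_error")
    }
    nm <- hierarchy$pt_name[idx[!is.na(idx)]]
    any(norm_term(nm) %in% want)
  })
  corpus[keep, , drop = FALSE]
}

#' Draw a simple random sample of records
#'
#' Samples `round_half_up(fraction * n)` records without replacement,
#' deterministically for a given seed (0.10 of 25,328 records gives 2533).
#' The global RNG state is untouched.
#'
#' @param corpus a corpus tibble.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return the sampled corpus tibble (row order randomised).
#' @export
sample_fraction <- function(corpus, fraction, seed = 1L) {
  check_that(is.numeric(fraction) && length(fraction) == 1 &&
               fraction > 0 && fraction <= 1,
             "fraction must be in (0, 1]",
             class = "icsrminer_validation_error")
  n <- nrow(corpus)
  size <- as.integer(round_half_up(fraction * n))
  idx <- withr::with_seed(seed, sample.int(n, size))
  corpus[idx, , drop = FALSE]
}
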