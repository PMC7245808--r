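# Internal helpers shared across modules.

#' Case-fold a string for matching
#'
#' All dictionary matching, preferred-term comparison and keyword search in
#' this package is case-insensitive; this is the single folding routine used
#' everywhere (Unicode NFKC then lower case), so that "Syringe", "SYRINGE"
#' and full-width variants compare equal.
#'
#' @param x character vector.
#' @return character vector, case-folded.
#' @keywords internal
fold_text <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_nfkc(x))
}

#' Normalise narrative text on ingest
#'
#' Applies Unicode NFKC normalisation and strips trademark glyphs
#' (\code{\U000AE}, \U2122) which occur in real safety narratives
#' ("NovoLog(R) FlexPen(R)") but never in rule dictionaries.  Case is
#' preserved; folding happens at match time.
#'
#' @param x character vector of raw text.
#' @return normalised character vector.
#' @export
#' @examples
#' normalize_narrative("NovoLog® FlexPen®")
normalize_narrative <- function(x) {
  x <- stringi::stri_trans_nfkc(x)
  x <- stringi::stri_replace_all_regex(x, "[®™]", "")
  x
}

# Normalise a MedDRA term name for comparison: case-fold and collapse
# internal whitespace.  Term names in narratives and fixtures vary in
# capitalisation; codes are carried for bookkeeping only.
norm_term <- function(x) {
  stringr::str_squish(fold_text(x))
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding: `round_half_up(2532.8) == 2533`,
#' `round_half_up(0.5) == 1`.  Used for sample sizes and planted positive
#' counts, where base R's round-half-to-even convention would disagree with
#' the conventional arithmetic.
#'
#' @param x numeric vector.
#' @return numeric vector of integers.
#' @export
#' @examples
#' round_half_up(0.1 * 25328)  # 2533
round_half_up <- function(x) {
  floor(x + 0.5)
}

# stopifnot-style validation with a readable message
check_that <- function(ok, msg, class = "icsrminer_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

# largest-remainder apportionment of `total` items over non-negative
# weights; deterministic (ties broken by position).  Returns integer counts
# summing to `total`.
apportion <- function(weights, total) {
  if (total == 0L) return(integer(length(weights)))
  w <- weights / sum(weights)
  raw <- w * total
  base <- floor(raw)
  rem <- raw - base
  short <- total - sum(base)
  if (short > 0) {
    idx <- order(-rem, seq_along(rem))[seq_len(short)]
    base[idx] <- base[idx] + 1L
  }
  as.integer(base)
}

# path to a packaged fixture under inst/extdata
pkg_extdata <- function(...) {
  system.file("extdata", ..., package = "icsrminer", mustWork = TRUE)
}
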