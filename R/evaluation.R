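# Evaluation protocol: confusion accounting against gold annotations,
# recall, precision under two conventions, Cohen's kappa, method-overlap
# analysis, preferred-term frequency profiling and false-positive-only
# n-gram term mining.

#' Confusion counts of a detector against gold annotations
#'
#' Standard 2x2 accounting restricted to an evaluation universe (the
#' annotated test set): `tp + fp + fn + tn == length(universe)`.
#'
#' @param result a `method_result`.
#' @param annotations tibble with columns `id`, `label`.
#' @param universe ids to evaluate over; default all annotated ids.  Every
#'   universe id must be annotated.
#' @return tibble with one row: `method`, `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(result, annotations, universe = annotations$id) {
  validate_annotations(annotations)
  missing <- setdiff(universe, annotations$id)
  check_that(length(missing) == 0,
             paste0("unannotated id(s) in universe: ",
                    paste(utils::head(missing, 5), collapse = ", ")),
             class = "icsrminer_validation_error")
  pos <- annotations$id[annotations$label == "EIPPCS"]
  ret <- intersect(retrieved_ids(result), universe)
  pos <- intersect(pos, universe)
  tibble(
    method = result$method,
    tp = length(intersect(ret, pos)),
    fp = length(setdiff(ret, pos)),
    fn = length(setdiff(pos, ret)),
    tn = length(universe) - length(union(ret, pos))
  )
}

#' Recall (sensitivity)
#'
#' Proportion of gold EIPPCS cases in the test set that the method
#' retrieved: `tp / (tp + fn)`.
#'
#' @param counts a confusion tibble from [confusion()], or `tp` as a
#'   number when `fn` is given.
#' @param fn optional false-negative count when `counts` is numeric.
#' @return a proportion in `[0, 1]`.
#' @export
#' @examples
#' recall(38, 4)   # 38 of 42 gold cases found
recall <- function(counts, fn = NULL) {
  if (is.numeric(counts) && !is.null(fn)) {
    tp <- counts
  } else {
    tp <- counts$tp
    fn <- counts$fn
  }
  check_that(tp + fn > 0, "recall undefined: no gold positives",
             class = "icsrminer_undefined_metric")
  tp / (tp + fn)
}

#' Precision, test-set convention (positive predictive value)
#'
#' `tp / (tp + fp)` within the annotated universe -- the textbook PPV.
#'
#' @param counts confusion tibble from [confusion()].
#' @return a proportion in `[0, 1]`.
#' @export
precision_testset <- function(counts) {
  check_that(counts$tp + counts$fp > 0,
             "precision undefined: nothing retrieved in universe",
             class = "icsrminer_undefined_metric")
  counts$tp / (counts$tp + counts$fp)
}

#' Precision, full-retrieval convention
#'
#' Confirmed test-set true positives divided by the method's *total*
#' retrieval from the full corpus (not just the annotated subset).  This is
#' the convention behind headline figures like 37/1104 = 3.4%: the
#' annotated sample contributes the numerator while the denominator counts
#' everything the method pulled from the whole database.  Reported side by
#' side with [precision_testset()]; the two differ whenever the universe is
#' a sample of the corpus.
#'
#' @param tp confirmed true-positive count.
#' @param retrieved_total total records retrieved from the full corpus
#'   (must be positive).
#' @return a proportion in `[0, 1]`.
#' @export
#' @examples
#' precision_paper(37, 1104)
precision_paper <- function(tp, retrieved_total) {
  check_that(retrieved_total > 0,
             "precision undefined: nothing retrieved",
             class = "icsrminer_undefined_metric")
  check_that(tp <= retrieved_total, "tp cannot exceed retrieved_total")
  tp / retrieved_total
}

#' Cohen's kappa for two binary annotators
#'
#' Chance-corrected agreement over an identical id set:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the marginal label frequencies.  When both
#' raters are constant and identical (`p_e == 1`, `p_o == 1`) the
#' coefficient is 1 by convention.
#'
#' @param labels_a,labels_b annotation tibbles (`id`, `label`) over the
#'   same id set.
#' @return a coefficient in `[-1, 1]`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  validate_annotations(labels_a)
  validate_annotations(labels_b)
  check_that(setequal(labels_a$id, labels_b$id) &&
               nrow(labels_a) == nrow(labels_b) && nrow(labels_a) > 0,
             "annotators must label the same non-empty id set",
             class = "icsrminer_validation_error")
  b <- labels_b$label[match(labels_a$id, labels_b$id)]
  a <- labels_a$label
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- sum(purrr::map_dbl(annotation_labels,
                            ~ mean(a == .x) * mean(b == .x)))
  if (p_e == 1) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Printed-percentage rendering
#'
#' Renders a proportion as a one-decimal percentage under either
#' convention seen in published tables: `"round"` (half-up at the first
#' decimal, 0.880952 -> 88.1) or `"truncate"` (drop beyond the first
#' decimal, 0.904762 -> 90.4).
#'
#' @param p proportion in `[0, 1]`.
#' @param rule `"round"` or `"truncate"`.
#' @return a numeric percentage with one decimal.
#' @export
format_percent <- function(p, rule = c("round", "truncate")) {
  rule <- match.arg(rule)
  v <- p * 100
  if (rule == "round") round_half_up(v * 10) / 10 else floor(v * 10) / 10
}

#' Method-overlap analysis of captured true positives
#'
#' For each non-empty subset of methods, counts the gold-positive records
#' retrieved by exactly that subset of methods; gold positives retrieved by
#' no method land in the `"none"` bucket.  All counts sum to the number of
#' gold positives.
#'
#' @param results list of two or more `method_result` objects.
#' @param positives character vector of gold-positive ids.
#' @return tibble of class `"overlap_counts"` with columns `methods`
#'   (subset signature such as `"CPR&SSA"`, or `"none"`) and `n`, covering
#'   every subset (zeros included).
#' @export
overlap_analysis <- function(results, positives) {
  check_that(length(results) >= 2, "need at least two method results")
  nm <- purrr::map_chr(results, "method")
  check_that(!any(duplicated(nm)), "method names must be distinct")
  hit <- purrr::map(results, ~ positives %in% retrieved_ids(.x))
  sig <- purrr::map_chr(seq_along(positives), function(i) {
    on <- nm[purrr::map_lgl(hit, ~ .x[i])]
    if (length(on) == 0) "none" else paste(sort(on), collapse = "&")
  })
  # all 2^k - 1 non-empty subsets, plus "none"
  all_subsets <- purrr::map(seq_along(nm), ~ utils::combn(sort(nm), .x,
                                                          simplify = FALSE))
  all_sigs <- c(purrr::map_chr(purrr::flatten(all_subsets), paste,
                               collapse = "&"), "none")
  out <- tibble(methods = all_sigs) |>
    left_join(tibble(methods = sig) |> count(.data$methods),
              by = "methods") |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
  structure(out, n_positives = length(positives),
            class = c("overlap_counts", class(out)))
}

#' Preferred-term capture frequency
#'
#' For a set of retrieved record ids (e.g. the true-positive or
#' false-positive pool of a method), tabulates which of the filter PTs
#' captured each record: a record carrying exactly one of the filter PTs
#' counts under that PT; a record carrying more than one counts once under
#' `"Composite PTs"`; PTs individually capturing fewer than
#' `group_threshold` records are merged into a `"PTs < N"` bucket.  Counts
#' sum to the number of ids carrying at least one filter PT.
#'
#' @param ids record ids to profile.
#' @param corpus the corpus tibble.
#' @param hierarchy hierarchy tibble.
#' @param pt_names the filter PT names (default: the packaged twelve).
#' @param group_threshold minimum per-PT count to stay listed (default 10).
#' @return tibble of class `"pt_frequency"` with columns `pt`, `n`.
#' @export
pt_frequency <- function(ids, corpus, hierarchy,
                         pt_names = default_pt_names(),
                         group_threshold = 10L) {
  want <- norm_term(pt_names)
  canon <- setNames(pt_names, want)
  sub <- corpus[corpus$id %in% ids, ]
  per_record <- purrr::map_chr(sub$pt_codes, function(codes) {
    idx <- match(as.character(codes), hierarchy$pt_code)
    nm <- unique(norm_term(hierarchy$pt_name[idx[!is.na(idx)]]))
    nm <- nm[nm %in% want]
    if (length(nm) == 0) NA_character_
    else if (length(nm) > 1) "Composite PTs"
    else canon[[nm]]
  })
  per_record <- per_record[!is.na(per_record)]
  counts <- tibble(pt = per_record) |> count(.data$pt, sort = TRUE)
  small <- counts$pt != "Composite PTs" & counts$n < group_threshold
  if (any(small)) {
    bucket <- tibble(pt = sprintf("PTs < %d", group_threshold),
                     n = sum(counts$n[small]))
    counts <- bind_rows(counts[!small, ], bucket)
  }
  structure(arrange(counts, desc(.data$n)),
            class = c("pt_frequency", class(counts)))
}

# fold a character vector of texts into a pooled n-gram count table
.ngram_counts <- function(texts, max_n) {
  grams <- purrr::map(texts, function(tx) {
    w <- tokenize_words(tx)
    if (length(w) == 0) return(character())
    unlist(purrr::map(seq_len(min(max_n, length(w))), function(k) {
      if (length(w) < k) return(character())
      m <- stats::embed(w, k)[, k:1, drop = FALSE]
      apply(m, 1, paste, collapse = " ")
    }))
  })
  tibble(term = unlist(grams)) |> count(.data$term, name = "n")
}

#' Terms found only in the false-positive pool
#'
#' Differential n-gram mining between a method's false-positive and
#' true-positive narrative pools: every word n-gram (1..`max_n` words,
#' case-folded, stop words kept) occurring in the FP pool but never in the
#' TP pool, ranked by descending FP-pool occurrence count (ties broken
#' lexicographically) and truncated to `top_k`.  These terms are candidate
#' future negative filters: removing records containing them cannot cost a
#' true positive in the evaluated set.
#'
#' @param fp_texts,tp_texts character vectors of retained narrative text
#'   (one element per record) for the FP and TP pools.
#' @param max_n maximum n-gram length in words (default 5).
#' @param top_k how many terms to return (default 25).
#' @return tibble with columns `term`, `n` (FP-pool occurrence count).
#' @export
fp_only_terms <- function(fp_texts, tp_texts, max_n = 5L, top_k = 25L) {
  fp <- .ngram_counts(fp_texts, max_n)
  tp <- .ngram_counts(tp_texts, max_n)
  out <- fp |>
    anti_join(tp, by = "term") |>
    arrange(desc(.data$n), .data$term)
  utils::head(out, top_k)
}

#' Side-by-side FP-only term table for several methods
#'
#' Joins the [fp_only_terms()] lists of several methods into one table,
#' with `NA` where a term was not in that method's FP-only list.  Rows are
#' sorted on the first method's counts where present, otherwise on the
#' later methods' -- mirroring the usual presentation of such comparative
#' term tables.
#'
#' @param term_lists named list of [fp_only_terms()] tibbles.
#' @return tibble with column `term` and one count column per method.
#' @export
compare_fp_terms <- function(term_lists) {
  tabs <- purrr::imap(term_lists, function(t, nm) {
    names(t)[names(t) == "n"] <- nm
    t
  })
  out <- purrr::reduce(tabs, dplyr::full_join, by = "term")
  ord <- do.call(order, c(purrr::map(names(term_lists),
                                     ~ -dplyr::coalesce(out[[.x]], -Inf)),
                          list(out$term)))
  out[ord, ]
}

#' Full metrics report for one or more detectors
#'
#' Computes, per method: confusion counts over the annotated universe,
#' recall, test-set precision, total retrieval from the full corpus and
#' full-retrieval precision, plus both one-decimal printed renderings of
#' each proportion.
#'
#' @param results list of `method_result` objects.
#' @param annotations gold annotation tibble.
#' @param universe evaluation universe (default: all annotated ids).
#' @return tibble of class `"metrics_report"`, one row per method.
#' @export
metrics_report <- function(results, annotations,
                           universe = annotations$id) {
  rows <- purrr::map(results, function(res) {
    cc <- confusion(res, annotations, universe)
    rt <- length(retrieved_ids(res))
    rec <- recall(cc)
    prec_t <- if (cc$tp + cc$fp > 0) precision_testset(cc) else NA_real_
    prec_p <- if (rt > 0) precision_paper(cc$tp, rt) else NA_real_
    mutate(cc,
           retrieved_total = rt,
           recall = rec,
           precision_testset = prec_t,
           precision_paper = prec_p,
           recall_pct_round = format_percent(rec, "round"),
           recall_pct_trunc = format_percent(rec, "truncate"),
           precision_paper_pct_round =
             if (is.na(prec_p)) NA_real_ else format_percent(prec_p, "round"))
  })
  out <- bind_rows(rows)
  structure(out, class = c("metrics_report", class(out)))
}

#' Summary of a metrics report
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return tibble with one row per method: `method`, `recall`,
#'   `precision_testset`, `precision_paper`, `retrieved_total`.
#' @export
glance.metrics_report <- function(x, ...) {
  select(as_tibble(x), "method", "recall", "precision_testset",
         "precision_paper", "retrieved_total")
}

# ---- plots -------------------------------------------------------------

#' Plot method-overlap counts
#'
#' Bar chart of true-positive counts per exact method subset -- a linear
#' rendering of the usual Venn diagram.
#'
#' @param object an `overlap_counts` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.overlap_counts <- function(object, ...) {
  d <- as_tibble(object)
  d$methods <- factor(d$methods, levels = d$methods)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$methods, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = "captured by exactly", y = "gold positives",
                  title = "True positives by method subset") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a preferred-term frequency profile
#'
#' @param object a `pt_frequency` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pt_frequency <- function(object, ...) {
  d <- as_tibble(object)
  d$pt <- factor(d$pt, levels = rev(d$pt))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$pt)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "records captured", y = NULL,
                  title = "Capture frequency by preferred term") +
    ggplot2::theme_minimal()
}

#' Plot recall and precision per method
#'
#' @param object a `metrics_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.metrics_report <- function(object, ...) {
  d <- as_tibble(object) |>
    select("method", "recall", "precision_testset", "precision_paper") |>
    tidyr::pivot_longer(-"method", names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$value,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "proportion",
                  title = "Detector performance") +
    ggplot2::theme_minimal()
}
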