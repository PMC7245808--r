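# End-to-end orchestration: HLGT pre-filter -> optional random sample ->
# detectors -> evaluation, with per-stage record-count bookkeeping in the
# style of a signal-detection workflow log (full corpus -> filtered ->
# annotated sample).

#' Run the full signal-detection workflow
#'
#' Applies the HLGT pre-filter to the corpus, optionally draws a random
#' sample of the filtered set as the evaluation universe, runs the chosen
#' detectors on the *full* corpus (retrieval totals are corpus-wide, as in
#' routine surveillance), and, when annotations are supplied, evaluates
#' each detector against the universe and runs the post-hoc analyses
#' (overlap, PT frequency, FP-only term mining).
#'
#' @param corpus a corpus tibble.
#' @param hierarchy hierarchy tibble.
#' @param annotations optional gold annotations (`id`, `label`).
#' @param methods subset of `c("ssa", "cpr", "i2e")`.
#' @param hlgt_names HLGT pre-filter set (default: packaged pair).
#' @param pt_names PT filter set for the surveillance method and the PT
#'   frequency profile.
#' @param fraction optional sampling fraction in (0, 1]; `NULL` or 1 uses
#'   the whole filtered set as universe.
#' @param seed seed for the sampling stage.
#' @param max_gap proximity window of the tagging method.
#' @param lexicons named lexicon list (default [default_lexicons()]).
#' @param out_dir optional directory; when given, artifacts are written
#'   there (method results and metrics as CSV, traces as JSONL, stage
#'   counts as CSV).
#' @return list with elements `stage_counts` (tibble `stage`, `n_in`,
#'   `n_out`), `results` (named list of `method_result`), `universe`
#'   (character ids), and when annotations were given `metrics`
#'   (`metrics_report`), `overlap` (`overlap_counts`), `pt_freq_tp`,
#'   `pt_freq_fp` (`pt_frequency`) and `fp_terms` (named list of
#'   [fp_only_terms()] tibbles).
#' @export
run_pipeline <- function(corpus, hierarchy, annotations = NULL,
                         methods = c("ssa", "cpr", "i2e"),
                         hlgt_names = default_hlgt_names(),
                         pt_names = default_pt_names(),
                         fraction = NULL, seed = 1L, max_gap = 8L,
                         lexicons = default_lexicons(), out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  validate_corpus(corpus)
  stage <- list()

  filtered <- hlgt_filter(corpus, hierarchy, hlgt_names)
  stage$hlgt_filter <- c(nrow(corpus), nrow(filtered))

  universe_corpus <- filtered
  if (!is.null(fraction) && fraction < 1) {
    universe_corpus <- sample_fraction(filtered, fraction, seed = seed)
  }
  stage$sample <- c(nrow(filtered), nrow(universe_corpus))
  universe <- universe_corpus$id

  results <- list()
  if ("ssa" %in% methods) {
    results$SSA <- run_ssa(corpus, hierarchy, pt_names)
  }
  if ("cpr" %in% methods) {
    results$CPR <- run_cpr(corpus, lexicons, max_gap = max_gap)
  }
  if ("i2e" %in% methods) {
    results$I2E <- run_i2e(corpus, default_i2e_ruleset(lexicons))
  }
  for (nm in names(results)) {
    stage[[paste0("detect_", nm)]] <- c(nrow(corpus),
                                        length(retrieved_ids(results[[nm]])))
  }
  stage_names <- names(stage)
  stage_in <- purrr::map_int(stage, ~ as.integer(.x[1]))
  stage_out <- purrr::map_int(stage, ~ as.integer(.x[2]))
  stage_counts <- tibble(stage = stage_names, n_in = unname(stage_in),
                         n_out = unname(stage_out))

  out <- list(stage_counts = stage_counts, results = results,
              universe = universe)

  if (!is.null(annotations)) {
    annotations <- validate_annotations(annotations)
    universe <- intersect(universe, annotations$id)
    out$universe <- universe
    out$metrics <- metrics_report(results, annotations, universe)
    positives <- intersect(annotations$id[annotations$label == "EIPPCS"],
                           universe)
    if (length(results) >= 2) {
      out$overlap <- overlap_analysis(results, positives)
    }
    if ("SSA" %in% names(results)) {
      ret <- intersect(retrieved_ids(results$SSA), universe)
      out$pt_freq_tp <- pt_frequency(intersect(ret, positives), corpus,
                                     hierarchy, pt_names)
      out$pt_freq_fp <- pt_frequency(setdiff(ret, positives), corpus,
                                     hierarchy, pt_names)
    }
    texts <- retained_text(corpus, exclude_sections = "analysis")
    out$fp_terms <- purrr::map(results[intersect(c("I2E", "CPR"),
                                                 names(results))],
                               function(res) {
      ret <- intersect(retrieved_ids(res), universe)
      fp_only_terms(texts[setdiff(ret, positives)],
                    texts[intersect(ret, positives)])
    })
  }

  if (!is.null(out_dir)) write_artifacts(out, out_dir)
  out
}

#' Write pipeline artifacts to a directory
#'
#' Per method: `result_<METHOD>.csv` (id, retrieved, last rule, decision)
#' and `trace_<METHOD>.jsonl`; plus `stage_counts.csv`, and when present
#' `metrics.csv`, `overlap.csv` and `fp_terms_<METHOD>.tsv`.
#'
#' @param pipeline result of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_artifacts <- function(pipeline, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(pipeline$stage_counts,
                   file.path(out_dir, "stage_counts.csv"), progress = FALSE)
  for (nm in names(pipeline$results)) {
    res <- pipeline$results[[nm]]
    last <- tidy(res) |>
      group_by(.data$id) |>
      slice(dplyr::n()) |>
      ungroup() |>
      mutate(retrieved = .data$id %in% retrieved_ids(res)) |>
      select("id", "retrieved", last_rule = "rule_id", "decision")
    readr::write_csv(last, file.path(out_dir,
                                     paste0("result_", nm, ".csv")),
                     progress = FALSE)
    traces <- tidy(res) |>
      tidyr::nest(steps = c("step", "rule_id", "decision"))
    lines <- purrr::map2_chr(traces$id, traces$steps, function(id, st) {
      jsonlite::toJSON(list(id = jsonlite::unbox(id),
                            steps = st), auto_unbox = FALSE)
    })
    readr::write_lines(lines, file.path(out_dir,
                                        paste0("trace_", nm, ".jsonl")))
  }
  if (!is.null(pipeline$metrics)) {
    readr::write_csv(as_tibble(pipeline$metrics),
                     file.path(out_dir, "metrics.csv"), progress = FALSE)
  }
  if (!is.null(pipeline$overlap)) {
    readr::write_csv(as_tibble(pipeline$overlap),
                     file.path(out_dir, "overlap.csv"), progress = FALSE)
  }
  for (nm in names(pipeline$fp_terms)) {
    readr::write_tsv(pipeline$fp_terms[[nm]],
                     file.path(out_dir, paste0("fp_terms_", nm, ".tsv")),
                     progress = FALSE)
  }
  invisible(out_dir)
}
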