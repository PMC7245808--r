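fake_result <- function(ids, method = "X", n = 100) {
  structure(list(method = method, retrieved = ids,
                 trace = tibble::tibble(id = ids, step = 1L,
                                        rule_id = "r", decision = "include"),
                 n_corpus = n),
            class = "method_result")
}

test_that("confusion counts partition the universe", {
  ann <- tibble::tibble(id = paste0("R", 1:6),
                        label = c("EIPPCS", "EIPPCS", "EIPPCS",
                                  "non_EIPPCS", "non_EIPPCS", "non_EIPPCS"))
  # hand fixture: retrieved = {R1, R2, R4}; by set arithmetic
  # tp = 2, fp = 1, fn = 1, tn = 2
  cc <- confusion(fake_result(c("R1", "R2", "R4")), ann)
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]),
               c(tp = 2, fp = 1, fn = 1, tn = 2))
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 6)

  perfect <- confusion(fake_result(c("R1", "R2", "R3")), ann)
  expect_equal(perfect$fp, 0)
  expect_equal(perfect$fn, 0)

  none <- confusion(fake_result(character()), ann)
  expect_equal(none$tp, 0)
  expect_equal(none$fn, 3)

  expect_error(confusion(fake_result("R1"), ann, universe = c("R1", "Z9")),
               class = "icsrminer_validation_error")
})

test_that("recall and both precision conventions reproduce worked examples", {
  expect_equal(recall(38, 4), 38 / 42)
  expect_equal(recall(37, 5), 37 / 42)
  expect_equal(recall(0, 5), 0)
  expect_error(recall(0, 0), class = "icsrminer_undefined_metric")

  expect_equal(precision_paper(37, 1104), 37 / 1104)
  expect_equal(precision_paper(38, 2042), 38 / 2042)
  expect_equal(precision_paper(5, 5), 1)
  expect_error(precision_paper(1, 0), class = "icsrminer_undefined_metric")

  cc <- tibble::tibble(tp = 3, fp = 1, fn = 1, tn = 5)
  expect_equal(precision_testset(cc), 0.75)
})

test_that("percentage rendering distinguishes rounding from truncation", {
  expect_equal(format_percent(38 / 42, "truncate"), 90.4)
  expect_equal(format_percent(38 / 42, "round"), 90.5)
  expect_equal(format_percent(37 / 42, "round"), 88.1)
  expect_equal(format_percent(33 / 42, "truncate"), 78.5)
  expect_equal(format_percent(37 / 1104, "round"), 3.4)
})

test_that("Cohen's kappa matches the closed form", {
  ids <- paste0("R", 1:100)
  lab <- function(x) tibble::tibble(id = ids, label = x)
  both <- rep(c("EIPPCS", "non_EIPPCS"), c(42, 58))
  expect_equal(cohens_kappa(lab(both), lab(both)), 1)

  # asymmetric 2x2 table a=40, b=2, c=2, d=56, evaluated independently:
  # p_o = 0.96, p_e = (42*42 + 58*58)/10000
  a_lab <- rep(c("EIPPCS", "non_EIPPCS"), c(42, 58))
  b_lab <- c(rep("EIPPCS", 40), rep("non_EIPPCS", 2),
             rep("EIPPCS", 2), rep("non_EIPPCS", 56))
  p_e <- (42 * 42 + 58 * 58) / 1e4
  expect_equal(cohens_kappa(lab(a_lab), lab(b_lab)),
               (0.96 - p_e) / (1 - p_e))

  # agreement exactly at chance level: kappa = 0
  a2 <- rep(c("EIPPCS", "non_EIPPCS"), each = 2)
  b2 <- c("EIPPCS", "non_EIPPCS", "EIPPCS", "non_EIPPCS")
  la <- tibble::tibble(id = paste0("R", 1:4), label = a2)
  lb <- tibble::tibble(id = paste0("R", 1:4), label = b2)
  expect_equal(cohens_kappa(la, lb), 0)

  # id-set mismatch is a validation error
  expect_error(cohens_kappa(la, lb[1:3, ]),
               class = "icsrminer_validation_error")
  # order of rows is irrelevant
  expect_equal(cohens_kappa(la, lb[c(3, 1, 4, 2), ]), 0)
})

test_that("overlap analysis enumerates method subsets exhaustively", {
  r1 <- fake_result("P1", "A")
  r2 <- fake_result("P1", "B")
  r3 <- fake_result("P1", "C")
  ov <- overlap_analysis(list(r1, r2, r3), positives = "P1")
  expect_equal(ov$n[ov$methods == "A&B&C"], 1)
  expect_equal(sum(ov$n), 1)
  expect_equal(nrow(ov), 8)  # 2^3 - 1 subsets + none

  ov2 <- overlap_analysis(list(r1, r2), positives = c("P1", "P9"))
  expect_equal(ov2$n[ov2$methods == "none"], 1)
  expect_equal(sum(ov2$n), 2)

  # random fixture vs brute-force subset enumeration
  set.seed(33)
  ids <- paste0("P", 1:20)
  res <- list(fake_result(sample(ids, 8), "A"),
              fake_result(sample(ids, 8), "B"),
              fake_result(sample(ids, 8), "C"))
  ov3 <- overlap_analysis(res, ids)
  brute <- table(vapply(ids, function(i) {
    on <- sort(c("A", "B", "C")[vapply(res, function(r)
      i %in% r$retrieved, TRUE)])
    if (length(on) == 0) "none" else paste(on, collapse = "&")
  }, ""))
  for (k in names(brute)) {
    expect_equal(ov3$n[ov3$methods == k], unname(as.integer(brute[k])))
  }
  expect_equal(sum(ov3$n), 20)
})

test_that("PT frequency groups composites and rare terms", {
  h <- mock_hierarchy()
  code <- function(nm) h$pt_code[match(nm, h$pt_name)]
  pts <- c(rep("Wrong technique in product usage process", 12),
           rep("Device malfunction", 11), rep("Device failure", 3))
  corpus <- mini_corpus(rep("t", length(pts)),
                        pt_codes = as.list(code(pts)))
  # two extra records coded with two filter PTs each -> Composite PTs
  extra <- icsr_corpus(
    id = c("X1", "X2"),
    sections = list(one_section("t"), one_section("t")),
    pt_codes = list(code(c("Device failure", "Device malfunction")),
                    code(c("Wrong device used", "Product use issue"))))
  corpus <- dplyr::bind_rows(corpus, extra)
  freq <- pt_frequency(corpus$id, corpus, h, group_threshold = 10)
  expect_equal(freq$n[freq$pt == "Wrong technique in product usage process"],
               12)
  expect_equal(freq$n[freq$pt == "Device malfunction"], 11)
  expect_equal(freq$n[freq$pt == "PTs < 10"], 3)
  expect_equal(freq$n[freq$pt == "Composite PTs"], 2)
  # 12 + 11 + 3 singles plus 2 composites = 28 records with >= 1 filter PT
  expect_equal(sum(freq$n), 28)

  # plain histogram when every record carries exactly one filter PT
  freq1 <- pt_frequency(paste0("R", 1:12), corpus, h, group_threshold = 1)
  expect_equal(nrow(freq1), 1)
})

test_that("FP-only term mining returns n-grams absent from the TP pool", {
  expect_equal(nrow(fp_only_terms("a b c", "a b c")), 0)

  out <- fp_only_terms("prefilled insulin syringes used daily",
                       "insulin used daily")
  expect_true(all(c("prefilled", "prefilled insulin",
                    "prefilled insulin syringes", "syringes") %in%
                    out$term))
  expect_false("insulin" %in% out$term)
  expect_false("used daily" %in% out$term)

  # every returned term has zero TP-pool occurrences (direct assertion)
  fp_pool <- c("the woman was introduced to prefilled pens",
               "elevated blood glucose changes observed")
  tp_pool <- c("patient withdrew insulin with a syringe")
  out2 <- fp_only_terms(fp_pool, tp_pool, top_k = 100)
  tp_grams <- icsrminer:::.ngram_counts(tp_pool, 5)$term
  expect_false(any(out2$term %in% tp_grams))

  top1 <- fp_only_terms(c("prefilled prefilled prefilled", "prefilled"),
                        "syringe", top_k = 1)
  expect_equal(top1$term, "prefilled")
  expect_equal(top1$n, 4)
})

test_that("FP-term comparison aligns methods with NA for absent terms", {
  a <- tibble::tibble(term = c("prefilled", "woman"), n = c(10L, 5L))
  b <- tibble::tibble(term = c("woman", "vial"), n = c(7L, 3L))
  cmp <- compare_fp_terms(list(I2E = a, CPR = b))
  expect_equal(names(cmp), c("term", "I2E", "CPR"))
  expect_true(is.na(cmp$CPR[cmp$term == "prefilled"]))
  expect_equal(cmp$term[1], "prefilled")  # sorted on first method first
  expect_equal(cmp$CPR[cmp$term == "woman"], 7)
})

test_that("metrics report combines both precision conventions", {
  ann <- tibble::tibble(id = paste0("R", 1:10),
                        label = rep(c("EIPPCS", "non_EIPPCS"), c(4, 6)))
  res <- fake_result(c("R1", "R2", "R5", "Z1", "Z2"), "M")
  m <- metrics_report(list(res), ann)
  expect_equal(m$tp, 2)
  expect_equal(m$recall, 0.5)
  expect_equal(m$precision_testset, 2 / 3)   # universe: R1, R2, R5
  expect_equal(m$precision_paper, 2 / 5)     # all five retrieved corpus-wide
  expect_s3_class(autoplot(m), "ggplot")
})
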