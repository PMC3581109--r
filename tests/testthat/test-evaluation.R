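test_that("the F-score is the harmonic mean with defined limits", {
  expect_equal(round(f_score(1, 0.7867), 3), 0.881)
  expect_equal(round(f_score(0.968, 0.822), 3), 0.889)
  expect_equal(f_score(0.93, 0.869), 0.899, tolerance = 0.001)
  expect_equal(f_score(0.5, 0.5), 0.5)
  expect_equal(f_score(0.3, 0.3), 0.3)
  expect_equal(f_score(0, 0), 0)
  expect_error(f_score(1.2, 0.5), "0, 1")
  expect_error(f_score(0.5, -0.1), "0, 1")
  # bounded by its inputs
  set.seed(2)
  p <- runif(200); s <- runif(200)
  f <- f_score(p, s)
  expect_true(all(f >= pmin(p, s) - 1e-12 & f <= pmax(p, s) + 1e-12))
})

test_that("age detection scoring counts TP/FP/FN and perfect ranges", {
  gold <- data.frame(pmid = letters[1:10], is_age_related = TRUE,
                     low_years = 1:10, high_years = 11:20)
  pred <- data.frame(pmid = letters[1:10],
                     age_related = c(rep(TRUE, 8), FALSE, FALSE),
                     low_years = c(1:7, 99, NA, NA),
                     high_years = c(11:17, 99, NA, NA))
  r <- evaluate_age_detection(pred, gold)
  expect_equal(r$sensitivity, 0.8)
  expect_equal(r$precision, 1)
  expect_equal(r$perfect_range_fraction, 7 / 8)
  expect_equal(r$f_score, f_score(1, 0.8))
  all_right <- evaluate_age_detection(
    data.frame(pmid = gold$pmid, age_related = TRUE,
               low_years = gold$low_years, high_years = gold$high_years),
    gold)
  expect_equal(unlist(all_right[c("precision", "sensitivity", "f_score",
                                  "perfect_range_fraction")]),
               c(precision = 1, sensitivity = 1, f_score = 1,
                 perfect_range_fraction = 1))
  expect_warning(
    none <- evaluate_age_detection(
      data.frame(pmid = gold$pmid, age_related = FALSE,
                 low_years = NA_real_, high_years = NA_real_), gold),
    "precision")
  expect_equal(none$precision, 0)
  expect_error(evaluate_age_detection(pred[1:5, ], gold), "PMID")
})

test_that("relationship scoring reports the three fractions", {
  gold <- data.frame(pmid = as.character(1:10),
                     gold_relationship = rep("AGE_OF_ONSET", 10))
  pred <- data.frame(pmid = as.character(1:10),
                     relationship = c(rep("AGE_OF_ONSET", 6),
                                      rep("UNDETERMINED", 3),
                                      "AGE_OF_DIAGNOSIS"))
  r <- evaluate_relationship(pred, gold)
  expect_equal(r$correct, 0.6)
  expect_equal(r$undetermined, 0.3)
  expect_equal(r$incorrect_of_assigned, 1 / 7)
  all_und <- evaluate_relationship(
    data.frame(pmid = gold$pmid, relationship = "UNDETERMINED"), gold)
  expect_equal(all_und$correct, 0)
  expect_equal(all_und$undetermined, 1)
  expect_true(is.na(all_und$incorrect_of_assigned))
  all_ok <- evaluate_relationship(
    data.frame(pmid = gold$pmid, relationship = "AGE_OF_ONSET"), gold)
  expect_equal(unlist(all_ok[c("correct", "undetermined",
                               "incorrect_of_assigned")]),
               c(correct = 1, undetermined = 0, incorrect_of_assigned = 0))
})

test_that("mapping scoring handles the two harmless modes", {
  gold <- data.frame(instance_id = c("i1", "i1"),
                     term_id = c("DOID:1", "DOID:2"),
                     is_harmless = c(FALSE, TRUE))
  pred <- data.frame(instance_id = c("i1", "i1"),
                     term_id = c("DOID:1", "DOID:2"))
  excl <- evaluate_mapping(pred, gold, "HARMLESS_EXCLUDED")
  asfp <- evaluate_mapping(pred, gold, "HARMLESS_AS_FP")
  expect_equal(excl$precision, 1)
  expect_equal(asfp$precision, 0.5)
  expect_equal(excl$sensitivity, asfp$sensitivity)

  perfect <- data.frame(instance_id = "i1", term_id = "DOID:1")
  gold1 <- data.frame(instance_id = "i1", term_id = "DOID:1",
                      is_harmless = FALSE)
  for (mode in c("HARMLESS_EXCLUDED", "HARMLESS_AS_FP")) {
    r <- evaluate_mapping(perfect, gold1, mode)
    expect_equal(unlist(r[c("precision", "sensitivity", "f_score")]),
                 c(precision = 1, sensitivity = 1, f_score = 1))
  }
  expect_warning(
    miss <- evaluate_mapping(perfect[0, ],
                             data.frame(instance_id = c("i1", "i1"),
                                        term_id = c("DOID:1", "DOID:3"),
                                        is_harmless = FALSE)),
    "precision")
  expect_equal(miss$sensitivity, 0)
})

test_that("snippet-quality judgements summarise into fractions", {
  j <- data.frame(instance_id = as.character(1:10),
                  gold_snippet_quality = c(rep("COMPLETE", 8),
                                           "MISSING_INFO", "ERRONEOUS"))
  r <- evaluate_snippet(j)
  expect_equal(r$complete, 0.8)
  expect_equal(r$missing_info, 0.1)
  expect_equal(r$erroneous, 0.1)
  expect_equal(r$complete + r$missing_info + r$erroneous, 1)
  j$gold_snippet_quality[1] <- "GREAT"
  expect_error(evaluate_snippet(j), "GREAT")
})

test_that("gold phenotypes absent from the lexicons are excluded as TN", {
  gold <- data.frame(instance_id = "i1",
                     term_id = c("DOID:1", "DOID:9"),
                     is_harmless = FALSE,
                     in_lexicon = c(TRUE, FALSE))
  pred <- data.frame(instance_id = "i1", term_id = "DOID:1")
  r <- evaluate_mapping(pred, gold)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$fn, 0L)
})

test_that("harmless-excluded precision always dominates harmless-as-FP", {
  set.seed(7)
  terms <- paste0("DOID:", 1:12)
  for (rep in 1:50) {
    ids <- sample(c("a", "b", "c"), 6, replace = TRUE)
    gold <- do.call(rbind, lapply(unique(ids), function(id) {
      k <- sample(1:4, 1)
      data.frame(instance_id = id, term_id = sample(terms, k),
                 is_harmless = sample(c(TRUE, FALSE), k, replace = TRUE))
    }))
    pred <- do.call(rbind, lapply(unique(ids), function(id) {
      k <- sample(0:5, 1)
      if (k == 0) return(NULL)
      data.frame(instance_id = id, term_id = sample(terms, k))
    }))
    if (is.null(pred)) next
    a <- suppressWarnings(evaluate_mapping(pred, gold, "HARMLESS_EXCLUDED"))
    b <- suppressWarnings(evaluate_mapping(pred, gold, "HARMLESS_AS_FP"))
    expect_gte(a$precision, b$precision)
    expect_equal(a$sensitivity, b$sensitivity)
  }
})
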