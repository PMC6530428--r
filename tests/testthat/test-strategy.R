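test_that("strategy predictions reproduce the documented wrong answers", {
  q_nanb_p <- inference_query("P(notA|notB)", "probability")
  expect_equal(100 * predict_answer("fisherian", mam, q_nanb_p)$value, 90.4)
  expect_equal(100 * predict_answer("joint_occurrence", eco, q_nanb_p)$value, 45)
  fr <- predict_answer("joint_occurrence", mam,
                       inference_query("P(notA|B)", "natural_frequency"))
  expect_equal(c(fr$numerator, fr$denominator), c(950, 10000))
  q_ab_p <- inference_query("P(A|B)", "probability")
  expect_equal(100 * predict_answer("likelihood_subtraction", mam, q_ab_p)$value,
               70.4, tolerance = 1e-9)
  fr <- predict_answer("pre_bayes", mam,
                       inference_query("P(A|B)", "natural_frequency"))
  expect_equal(c(fr$numerator, fr$denominator), c(100, 1030))
  # likelihood addition reproduces the 80% + 9.6% pattern
  expect_equal(100 * predict_answer("likelihood_addition", mam, q_ab_p)$value,
               89.6, tolerance = 1e-9)
  # conjoint-sum variant collapses onto the evidence margin
  expect_equal(predict_answer("likelihood_addition", mam, q_ab_p,
                              likelihood_addition_variant = "conjoint")$value,
               0.10304, tolerance = 1e-12)
  expect_equal(predict_answer("base_rate_only", mam, q_ab_p)$value, 0.01)
  expect_equal(predict_answer("evidence_only", mam, q_ab_p)$value, 0.10304,
               tolerance = 1e-12)
  expect_equal(predict_answer("cpr_fpr_ratio", mam, q_ab_p)$value, 1)
  # fisherian for a negative-direction query is the inverse conditional
  fr <- predict_answer("fisherian", mam,
                       inference_query("P(notA|B)", "natural_frequency"))
  expect_equal(c(fr$numerator, fr$denominator), c(950, 9900))
})

test_that("strategy applicability respects format and inference class", {
  expect_error(predict_answer("pre_bayes", mam,
                              inference_query("P(A|B)", "probability")),
               class = "bg_applicability_error")
  for (nm in c("likelihood_subtraction", "likelihood_addition",
               "cpr_fpr_ratio")) {
    expect_error(predict_answer(nm, mam,
                                inference_query("P(A|B)", "natural_frequency")),
                 class = "bg_applicability_error")
  }
  expect_error(predict_answer("fisherian", mam,
                              inference_query("P(B)", "probability")),
               class = "bg_applicability_error")
  # quantity confusion applies to any query
  a <- predict_answer(strategy("quantity_confusion", quantity = "P(B|A)"),
                      mam, inference_query("P(A&B)", "probability"))
  expect_equal(a$value, 0.8)
})

test_that("candidate spaces contain the documented confusions", {
  cfg <- classifier_config()
  labels_of <- function(space) unlist(lapply(space, `[[`, "labels"))
  values_of <- function(space) lapply(space, `[[`, "answer")

  # conjoint frequency query: correct pair and the reference-class confusion
  sp <- candidate_space(mam, inference_query("P(A&notB)", "natural_frequency"),
                        cfg)
  pairs <- vapply(values_of(sp), function(a) {
    if (a$format == "natural_frequency") {
      sprintf("%g/%g", a$numerator, a$denominator)
    } else {
      ""
    }
  }, character(1))
  expect_true("20/10000" %in% pairs)   # correct conjoint
  i <- which(pairs == "20/100")        # read as "out of 100 with cancer"
  expect_length(i, 1)
  expect_true(any(grepl("quantity_confusion:P\\(notB\\|A\\)",
                        sp[[i]]$labels)))

  # conjoint probability query: 80% present as the P(B|A) confusion
  sp <- candidate_space(mam, inference_query("P(A&B)", "probability"), cfg)
  vals <- vapply(values_of(sp), function(a) a$value, numeric(1))
  i <- which(abs(vals - 0.8) < 1e-12)
  expect_true(any(grepl("quantity_confusion:P\\(B\\|A\\)", sp[[i]]$labels)))

  # the correct strategy is always present
  for (s in both_scenarios) {
    for (code in c("P(B)", "P(A&B)", "P(B|A)", bayesian_codes)) {
      for (fmt in c("probability", "natural_frequency")) {
        sp <- candidate_space(s, inference_query(code, fmt), cfg)
        expect_true("correct" %in% labels_of(sp))
      }
    }
  }
})

test_that("classification reproduces the documented attributions", {
  q <- inference_query("P(notA|B)", "natural_frequency")
  cl <- classify_answer(frequency_answer(950, 10000), mam, q)
  expect_equal(cl$assigned, "joint_occurrence")
  cl <- classify_answer(frequency_answer(950, 9900), mam, q)
  expect_equal(cl$assigned, "fisherian")
  # the misread "20 out of 100" only matches a complement-misread variant
  cl <- classify_answer(frequency_answer(20, 100), mam, q)
  expect_true(cl$misread_flag)
  expect_equal(cl$assigned, "complement_misread")
  # probability answers inside the integer-percent band count as correct
  cl <- classify_answer(probability_answer(0.075), mam,
                        inference_query("P(A|B)", "probability"))
  expect_equal(cl$assigned, "correct")
  # far-off answers are unclassified
  cl <- classify_answer(probability_answer(0.333), mam,
                        inference_query("P(A|B)", "probability"))
  expect_equal(cl$assigned, "unclassified")
  expect_error(classify_answer(frequency_answer(1, 2), mam,
                               inference_query("P(A|B)", "probability")),
               "format")
})

test_that("noise-free predictions are always recovered in the candidate set", {
  cfg <- classifier_config()
  for (s in both_scenarios) {
    for (code in bayesian_codes) {
      for (fmt in c("probability", "natural_frequency")) {
        q <- inference_query(code, fmt, s$context_id)
        for (nm in setdiff(applicable_strategies_for_test(q),
                           "quantity_confusion")) {
          pred <- predict_answer(nm, s, q)
          cl <- classify_answer(pred, s, q, cfg)
          hit <- any(grepl(nm, cl$candidates$label, fixed = TRUE))
          expect_true(hit, info = sprintf("%s %s %s %s", s$context_id, code,
                                          fmt, nm))
          # non-separable predictions must never resolve silently
          if (cl$assigned != nm) expect_true(cl$ambiguous)
        }
      }
    }
  }
})

test_that("candidate sets grow monotonically with the tolerance", {
  q <- inference_query("P(notA|notB)", "probability")
  answers <- lapply(c(0.89, 0.90, 0.904, 0.95, 0.998), probability_answer)
  tols <- c(0, 0.25, 0.5, 1, 2)
  for (ans in answers) {
    n_prev <- -1
    for (tol in tols) {
      cl <- classify_answer(ans, mam, q,
                            classifier_config(probability_tolerance = tol))
      expect_gte(nrow(cl$candidates), n_prev)
      n_prev <- nrow(cl$candidates)
    }
  }
})

test_that("ratio-equivalent matching flags reduced pairs", {
  cfg <- classifier_config(frequency_match_mode = "ratio_equivalent")
  q <- inference_query("P(A|B)", "natural_frequency")
  cl <- classify_answer(frequency_answer(8, 103), mam, q, cfg)
  expect_equal(cl$assigned, "correct")
  expect_true(any(cl$candidates$reduced_ratio))
  # exact-pair mode rejects the reduced pair
  cl <- classify_answer(frequency_answer(8, 103), mam, q, classifier_config())
  expect_equal(cl$assigned, "unclassified")
})

test_that("the separability audit flags colliding predictions", {
  # economics P(notA|notB) probability: joint occurrence (45%) vs the
  # on-screen cell k — audits report pairs within tolerance
  aud <- separability_audit(mam, inference_query("P(notA|notB)", "probability"))
  expect_true(is.data.frame(aud))
  if (nrow(aud)) {
    for (i in seq_len(nrow(aud))) {
      v <- predict_answer(aud$strategy1[i], mam,
                          inference_query("P(notA|notB)", "probability"))
      cl <- classify_answer(v, mam,
                            inference_query("P(notA|notB)", "probability"))
      expect_true(cl$ambiguous)
    }
  }
})

test_that("error tallies count injections and conserve trials", {
  plan <- simulate_design(simulation_config(n_participants = 4), seed = 5)
  bayes <- plan[plan$inference_class == "bayesian", ]
  rows <- lapply(seq_len(nrow(bayes)), function(i) {
    r <- bayes[i, ]
    s <- both_scenarios[[r$context_id]]
    q <- inference_query(r$query_code, r$format, r$context_id)
    nm <- if (i <= 5) "fisherian" else "correct"
    a <- predict_answer(nm, s, q)
    data.frame(r, answer_prob = if (a$format == "probability") 100 * a$value
                                else NA_real_,
               answer_num = if (a$format == "probability") NA_real_
                            else a$numerator,
               answer_den = if (a$format == "probability") NA_real_
                            else a$denominator)
  })
  log <- do.call(rbind, rows)
  cl <- classify_answers(log, both_scenarios)
  tly <- tally_errors(cl)
  expect_equal(sum(tly$counts$n[tly$counts$strategy == "fisherian"]), 5)
  expect_equal(tly$n_errors, sum(!cl$correct))
  expect_equal(sum(tly$counts$n), tly$n_errors)
  # all-correct input gives an empty tally
  all_ok <- log
  for (i in seq_len(nrow(all_ok))) {
    r <- all_ok[i, ]
    a <- predict_answer("correct", both_scenarios[[r$context_id]],
                        inference_query(r$query_code, r$format))
    if (a$format == "probability") {
      all_ok$answer_prob[i] <- 100 * a$value
    } else {
      all_ok$answer_num[i] <- a$numerator
      all_ok$answer_den[i] <- a$denominator
    }
  }
  tly0 <- tally_errors(classify_answers(all_ok, both_scenarios))
  expect_equal(tly0$n_errors, 0)
  expect_equal(nrow(tly0$counts), 0)
})
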