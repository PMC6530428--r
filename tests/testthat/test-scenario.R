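test_that("scenario construction from branch rates fills the joint cells", {
  cases <- list(
    # base rate, hit rate, false-alarm rate, N, expected cells
    list(0.01, 0.80, 0.096, 10000, c(0.008, 0.002, 0.09504, 0.89496)),
    list(0.5, 1.0, 0.0, 100, c(0.5, 0, 0, 0.5)),          # perfect test
    list(0.25, 0.80, 0.40, 1000, c(0.20, 0.05, 0.30, 0.45)))  # economics
  for (cs in cases) {
    s <- scenario_from_rates(cs[[1]], cs[[2]], cs[[3]], cs[[4]])
    expect_equal(c(s$p11, s$p10, s$p01, s$p00), cs[[5]], tolerance = 1e-12)
    expect_equal(s$p11 + s$p10 + s$p01 + s$p00, 1, tolerance = 1e-12)
  }
})

test_that("invalid scenario inputs are rejected", {
  expect_error(scenario_from_rates(1.2, 0.5, 0.5, 100), "rates")
  expect_error(scenario_from_rates(0.5, -0.1, 0.5, 100), "rates")
  expect_error(scenario_from_rates(0.5, 0.5, 0.5, 0), "population_n")
  expect_error(scenario("x", 0.5, 0.5, 0.2, 0.2, 100), "sum to 1")
  expect_error(scenario("x", -0.1, 0.5, 0.3, 0.3, 100), ">= 0")
})

test_that("branch probabilities round-trip through the joint cells", {
  set.seed(11)
  for (i in 1:50) {
    s <- random_scenario()
    br <- branch_probabilities(s)
    expect_equal(br[["b"]] + br[["c"]], 1, tolerance = 1e-12)
    expect_equal(br[["d"]] + br[["e"]], 1, tolerance = 1e-12)
    expect_equal(br[["f"]] + br[["g"]], 1, tolerance = 1e-12)
    expect_equal(br[["b"]] * br[["d"]], s$p11, tolerance = 1e-12)
    expect_equal(br[["c"]] * br[["f"]], s$p01, tolerance = 1e-12)
    s2 <- scenario_from_rates(br[["b"]], br[["d"]], br[["f"]], s$population_n)
    expect_equal(c(s2$p11, s2$p10, s2$p01, s2$p00),
                 c(s$p11, s$p10, s$p01, s$p00), tolerance = 1e-12)
  }
})

test_that("the probability set satisfies its internal identities", {
  ps <- probability_set(mam)
  expect_length(unclass(ps), 16)
  expect_equal(round(100 * ps[["P(B)"]], 1), 10.3)
  expect_equal(round(100 * ps[["P(notA|notB)"]], 1), 99.8)
  # independence: every conditional equals its marginal
  ind <- scenario("ind", 0.25, 0.25, 0.25, 0.25, 100)
  psi <- probability_set(ind)
  for (code in c("P(B|A)", "P(B|notA)", "P(A|B)", "P(A|notB)")) {
    expect_equal(psi[[code]], 0.5, tolerance = 1e-12)
  }
  set.seed(21)
  for (i in 1:30) {
    s <- random_scenario()
    p <- probability_set(s)
    expect_equal(p[["P(A)"]] + p[["P(notA)"]], 1, tolerance = 1e-12)
    expect_equal(p[["P(B)"]] + p[["P(notB)"]], 1, tolerance = 1e-12)
    # law of total probability for both marginals
    expect_equal(p[["P(B)"]], p[["P(A&B)"]] + p[["P(notA&B)"]],
                 tolerance = 1e-12)
    expect_equal(p[["P(A)"]], p[["P(A&B)"]] + p[["P(A&notB)"]],
                 tolerance = 1e-12)
    # each conditional is its defining cell ratio
    expect_equal(p[["P(notA|B)"]], s$p01 / (s$p11 + s$p01), tolerance = 1e-12)
    expect_equal(p[["P(notB|notA)"]], s$p00 / (s$p01 + s$p00),
                 tolerance = 1e-12)
  }
})

test_that("zero conditioning margins are flagged undefined, not numeric", {
  s <- scenario_from_rates(0, 0.5, 0.1, 100)   # P(A) = 0
  ps <- probability_set(s)
  expect_true(all(c("P(B|A)", "P(notB|A)") %in% attr(ps, "undefined")))
  expect_true(is.na(ps[["P(B|A)"]]))
  expect_error(answer_query(s, inference_query("P(B|A)", "probability")),
               class = "bg_undefined_conditional")
})

test_that("frequency trees match the printed counts and are exactly additive", {
  expect_equal(unclass(frequency_tree(mam)),
               c(A = 10000L, B = 100L, C = 9900L, D = 80L, E = 20L,
                 F = 950L, G = 8950L))
  expect_equal(unclass(frequency_tree(eco)),
               c(A = 1000L, B = 250L, C = 750L, D = 200L, E = 50L,
                 F = 300L, G = 450L))
  set.seed(31)
  for (n in c(1, 7, 100, 12345)) {
    for (i in 1:10) {
      tr <- frequency_tree(random_scenario(n))
      expect_identical(tr[["B"]] + tr[["C"]], tr[["A"]])
      expect_identical(tr[["D"]] + tr[["E"]], tr[["B"]])
      expect_identical(tr[["F"]] + tr[["G"]], tr[["C"]])
      expect_true(all(unclass(tr) >= 0))
    }
  }
})

test_that("answer_query reproduces the worked answers in both formats", {
  expect_equal(
    round(100 * answer_query(mam, inference_query("P(A|B)", "probability"))$value, 1),
    7.8)
  fr <- answer_query(mam, inference_query("P(A|B)", "natural_frequency"))
  expect_equal(c(fr$numerator, fr$denominator), c(80, 1030))
  fr <- answer_query(mam, inference_query("P(notB)", "natural_frequency"))
  expect_equal(c(fr$numerator, fr$denominator), c(8970, 10000))
  expect_equal(
    100 * answer_query(eco, inference_query("P(notA|notB)", "probability"))$value,
    90)
  fr <- answer_query(eco, inference_query("P(notA|B)", "natural_frequency"))
  expect_equal(c(fr$numerator, fr$denominator), c(300, 500))
  # conjoint and marginal frequency answers use the whole population
  fr <- answer_query(mam, inference_query("P(A&notB)", "natural_frequency"))
  expect_equal(c(fr$numerator, fr$denominator), c(20, 10000))
})

test_that("frequency and probability answers agree within integer rounding", {
  set.seed(41)
  for (i in 1:30) {
    s <- random_scenario(n_pop = sample(c(50, 1000, 10000), 1))
    for (code in sample(all_quantities(), 6)) {
      p <- tryCatch(answer_query(s, inference_query(code, "probability")),
                    bg_undefined_conditional = function(e) NULL)
      f <- tryCatch(answer_query(s, inference_query(code, "natural_frequency")),
                    bg_undefined_conditional = function(e) NULL)
      if (is.null(p) || is.null(f)) next
      expect_lt(abs(p$value - f$numerator / f$denominator),
                2 / s$population_n + 2 / f$denominator)
    }
  }
})

test_that("complementary answers are normalized to their conditioning set", {
  pairs <- list(c("P(A|B)", "P(notA|B)"), c("P(B|notA)", "P(notB|notA)"),
                c("P(B)", "P(notB)"))
  for (s in both_scenarios) {
    for (pr in pairs) {
      a1 <- answer_query(s, inference_query(pr[1], "probability"))
      a2 <- answer_query(s, inference_query(pr[2], "probability"))
      expect_equal(a1$value + a2$value, 1, tolerance = 1e-12)
      f1 <- answer_query(s, inference_query(pr[1], "natural_frequency"))
      f2 <- answer_query(s, inference_query(pr[2], "natural_frequency"))
      expect_equal(f1$denominator, f2$denominator)
      expect_equal(f1$numerator + f2$numerator, f1$denominator)
    }
  }
})

test_that("quantity codes parse, classify and canonicalize", {
  expect_equal(parse_quantity("P(B&A)")$code, "P(A&B)")
  expect_equal(parse_quantity("P(notB&notA)")$code, "P(notA&notB)")
  expect_equal(inference_class_of(c("P(A)", "P(A&B)", "P(B|A)", "P(A|B)")),
               c("marginal", "conjoint", "conditional", "bayesian"))
  expect_error(parse_quantity("P(A|A)"), "both events")
  expect_error(parse_quantity("Q(A)"), "invalid quantity code")
  expect_length(all_quantities(), 16)
  expect_equal(anyDuplicated(all_quantities()), 0L)
})

test_that("the design poses 10 queries per context with balanced cells", {
  for (ctx in c("mammography", "economics")) {
    qs <- design_queries(ctx)
    expect_length(qs, 10)
    cls <- vapply(qs, `[[`, "", "inference_class")
    expect_equal(as.vector(table(cls)[c("marginal", "conjoint", "conditional",
                                        "bayesian")]),
                 c(2L, 2L, 2L, 4L))
    fmt <- vapply(qs, `[[`, "", "format")
    expect_equal(sum(fmt == "probability"), 5L)
    # each non-Bayesian pair mixes formats; Bayesian split 2/2
    for (k in c("marginal", "conjoint", "conditional")) {
      expect_setequal(fmt[cls == k], c("probability", "natural_frequency"))
    }
    expect_equal(sum(cls == "bayesian" & fmt == "probability"), 2L)
    expect_setequal(vapply(qs[cls == "bayesian"], `[[`, "", "code"),
                    bayesian_codes)
  }
})

test_that("scenario JSON round-trips and the packaged contexts load", {
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario_json(mam, path)
  s2 <- read_scenario_json(path)
  expect_equal(s2$p11, mam$p11, tolerance = 1e-15)
  expect_equal(s2$population_n, mam$population_n)
  expect_equal(s2$context_id, "mammography")
  pk_mam <- builtin_scenario("mammography")
  expect_equal(pk_mam$p01, 0.09504, tolerance = 1e-12)
  pk_eco <- builtin_scenario("economics")
  expect_equal(c(pk_eco$p11, pk_eco$p10, pk_eco$p01, pk_eco$p00),
               c(0.2, 0.05, 0.3, 0.45))
  expect_error(builtin_scenario("unknown"))
})
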