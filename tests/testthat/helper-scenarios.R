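# shared fixtures: the two study contexts, built in code
mam <- scenario_from_rates(0.01, 0.80, 0.096, 10000, "mammography",
                           "breast cancer", "positive mammogram")
eco <- scenario(
  "economics", p11 = 0.20, p10 = 0.05, p01 = 0.30, p00 = 0.45,
  population_n = 1000,
  event_a_label = "attends economics course", event_b_label = "career-oriented")
both_scenarios <- list(mammography = mam, economics = eco)

# random valid scenario with strictly positive margins
random_scenario <- function(n_pop = 1000) {
  repeat {
    cells <- stats::rgamma(4, shape = 1)
    cells <- cells / sum(cells)
    # force exact normalization
    cells[4] <- 1 - sum(cells[1:3])
    if (all(cells > 1e-4)) break
  }
  scenario("random", cells[1], cells[2], cells[3], cells[4], n_pop)
}

bayesian_codes <- c("P(A|B)", "P(notA|B)", "P(A|notB)", "P(notA|notB)")

applicable_strategies_for_test <- function(q) {
  getFromNamespace("applicable_strategies", "bayesgaze")(q)
}
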