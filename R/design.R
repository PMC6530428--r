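#' Built-in scenarios
#'
#' Two scenarios ship with the package as JSON under `extdata/`:
#'
#' * `"mammography"` — prevalence 1%, sensitivity 80%, false-alarm rate 9.6%,
#'   reference population 10,000 women (shown on tree diagrams).
#' * `"economics"` — a synthetic reconstruction of the economics-course
#'   context from its published cell values: conjoint cells
#'   (0.20, 0.05, 0.30, 0.45) for (A&B, A&notB, notA&B, notA&notB) over
#'   1,000 students (shown on 2x2 tables).
#'
#' @param context_id `"mammography"` or `"economics"`.
#' @return a [scenario()].
#' @export
builtin_scenario <- function(context_id = c("mammography", "economics")) {
  context_id <- match.arg(context_id)
  path <- system.file("extdata", paste0(context_id, ".json"),
                      package = "bayesgaze", mustWork = TRUE)
  read_scenario_json(path)
}

#' Scenario JSON input/output
#'
#' The on-disk form is a JSON object with `context_id`, `event_a_label`,
#' `event_b_label`, `population_n` and either `cells` (the four conjoint
#' probabilities `[p11, p10, p01, p00]`) or `branches`
#' (`[base_rate, hit_rate, false_alarm_rate]`).
#'
#' @param path file path.
#' @param s a [scenario()].
#' @return `read_scenario_json()` returns a `bg_scenario`;
#'   `write_scenario_json()` invisibly returns `path`.
#' @export
read_scenario_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  labs <- list(a = j$event_a_label %||% "A", b = j$event_b_label %||% "B")
  if (!is.null(j$cells)) {
    scenario(j$context_id, j$cells[1], j$cells[2], j$cells[3], j$cells[4],
             j$population_n, labs$a, labs$b)
  } else if (!is.null(j$branches)) {
    scenario_from_rates(j$branches[1], j$branches[2], j$branches[3],
                        j$population_n, j$context_id, labs$a, labs$b)
  } else {
    stop("scenario JSON needs either 'cells' or 'branches': ", path,
         call. = FALSE)
  }
}

#' @rdname read_scenario_json
#' @export
write_scenario_json <- function(s, path) {
  stopifnot(inherits(s, "bg_scenario"))
  jsonlite::write_json(
    list(context_id = s$context_id,
         event_a_label = s$event_a_label, event_b_label = s$event_b_label,
         cells = c(s$p11, s$p10, s$p01, s$p00),
         population_n = s$population_n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' The ten inferences posed per context
#'
#' Each context poses 10 of the 16 quantities: 2 marginal, 2 conjoint,
#' 2 (non-inverted) conditional and all 4 Bayesian quantities
#' (P(A|B), P(notA|B), P(A|notB), P(notA|notB)). Formats are balanced 5/5:
#' within each non-Bayesian pair one query is asked as a probability and the
#' other as a natural frequency, and the Bayesian four are split 2/2.
#'
#' The second conditional is posed as `P(notB|A)` (probability format),
#' whose correct answer in the economics context is 20%.
#'
#' @param context_id scenario context label attached to the queries.
#' @return list of 10 [inference_query()] objects.
#' @examples
#' qs <- design_queries("mammography")
#' table(vapply(qs, `[[`, "", "inference_class"))
#' @export
design_queries <- function(context_id = "mammography") {
  spec <- list(
    c("P(B)",          "probability"),
    c("P(notB)",       "natural_frequency"),
    c("P(A&B)",        "probability"),
    c("P(A&notB)",     "natural_frequency"),
    c("P(notB|A)",     "probability"),
    c("P(B|A)",        "natural_frequency"),
    c("P(A|B)",        "probability"),
    c("P(notA|notB)",  "probability"),
    c("P(notA|B)",     "natural_frequency"),
    c("P(A|notB)",     "natural_frequency"))
  lapply(spec, function(x) inference_query(x[1], x[2], context_id))
}
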