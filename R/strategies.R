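#' Reasoning strategies for Bayesian inference tasks
#'
#' The catalog covers the correct Bayesian strategy and the documented
#' erroneous ones. Written for the canonical task "P(X|Y) given a tree that
#' first splits on X's event", they generalize to all four Bayesian queries
#' by structural role (target cell, conditioning margin, inverse
#' conditional):
#'
#' * `correct` — cell(X&Y) / margin(Y)
#' * `joint_occurrence` — the conjoint cell(X&Y) alone (out of the population)
#' * `fisherian` — the inverse conditional P(Y|X) (representative thinking)
#' * `likelihood_subtraction` — P(Y|X) - P(Y|notX), floored at 0 (probability only)
#' * `base_rate_only` — P(X) (conservatism)
#' * `evidence_only` — margin(Y) out of the population
#' * `pre_bayes` — margin(X) out of margin(Y) (frequency only)
#' * `cpr_fpr_ratio` — P(Y|X) / P(Y|notX), capped at 1 (probability only)
#' * `likelihood_addition` — P(Y|X) + P(Y|notX), capped at 1 (probability only)
#' * `quantity_confusion(q)` — answering with a different quantity q
#'   altogether (applies to any query, not only Bayesian ones)
#' * `complement_misread(wrapped)` — a wrapped strategy applied after
#'   misreading the question (an event read as its complement)
#'
#' @param name strategy name; `"quantity_confusion"` needs `quantity`,
#'   `"complement_misread"` needs `wrapped`. Strings of the form
#'   `"quantity_confusion:P(B|A)"` are also accepted.
#' @param quantity quantity code for `quantity_confusion`.
#' @param wrapped a `bg_strategy` (or name) for `complement_misread`.
#' @param misread for `complement_misread`, which event was misread:
#'   `"condition"` or `"target"`.
#' @return a `bg_strategy` object.
#' @examples
#' strategy("fisherian")
#' strategy("quantity_confusion", quantity = "P(B|A)")
#' @export
strategy <- function(name, quantity = NULL, wrapped = NULL,
                     misread = c("condition", "target")) {
  if (grepl(":", name, fixed = TRUE)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1]]
    name <- parts[1]
    if (name == "quantity_confusion") quantity <- parts[2]
  }
  name <- match.arg(name, strategy_names())
  if (name == "quantity_confusion") {
    if (is.null(quantity)) stop("quantity_confusion needs a quantity code")
    quantity <- parse_quantity(quantity)$code
  }
  if (name == "complement_misread") {
    if (is.null(wrapped)) stop("complement_misread needs a wrapped strategy")
    if (is.character(wrapped)) wrapped <- strategy(wrapped)
    misread <- match.arg(misread)
  } else {
    misread <- NULL
  }
  structure(list(name = name, quantity = quantity, wrapped = wrapped,
                 misread = misread),
            class = "bg_strategy")
}

#' @rdname strategy
#' @export
strategy_names <- function() {
  c("correct", "joint_occurrence", "fisherian", "likelihood_subtraction",
    "base_rate_only", "evidence_only", "pre_bayes", "cpr_fpr_ratio",
    "likelihood_addition", "quantity_confusion", "complement_misread")
}

#' @export
format.bg_strategy <- function(x, ...) {
  switch(x$name,
    quantity_confusion = sprintf("quantity_confusion:%s", x$quantity),
    complement_misread = sprintf("complement_misread(%s)", format(x$wrapped)),
    x$name)
}

#' @export
print.bg_strategy <- function(x, ...) {
  cat("<strategy>", format(x), "\n")
  invisible(x)
}

applicability_error <- function(strat, query) {
  stop(structure(class = c("bg_applicability_error", "error", "condition"),
                 list(message = sprintf(
                        "strategy '%s' is not applicable to query %s in %s format",
                        format(strat), query$code, query$format),
                      call = NULL)))
}

# strategies applicable to a given query/format (by base name)
applicable_strategies <- function(query) {
  if (query$inference_class != "bayesian") return(c("correct", "quantity_confusion"))
  base <- strategy_names()
  if (query$format == "probability") {
    setdiff(base, c("pre_bayes", "complement_misread"))
  } else {
    setdiff(base, c("likelihood_subtraction", "likelihood_addition",
                    "cpr_fpr_ratio", "complement_misread"))
  }
}

#' Predict the answer a strategy produces
#'
#' @param strat a [strategy()] (or its name).
#' @param s a [scenario()].
#' @param query an [inference_query()]; must be Bayesian for the composite
#'   strategies (everything except `correct` and `quantity_confusion`).
#' @param likelihood_addition_variant `"conditional"` (default,
#'   P(Y|X) + P(Y|notX)) or `"conjoint"` (sum of the two conjoint cells).
#' @return a `bg_answer` in the query's format.
#' @examples
#' mam <- scenario_from_rates(0.01, 0.8, 0.096, 10000, "mammography")
#' q <- inference_query("P(notA|notB)", "probability")
#' predict_answer("fisherian", mam, q)   # 90.4%
#' @export
predict_answer <- function(strat, s, query,
                           likelihood_addition_variant = c("conditional", "conjoint")) {
  if (is.character(strat)) strat <- strategy(strat)
  likelihood_addition_variant <- match.arg(likelihood_addition_variant)
  stopifnot(inherits(s, "bg_scenario"), inherits(query, "bg_query"))

  if (strat$name == "quantity_confusion") {
    return(answer_query(s, inference_query(strat$quantity, query$format,
                                           query$context_id)))
  }
  if (strat$name == "complement_misread") {
    if (query$inference_class != "bayesian") applicability_error(strat, query)
    mis <- inference_query(complement_code(query$code, strat$misread),
                           query$format, query$context_id)
    return(predict_answer(strat$wrapped, s, mis, likelihood_addition_variant))
  }
  if (strat$name == "correct") {
    return(answer_query(s, query))
  }
  if (query$inference_class != "bayesian" ||
      !strat$name %in% applicable_strategies(query)) {
    applicability_error(strat, query)
  }

  # structural roles for the Bayesian query P(X|Y): X on the tree's first
  # split (event A side), Y on the second (event B side)
  tx <- query$quantity$a_pos   # X = A or notA
  cy <- query$quantity$b_pos   # Y = B or notB
  p_cell  <- cell_prob(s, tx, cy)            # P(X & Y)
  p_cell2 <- cell_prob(s, !tx, cy)           # P(notX & Y)
  m_x  <- margin_prob(s, "A", tx)
  m_nx <- 1 - m_x
  m_y  <- margin_prob(s, "B", cy)
  p_y_x  <- if (m_x > 0) p_cell / m_x else NA_real_     # P(Y|X)
  p_y_nx <- if (m_nx > 0) p_cell2 / m_nx else NA_real_  # P(Y|notX)

  if (query$format == "probability") {
    val <- switch(strat$name,
      joint_occurrence = p_cell,
      fisherian = p_y_x,
      likelihood_subtraction = max(0, p_y_x - p_y_nx),
      base_rate_only = m_x,
      evidence_only = m_y,
      cpr_fpr_ratio = if (is.na(p_y_nx) || p_y_nx == 0) NA_real_
                      else min(1, p_y_x / p_y_nx),
      likelihood_addition = if (likelihood_addition_variant == "conditional")
                              min(1, p_y_x + p_y_nx)
                            else min(1, p_cell + p_cell2))
    if (is.na(val)) applicability_error(strat, query)
    return(probability_answer(val))
  }

  tr <- frequency_tree(s)
  n_cell <- tree_count(tr, a_pos = tx,  b_pos = cy, event = NULL)   # n(X&Y)
  n_x <- tree_count(tr, "A", tx)
  n_y <- tree_count(tr, "B", cy)
  N <- tr[["A"]]
  pair <- switch(strat$name,
    joint_occurrence = c(n_cell, N),
    fisherian = c(n_cell, n_x),
    base_rate_only = c(n_x, N),
    evidence_only = c(n_y, N),
    pre_bayes = c(n_x, n_y))
  if (pair[2] < 1) applicability_error(strat, query)
  frequency_answer(pair[1], pair[2])
}
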