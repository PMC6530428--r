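#' Two-binary-event scenarios
#'
#' A scenario is the joint distribution of two binary events A (e.g. having
#' breast cancer, attending an economics course) and B (e.g. a positive
#' mammogram, being career-oriented), together with a reference population
#' size used to express the same information as natural frequencies.
#'
#' `scenario()` builds one from the four conjoint cell probabilities;
#' `scenario_from_rates()` builds one the way diagnostic problems are usually
#' stated, from base rate P(A), hit rate P(B|A) (sensitivity) and false-alarm
#' rate P(B|notA).
#'
#' @param context_id short text label, e.g. `"mammography"`.
#' @param p11,p10,p01,p00 probabilities of A&B, A&notB, notA&B, notA&notB.
#'   Must be non-negative and sum to 1 within 1e-12.
#' @param population_n reference population size (integer >= 1).
#' @param event_a_label,event_b_label human-readable event names.
#' @return an object of class `bg_scenario`.
#' @examples
#' mam <- scenario_from_rates(0.01, 0.80, 0.096, 10000, "mammography")
#' mam$p11   # 0.008
#' @export
scenario <- function(context_id, p11, p10, p01, p00, population_n,
                     event_a_label = "A", event_b_label = "B") {
  cells <- c(p11 = p11, p10 = p10, p01 = p01, p00 = p00)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("cell probabilities must be finite and >= 0", call. = FALSE)
  }
  if (abs(sum(cells) - 1) > 1e-12) {
    stop("cell probabilities must sum to 1 (got ",
         format(sum(cells), digits = 15), ")", call. = FALSE)
  }
  if (!is.numeric(population_n) || length(population_n) != 1L ||
      population_n < 1 || population_n != round(population_n)) {
    stop("population_n must be a positive integer", call. = FALSE)
  }
  structure(
    list(context_id = context_id,
         event_a_label = event_a_label, event_b_label = event_b_label,
         p11 = p11, p10 = p10, p01 = p01, p00 = p00,
         population_n = as.integer(population_n)),
    class = "bg_scenario")
}

#' @rdname scenario
#' @param base_rate P(A), the prevalence of event A.
#' @param hit_rate P(B|A), the sensitivity.
#' @param false_alarm_rate P(B|notA).
#' @export
scenario_from_rates <- function(base_rate, hit_rate, false_alarm_rate,
                                population_n, context_id = "scenario",
                                event_a_label = "A", event_b_label = "B") {
  rates <- c(base_rate = base_rate, hit_rate = hit_rate,
             false_alarm_rate = false_alarm_rate)
  bad <- !is.finite(rates) | rates < 0 | rates > 1
  if (any(bad)) {
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[bad], collapse = ", "), call. = FALSE)
  }
  scenario(context_id,
           p11 = base_rate * hit_rate,
           p10 = base_rate * (1 - hit_rate),
           p01 = (1 - base_rate) * false_alarm_rate,
           p00 = (1 - base_rate) * (1 - false_alarm_rate),
           population_n = population_n,
           event_a_label = event_a_label, event_b_label = event_b_label)
}

#' @export
print.bg_scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s  (A: %s, B: %s), N = %s\n", x$context_id,
              x$event_a_label, x$event_b_label,
              format(x$population_n, big.mark = ",")))
  cells <- matrix(c(x$p11, x$p10, x$p01, x$p00), 2, byrow = TRUE,
                  dimnames = list(c("A", "notA"), c("B", "notB")))
  print(round(cells, 6))
  invisible(x)
}

# --- cell / margin accessors ------------------------------------------------

cell_prob <- function(s, a_pos, b_pos) {
  if (a_pos) { if (b_pos) s$p11 else s$p10 } else { if (b_pos) s$p01 else s$p00 }
}

margin_prob <- function(s, event, pos) {
  if (event == "A") {
    m <- s$p11 + s$p10
  } else {
    m <- s$p11 + s$p01
  }
  if (pos) m else 1 - m
}

#' Branch probabilities of the canonical tree
#'
#' The tree first splits the population on A, then on B: its branches carry
#' b = P(A), c = P(notA), d = P(B|A), e = P(notB|A), f = P(B|notA),
#' g = P(notB|notA). These are the lowercase symbols used to label the
#' probability-format stimuli and AOIs.
#'
#' @param s a [scenario()].
#' @return named numeric vector `c(b, c, d, e, f, g)`; conditional branches
#'   are `NA` when their parent margin is zero.
#' @export
branch_probabilities <- function(s) {
  stopifnot(inherits(s, "bg_scenario"))
  b <- s$p11 + s$p10
  cc <- 1 - b
  d <- if (b > 0) s$p11 / b else NA_real_
  f <- if (cc > 0) s$p01 / cc else NA_real_
  c(b = b, c = cc, d = d, e = if (is.na(d)) NA_real_ else 1 - d,
    f = f, g = if (is.na(f)) NA_real_ else 1 - f)
}

#' All sixteen probabilities of a scenario
#'
#' Computes every marginal, conjoint and conditional probability of the
#' situation. Conditionals are cell/margin ratios; those whose conditioning
#' margin is exactly zero are flagged undefined (returned as `NA` and listed
#' in the `undefined` attribute) rather than silently propagated.
#'
#' @param s a [scenario()].
#' @return named numeric vector over the codes of [all_quantities()], class
#'   `bg_probability_set`, with attribute `undefined` (character vector of
#'   codes whose conditioning margin is zero).
#' @examples
#' ps <- probability_set(scenario_from_rates(0.01, 0.8, 0.096, 10000))
#' round(100 * ps[["P(B)"]], 1)   # 10.3
#' @export
probability_set <- function(s) {
  stopifnot(inherits(s, "bg_scenario"))
  codes <- all_quantities()
  vals <- vapply(codes, function(cd) {
    v <- quantity_value(s, cd)
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
  structure(vals, undefined = codes[is.na(vals)], class = "bg_probability_set")
}

#' @export
print.bg_probability_set <- function(x, digits = 4, ...) {
  cat("<probability set> (16 quantities)\n")
  print(round(unclass(x), digits))
  und <- attr(x, "undefined")
  if (length(und)) cat("undefined (zero conditioning margin):",
                       paste(und, collapse = ", "), "\n")
  invisible(x)
}

# full-precision value of one quantity; NULL when conditioning margin is 0
quantity_value <- function(s, code) {
  q <- if (is.list(code)) code else parse_quantity(code)
  switch(q$kind,
    marginal = {
      if (!is.na(q$a_pos)) margin_prob(s, "A", q$a_pos)
      else margin_prob(s, "B", q$b_pos)
    },
    conjoint = cell_prob(s, q$a_pos, q$b_pos),
    conditional = {
      cond <- q$condition
      den <- margin_prob(s, cond$event, cond$pos)
      if (den <= 0) return(NULL)
      cell_prob(s, q$a_pos, q$b_pos) / den
    })
}

# --- frequency tree ---------------------------------------------------------

round_half_up <- function(x) floor(x + 0.5)

#' Natural-frequency tree of a scenario
#'
#' Expected frequencies on the canonical tree: A = population, B/C = counts
#' with/without event A, D/E = counts of A&B / A&notB, F/G = counts of
#' notA&B / notA&notB (the uppercase symbols of the frequency stimuli).
#' Counts are expected frequencies rounded half-away-from-zero to the nearest
#' integer; E and G are then derived by subtraction so that the tree is
#' exactly additive (B+C = A, D+E = B, F+G = C) even when rounding would
#' break it (e.g. 9,900 x 0.096 = 950.4 is shown as 950, leaving G = 8,950).
#'
#' @param s a [scenario()].
#' @return named integer vector `c(A, B, C, D, E, F, G)`, class
#'   `bg_frequency_tree`.
#' @examples
#' frequency_tree(scenario_from_rates(0.01, 0.8, 0.096, 10000))
#' @export
frequency_tree <- function(s) {
  stopifnot(inherits(s, "bg_scenario"))
  N <- s$population_n
  A <- N
  B <- round_half_up(N * (s$p11 + s$p10))
  C <- A - B
  D <- min(round_half_up(N * s$p11), B)
  E <- B - D
  F_ <- min(round_half_up(N * s$p01), C)
  G <- C - F_
  structure(as.integer(c(A = A, B = B, C = C, D = D, E = E, F = F_, G = G)),
            names = c("A", "B", "C", "D", "E", "F", "G"),
            class = "bg_frequency_tree")
}

#' @export
print.bg_frequency_tree <- function(x, ...) {
  cat("<frequency tree>\n")
  v <- format(unclass(x), big.mark = ",")
  cat(sprintf("  A=%s -> (B=%s, C=%s) -> (D=%s, E=%s | F=%s, G=%s)\n",
              v[1], v[2], v[3], v[4], v[5], v[6], v[7]))
  invisible(x)
}

# counts of an event set from the tree: returns integer count
tree_count <- function(tr, event, pos = NULL, a_pos = NULL, b_pos = NULL) {
  if (!is.null(a_pos) && !is.null(b_pos)) {    # conjoint cell
    return(if (a_pos) { if (b_pos) tr[["D"]] else tr[["E"]] }
           else { if (b_pos) tr[["F"]] else tr[["G"]] })
  }
  if (event == "A") {
    if (pos) tr[["B"]] else tr[["C"]]
  } else {
    if (pos) tr[["D"]] + tr[["F"]] else tr[["E"]] + tr[["G"]]
  }
}

# --- answers ----------------------------------------------------------------

#' Answers in probability or natural-frequency form
#'
#' @param value probability in `[0, 1]`.
#' @param numerator,denominator non-negative integers, denominator >= 1.
#' @return an object of class `bg_answer`.
#' @export
probability_answer <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(format = "probability", value = value), class = "bg_answer")
}

#' @rdname probability_answer
#' @export
frequency_answer <- function(numerator, denominator) {
  stopifnot(numerator >= 0, denominator >= 1)
  structure(list(format = "natural_frequency",
                 numerator = as.numeric(numerator),
                 denominator = as.numeric(denominator)),
            class = "bg_answer")
}

#' @export
print.bg_answer <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.bg_answer <- function(x, ...) {
  if (x$format == "probability") {
    sprintf("%.4g%%", 100 * x$value)
  } else {
    sprintf("%s out of %s", format(x$numerator, big.mark = ",", scientific = FALSE),
            format(x$denominator, big.mark = ",", scientific = FALSE))
  }
}

answer_ratio <- function(a) {
  if (a$format == "probability") a$value else a$numerator / a$denominator
}

# typed error for zero conditioning margins
undefined_conditional_error <- function(code) {
  stop(structure(class = c("bg_undefined_conditional", "error", "condition"),
                 list(message = paste0("conditional ", code,
                                       " is undefined: conditioning margin is 0"),
                      call = NULL)))
}

#' Correct answer to an inference query
#'
#' Probability-format queries get the exact probability ratio; frequency
#' queries get the natural-frequency pair from the scenario's
#' [frequency_tree()]: the target-subset count out of the conditioning-set
#' count, where the conditioning set of marginal and conjoint queries is the
#' whole population.
#'
#' @param s a [scenario()].
#' @param query an [inference_query()].
#' @return a `bg_answer`. Conditionals with a zero conditioning margin raise
#'   a `bg_undefined_conditional` error.
#' @examples
#' mam <- scenario_from_rates(0.01, 0.8, 0.096, 10000, "mammography")
#' answer_query(mam, inference_query("P(A|B)", "natural_frequency"))
#' # 80 out of 1,030
#' @export
answer_query <- function(s, query) {
  stopifnot(inherits(s, "bg_scenario"), inherits(query, "bg_query"))
  q <- query$quantity
  if (query$format == "probability") {
    v <- quantity_value(s, q)
    if (is.null(v)) undefined_conditional_error(q$code)
    return(probability_answer(v))
  }
  tr <- frequency_tree(s)
  pair <- quantity_frequency_pair(s, q, tr)
  if (is.null(pair)) undefined_conditional_error(q$code)
  frequency_answer(pair[1], pair[2])
}

# frequency pair for a quantity; denominator = "natural" conditioning set
# (population for marginals/conjoints) or forced "population"
quantity_frequency_pair <- function(s, q, tr = frequency_tree(s),
                                    denominator = c("natural", "population")) {
  denominator <- match.arg(denominator)
  if (is.character(q)) q <- parse_quantity(q)
  num <- switch(q$kind,
    marginal = if (!is.na(q$a_pos)) tree_count(tr, "A", q$a_pos)
               else tree_count(tr, "B", q$b_pos),
    conjoint = tree_count(tr, a_pos = q$a_pos, b_pos = q$b_pos, event = NULL),
    conditional = tree_count(tr, a_pos = q$a_pos, b_pos = q$b_pos, event = NULL))
  den <- if (denominator == "population" || q$kind != "conditional") {
    tr[["A"]]
  } else {
    tree_count(tr, q$condition$event, q$condition$pos)
  }
  if (den <= 0) return(NULL)
  c(num, den)
}
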