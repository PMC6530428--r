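#' Quantity codes for two-binary-event situations
#'
#' A situation with two binary events A and B admits sixteen probabilities:
#' four marginals, four conjoints and eight conditionals. Each is addressed by
#' a compact code string with the grammar
#'
#' ```
#' code := "P(" term ")" | "P(" term "&" term ")" | "P(" term "|" term ")"
#' term := "A" | "notA" | "B" | "notB"
#' ```
#'
#' Conjoint codes are canonicalized with the A-side term first, so
#' `"P(B&A)"` parses to `"P(A&B)"`. The tree's first split is on A, which
#' fixes the inference classes: conditioning on A/notA is a plain
#' (non-inverted) `conditional`, conditioning on B/notB is `bayesian`
#' (inverted relative to the tree).
#'
#' @param code a quantity code string.
#' @return `parse_quantity()` returns a list with elements `code`, `kind`
#'   (`"marginal"`, `"conjoint"` or `"conditional"`), `inference_class`
#'   (`"marginal"`, `"conjoint"`, `"conditional"` or `"bayesian"`) and the
#'   event indicators `a_pos`, `b_pos` (logical or `NA` when the event does
#'   not occur in the code), plus `target`/`condition` terms for
#'   conditionals. `all_quantities()` returns the sixteen canonical codes.
#' @examples
#' parse_quantity("P(A|B)")$inference_class   # "bayesian"
#' parse_quantity("P(notB|A)")$inference_class # "conditional"
#' length(all_quantities())                    # 16
#' @export
parse_quantity <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  m <- regmatches(code, regexec(
    "^P\\((not)?([AB])(?:([&|])(not)?([AB]))?\\)$", code))[[1]]
  if (length(m) == 0L) {
    stop("invalid quantity code: ", sQuote(code), call. = FALSE)
  }
  term1 <- list(event = m[3], pos = !nzchar(m[2]))
  op <- m[4]
  if (!nzchar(op)) {
    out <- list(
      code = sprintf("P(%s%s)", if (term1$pos) "" else "not", term1$event),
      kind = "marginal", inference_class = "marginal",
      a_pos = if (term1$event == "A") term1$pos else NA,
      b_pos = if (term1$event == "B") term1$pos else NA)
    return(out)
  }
  term2 <- list(event = m[6], pos = !nzchar(m[5]))
  if (term1$event == term2$event) {
    stop("quantity code must involve both events: ", sQuote(code), call. = FALSE)
  }
  term_str <- function(t) sprintf("%s%s", if (t$pos) "" else "not", t$event)
  if (op == "&") {
    a <- if (term1$event == "A") term1 else term2
    b <- if (term1$event == "B") term1 else term2
    list(
      code = sprintf("P(%s&%s)", term_str(a), term_str(b)),
      kind = "conjoint", inference_class = "conjoint",
      a_pos = a$pos, b_pos = b$pos)
  } else {
    bayes <- term2$event == "B"  # conditioning on B / notB inverts the tree
    list(
      code = sprintf("P(%s|%s)", term_str(term1), term_str(term2)),
      kind = "conditional",
      inference_class = if (bayes) "bayesian" else "conditional",
      a_pos = if (term1$event == "A") term1$pos else term2$pos,
      b_pos = if (term1$event == "B") term1$pos else term2$pos,
      target = term1, condition = term2)
  }
}

#' @rdname parse_quantity
#' @export
all_quantities <- function() {
  terms_a <- c("A", "notA")
  terms_b <- c("B", "notB")
  c(sprintf("P(%s)", c(terms_a, terms_b)),
    as.vector(outer(terms_a, terms_b, function(a, b) sprintf("P(%s&%s)", a, b))),
    as.vector(outer(terms_b, terms_a, function(b, a) sprintf("P(%s|%s)", b, a))),
    as.vector(outer(terms_a, terms_b, function(a, b) sprintf("P(%s|%s)", a, b))))
}

#' @rdname parse_quantity
#' @export
inference_class_of <- function(code) {
  vapply(code, function(cd) parse_quantity(cd)$inference_class, character(1),
         USE.NAMES = FALSE)
}

#' Construct an inference query
#'
#' A query poses one of the sixteen quantities of a scenario in one of the
#' two response formats used in the experiment: a single probability, or a
#' natural frequency ("x out of y") relative to a concrete reference set.
#'
#' @param code quantity code, see [parse_quantity()].
#' @param format `"probability"` or `"natural_frequency"`.
#' @param context_id optional scenario context label carried along.
#' @return an object of class `bg_query`.
#' @examples
#' inference_query("P(A|B)", "probability", "mammography")
#' @export
inference_query <- function(code, format = c("probability", "natural_frequency"),
                            context_id = NULL) {
  format <- match.arg(format)
  q <- parse_quantity(code)
  structure(
    list(code = q$code, quantity = q, inference_class = q$inference_class,
         format = format, context_id = context_id),
    class = "bg_query")
}

#' @export
print.bg_query <- function(x, ...) {
  cat(sprintf("<query> %s  [%s, %s%s]\n", x$code, x$inference_class, x$format,
              if (is.null(x$context_id)) "" else paste0(", ", x$context_id)))
  invisible(x)
}

# complement a term string inside a code, used for misread variants
complement_code <- function(code, which = c("condition", "target")) {
  which <- match.arg(which)
  q <- parse_quantity(code)
  if (q$kind != "conditional") stop("complement_code() needs a conditional code")
  flip <- function(t) list(event = t$event, pos = !t$pos)
  tgt <- q$target; cond <- q$condition
  if (which == "condition") cond <- flip(cond) else tgt <- flip(tgt)
  ts <- function(t) sprintf("%s%s", if (t$pos) "" else "not", t$event)
  parse_quantity(sprintf("P(%s|%s)", ts(tgt), ts(cond)))$code
}
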