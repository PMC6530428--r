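#' Classifier configuration
#'
#' Operationalizes the study's coding rule: a probability answer matches a
#' candidate if both round to the same integer percent or if they differ by
#' at most `probability_tolerance` percentage points (the default half-width
#' 0.5 reproduces coding answers near 7.8% as correct when they fall between
#' 7 and 8%). Frequency answers match exactly as pairs by default; in
#' `ratio_equivalent` mode, pairs with equal ratios (e.g. "8 out of 103")
#' also match and are flagged as reduced ratios.
#'
#' @param probability_tolerance half-width in percentage points (>= 0).
#' @param frequency_match_mode `"exact_pair"` or `"ratio_equivalent"`.
#' @param priority_order tie-break order over strategy names, most plausible
#'   first; must contain every name in [strategy_names()] exactly once.
#' @param generate_misreads also generate complement-misread candidate
#'   variants for Bayesian queries.
#' @param likelihood_addition_variant see [predict_answer()].
#' @return an object of class `bg_classifier_config`.
#' @export
classifier_config <- function(probability_tolerance = 0.5,
                              frequency_match_mode = c("exact_pair", "ratio_equivalent"),
                              priority_order = c(
                                "correct", "fisherian", "joint_occurrence",
                                "evidence_only", "base_rate_only", "pre_bayes",
                                "likelihood_subtraction", "likelihood_addition",
                                "cpr_fpr_ratio", "quantity_confusion",
                                "complement_misread"),
                              generate_misreads = TRUE,
                              likelihood_addition_variant = c("conditional", "conjoint")) {
  stopifnot(probability_tolerance >= 0)
  if (!setequal(priority_order, strategy_names()) ||
      anyDuplicated(priority_order)) {
    stop("priority_order must contain every strategy name exactly once",
         call. = FALSE)
  }
  structure(
    list(probability_tolerance = probability_tolerance,
         frequency_match_mode = match.arg(frequency_match_mode),
         priority_order = priority_order,
         generate_misreads = isTRUE(generate_misreads),
         likelihood_addition_variant = match.arg(likelihood_addition_variant)),
    class = "bg_classifier_config")
}

# quantity codes reachable from a conditional code by complementing events
# (either direction), excluding the code itself and its plain inverse
misread_family <- function(code) {
  q <- parse_quantity(code)
  if (q$kind != "conditional") return(character(0))
  ts <- function(e, p) sprintf("%s%s", if (p) "" else "not", e)
  combos <- expand.grid(tp = c(TRUE, FALSE), cp = c(TRUE, FALSE),
                        inv = c(FALSE, TRUE))
  codes <- apply(combos, 1, function(r) {
    tgt <- list(event = q$target$event, pos = as.logical(r[["tp"]]))
    cond <- list(event = q$condition$event, pos = as.logical(r[["cp"]]))
    if (as.logical(r[["inv"]])) { tmp <- tgt; tgt <- cond; cond <- tmp }
    sprintf("P(%s|%s)", ts(tgt$event, tgt$pos), ts(cond$event, cond$pos))
  })
  inverse <- sprintf("P(%s|%s)", ts(q$condition$event, q$condition$pos),
                     ts(q$target$event, q$target$pos))
  setdiff(unique(codes), c(code, inverse))
}

answer_key <- function(a) {
  if (a$format == "probability") sprintf("p:%.12g", a$value)
  else sprintf("f:%g/%g", a$numerator, a$denominator)
}

#' Labeled prediction table for one query
#'
#' Every applicable named strategy's prediction, plus quantity-confusion
#' predictions for the other fifteen quantities (frequency quantities are
#' offered both with their natural conditioning set and with the whole
#' population as denominator, covering reference-class confusions), plus
#' complement-misread variants when enabled. Candidates with identical
#' predictions are collapsed, keeping all labels.
#'
#' @param s a [scenario()].
#' @param query an [inference_query()].
#' @param cfg a [classifier_config()].
#' @return a list of candidates, each with elements `labels` (character),
#'   `answer` (`bg_answer`) and `misread` (logical: TRUE when every label of
#'   the candidate is a misread variant).
#' @export
candidate_space <- function(s, query, cfg = classifier_config()) {
  stopifnot(inherits(cfg, "bg_classifier_config"))
  cands <- list()
  add <- function(label, answer, misread = FALSE) {
    key <- answer_key(answer)
    if (is.null(cands[[key]])) {
      cands[[key]] <<- list(labels = label, answer = answer, misread = misread)
    } else {
      cands[[key]]$labels <<- unique(c(cands[[key]]$labels, label))
      cands[[key]]$misread <<- cands[[key]]$misread && misread
    }
  }
  named <- setdiff(applicable_strategies(query), "quantity_confusion")
  for (nm in named) {
    ans <- tryCatch(predict_answer(nm, s, query, cfg$likelihood_addition_variant),
                    bg_applicability_error = function(e) NULL,
                    bg_undefined_conditional = function(e) NULL)
    if (!is.null(ans)) add(nm, ans)
  }
  fam <- if (cfg$generate_misreads) misread_family(query$code) else character(0)
  tr <- frequency_tree(s)
  for (q2 in setdiff(all_quantities(), query$code)) {
    lab <- sprintf("quantity_confusion:%s", q2)
    mis <- q2 %in% fam
    if (mis) lab <- sprintf("complement_misread(%s)", lab)
    if (query$format == "probability") {
      v <- quantity_value(s, q2)
      if (!is.null(v)) add(lab, probability_answer(v), mis)
    } else {
      pq <- parse_quantity(q2)
      nat <- quantity_frequency_pair(s, pq, tr, "natural")
      if (!is.null(nat)) add(lab, frequency_answer(nat[1], nat[2]), mis)
      if (pq$kind == "conditional") {
        pop <- quantity_frequency_pair(s, pq, tr, "population")
        if (!is.null(pop) && !identical(pop, nat)) {
          add(lab, frequency_answer(pop[1], pop[2]), mis)
        }
      }
    }
  }
  if (cfg$generate_misreads && query$inference_class == "bayesian") {
    for (nm in named) for (which in c("condition", "target")) {
      st <- strategy("complement_misread", wrapped = nm, misread = which)
      ans <- tryCatch(predict_answer(st, s, query, cfg$likelihood_addition_variant),
                      bg_applicability_error = function(e) NULL,
                      bg_undefined_conditional = function(e) NULL)
      if (!is.null(ans)) add(format(st), ans, misread = TRUE)
    }
  }
  unname(cands)
}

base_label <- function(label) sub("[(:].*$", "", label)

#' Classify an observed answer
#'
#' Matches the answer against the [candidate_space()] of the query. The
#' assigned strategy is the unique exact match if there is one; otherwise the
#' match with minimal distance, ties broken by the configured priority
#' order. With no match the answer is `"unclassified"`. `ambiguous` is TRUE
#' whenever more than one candidate (or one candidate carrying several
#' strategy labels) matches — non-separable strategies are never silently
#' resolved to a unique label. `misread_flag` is TRUE when only
#' complement-misread variants match.
#'
#' @param answer a `bg_answer` in the query's format.
#' @param s a [scenario()].
#' @param query an [inference_query()].
#' @param cfg a [classifier_config()].
#' @param space optional precomputed [candidate_space()] for the query
#'   (classifying many answers to the same query is much faster with one).
#' @return an object of class `bg_classification` with fields `assigned`,
#'   `assigned_label`, `candidates` (data.frame of label, distance, misread,
#'   exact), `ambiguous`, `misread_flag`, `correct`.
#' @examples
#' mam <- scenario_from_rates(0.01, 0.8, 0.096, 10000, "mammography")
#' q <- inference_query("P(notA|B)", "natural_frequency")
#' classify_answer(frequency_answer(950, 10000), mam, q)$assigned
#' # "joint_occurrence"
#' @export
classify_answer <- function(answer, s, query, cfg = classifier_config(),
                            space = NULL) {
  stopifnot(inherits(answer, "bg_answer"))
  if (answer$format != query$format) {
    stop("answer format (", answer$format, ") does not match query format (",
         query$format, ")", call. = FALSE)
  }
  if (is.null(space)) space <- candidate_space(s, query, cfg)
  rows <- lapply(space, function(cand) {
    pred <- cand$answer
    if (query$format == "probability") {
      obs_pct <- 100 * answer$value
      pred_pct <- 100 * pred$value
      dist <- abs(obs_pct - pred_pct)
      exact <- dist < 1e-9
      match <- exact || round(obs_pct) == round(pred_pct) ||
        dist <= cfg$probability_tolerance
      reduced <- FALSE
    } else {
      pair_eq <- answer$numerator == pred$numerator &&
        answer$denominator == pred$denominator
      dist <- abs(answer_ratio(answer) - answer_ratio(pred)) * 100
      exact <- pair_eq
      match <- if (cfg$frequency_match_mode == "exact_pair") pair_eq
               else dist < 1e-9
      reduced <- match && !pair_eq
    }
    list(cand = cand, match = match, exact = exact, dist = dist,
         reduced = reduced)
  })
  matched <- Filter(function(r) r$match, rows)
  cand_df <- if (length(matched)) {
    do.call(rbind, lapply(matched, function(r) {
      data.frame(label = paste(r$cand$labels, collapse = " | "),
                 distance = r$dist, exact = r$exact,
                 misread = r$cand$misread, reduced_ratio = r$reduced)
    }))
  } else {
    data.frame(label = character(0), distance = numeric(0),
               exact = logical(0), misread = logical(0),
               reduced_ratio = logical(0))
  }
  if (!length(matched)) {
    return(structure(list(assigned = "unclassified", assigned_label = NA_character_,
                          candidates = cand_df, ambiguous = FALSE,
                          misread_flag = FALSE, correct = FALSE),
                     class = "bg_classification"))
  }
  pool <- Filter(function(r) r$exact, matched)
  if (!length(pool)) pool <- matched
  dmin <- min(vapply(pool, `[[`, numeric(1), "dist"))
  pool <- Filter(function(r) r$dist <= dmin + 1e-12, pool)
  labels <- unique(unlist(lapply(pool, function(r) r$cand$labels)))
  prio <- match(base_label(labels), cfg$priority_order)
  winner <- labels[order(prio, labels)][1]
  n_labels_winner <- length(unique(base_label(
    unlist(lapply(matched, function(r) r$cand$labels)))))
  structure(
    list(assigned = base_label(winner), assigned_label = winner,
         candidates = cand_df,
         ambiguous = length(matched) > 1L || n_labels_winner > 1L,
         misread_flag = all(vapply(matched, function(r) r$cand$misread,
                                   logical(1))),
         correct = base_label(winner) == "correct"),
    class = "bg_classification")
}

#' @export
print.bg_classification <- function(x, ...) {
  cat(sprintf("<classification> %s%s%s\n", x$assigned,
              if (x$ambiguous) " (ambiguous)" else "",
              if (x$misread_flag) " [misread]" else ""))
  if (nrow(x$candidates)) {
    print(x$candidates, row.names = FALSE)
  }
  invisible(x)
}

#' Classify an answer log
#'
#' Vectorized classification of an answer-log data frame (the dialect
#' written by [simulate_experiment()] / read by [load_dataset()]):
#' columns `participant_id`, `context_id`, `trial_index`, `query_code`,
#' `format`, `visualization`, and `answer_prob` (in percent) or
#' `answer_num`/`answer_den`.
#'
#' @param answers answer-log data frame.
#' @param scenarios named list of [scenario()] objects keyed by context_id.
#' @param cfg a [classifier_config()].
#' @return the input with columns `assigned`, `assigned_label`, `ambiguous`,
#'   `misread_flag`, `correct`, `n_candidates` appended.
#' @export
classify_answers <- function(answers, scenarios, cfg = classifier_config()) {
  stopifnot(is.data.frame(answers))
  n <- nrow(answers)
  out <- answers
  out$assigned <- character(n); out$assigned_label <- NA_character_
  out$ambiguous <- logical(n); out$misread_flag <- logical(n)
  out$correct <- logical(n); out$n_candidates <- integer(n)
  space_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    s <- scenarios[[answers$context_id[i]]]
    if (is.null(s)) stop("unknown context: ", answers$context_id[i], call. = FALSE)
    query <- inference_query(answers$query_code[i], answers$format[i],
                             answers$context_id[i])
    key <- paste(answers$context_id[i], query$code, query$format)
    if (is.null(space_cache[[key]])) {
      space_cache[[key]] <- candidate_space(s, query, cfg)
    }
    ans <- if (answers$format[i] == "probability") {
      probability_answer(answers$answer_prob[i] / 100)
    } else {
      frequency_answer(answers$answer_num[i], answers$answer_den[i])
    }
    cl <- classify_answer(ans, s, query, cfg, space = space_cache[[key]])
    out$assigned[i] <- cl$assigned
    out$assigned_label[i] <- cl$assigned_label
    out$ambiguous[i] <- cl$ambiguous
    out$misread_flag[i] <- cl$misread_flag
    out$correct[i] <- cl$correct
    out$n_candidates[i] <- nrow(cl$candidates)
  }
  out
}

#' Tally errors by visualization and format
#'
#' Counts assigned strategies per (visualization, format) cell for the
#' erroneous trials of a classified answer log, with an "established errors
#' out of all errors" subtotal per cell (established = the named catalog
#' strategies, as opposed to quantity confusions, misreads and unclassified
#' answers).
#'
#' @param classified output of [classify_answers()] (must carry
#'   `visualization`, `format`, `assigned`).
#' @param bayesian_only restrict to Bayesian inferences (default TRUE, the
#'   stratum the error catalog addresses).
#' @return a list with `counts` (data.frame visualization x format x strategy
#'   x n) and `summary` (errors and established errors per cell), class
#'   `bg_error_tally`.
#' @export
tally_errors <- function(classified, bayesian_only = TRUE) {
  stopifnot(all(c("visualization", "format", "assigned", "query_code") %in%
                  names(classified)))
  df <- classified
  df$inference_class <- inference_class_of(df$query_code)
  if (bayesian_only) df <- df[df$inference_class == "bayesian", , drop = FALSE]
  err <- df[df$assigned != "correct", , drop = FALSE]
  established <- setdiff(strategy_names(),
                         c("correct", "quantity_confusion", "complement_misread"))
  counts <- as.data.frame(table(visualization = err$visualization,
                                format = err$format,
                                strategy = err$assigned),
                          responseName = "n", stringsAsFactors = FALSE)
  counts <- counts[counts$n > 0, , drop = FALSE]
  cells <- unique(df[c("visualization", "format")])
  summary <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- err[err$visualization == cells$visualization[i] &
                 err$format == cells$format[i], , drop = FALSE]
    data.frame(visualization = cells$visualization[i],
               format = cells$format[i],
               errors = nrow(sub),
               established = sum(sub$assigned %in% established))
  }))
  structure(list(counts = counts, summary = summary,
                 n_trials = nrow(df), n_errors = nrow(err)),
            class = "bg_error_tally")
}

#' @export
print.bg_error_tally <- function(x, ...) {
  cat(sprintf("<error tally> %d errors in %d trials\n", x$n_errors, x$n_trials))
  for (i in seq_len(nrow(x$summary))) {
    r <- x$summary[i, ]
    cat(sprintf("  %s / %s: %d established out of %d errors\n",
                r$visualization, r$format, r$established, r$errors))
  }
  invisible(x)
}

#' Which strategy predictions are non-separable?
#'
#' For a scenario and query, reports every pair of named-strategy
#' predictions that the classifier cannot distinguish at its configured
#' tolerance (for probabilities) or that coincide as pairs (frequencies).
#' Answers falling on such predictions are always classified with
#' `ambiguous = TRUE`.
#'
#' @param s a [scenario()].
#' @param query an [inference_query()].
#' @param cfg a [classifier_config()].
#' @return data.frame with columns `strategy1`, `strategy2`, `distance`.
#' @export
separability_audit <- function(s, query, cfg = classifier_config()) {
  named <- setdiff(applicable_strategies(query), "quantity_confusion")
  preds <- list()
  for (nm in named) {
    ans <- tryCatch(predict_answer(nm, s, query, cfg$likelihood_addition_variant),
                    bg_applicability_error = function(e) NULL)
    if (!is.null(ans)) preds[[nm]] <- ans
  }
  nms <- names(preds)
  out <- data.frame(strategy1 = character(0), strategy2 = character(0),
                    distance = numeric(0))
  if (length(nms) < 2) return(out)
  for (i in seq_len(length(nms) - 1)) for (j in seq(i + 1, length(nms))) {
    a <- preds[[i]]; b <- preds[[j]]
    if (query$format == "probability") {
      d <- abs(a$value - b$value) * 100
      clash <- d <= cfg$probability_tolerance ||
        round(100 * a$value) == round(100 * b$value)
    } else {
      clash <- a$numerator == b$numerator && a$denominator == b$denominator
      d <- abs(answer_ratio(a) - answer_ratio(b)) * 100
    }
    if (clash) out <- rbind(out, data.frame(strategy1 = nms[i],
                                            strategy2 = nms[j], distance = d))
  }
  out
}
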