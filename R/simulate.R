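#' Simulation configuration
#'
#' Describes the full experimental design the simulator emulates: 24
#' participants, each answering 20 inferences — a first block of 10
#' mammography questions on tree diagrams, then 10 economics questions on
#' 2x2 tables; within each block the 6 non-Bayesian inferences precede the
#' 4 Bayesian ones, each group in random order, with formats balanced 5/5;
#' 30 s per trial.
#'
#' Latent per-trial strategies are drawn from `strategy_mixture`, a named
#' list keyed `"<inference_class>.<format>"`, each element a named
#' probability vector over strategy names (use `"quantity_confusion"` for a
#' confusion with a uniformly drawn other quantity). Mixture defaults are
#' the package's stand-in for a plausible cohort (mostly correct on
#' non-Bayesian items; Fisherian and joint-occurrence dominating Bayesian
#' errors, frequency formats easier than probability formats); they define
#' the simulator, not claims about any real cohort.
#'
#' @param n_participants number of simulated participants (default 24).
#' @param strategy_mixture see above; partial lists override the defaults
#'   per key.
#' @param answer_noise probability that a trial's numeric answer is replaced
#'   by a uniformly drawn distractor quantity (default 0.05).
#' @param answer_rounding `"one_decimal"` (percent with one decimal, e.g.
#'   "90.4%") or `"integer"` (spoken-style integer percent).
#' @param gaze_params list of gaze-generator knobs: `n_question` initial
#'   question fixations, `n_exec` execution-phase fixations,
#'   `relevant_weight` dwell weight of formula-relevant AOIs vs others
#'   (default 4), `revisit_prob`/`revisit_prob_bayesian` probability of a
#'   question revisit, `dur_meanlog`/`dur_sdlog` lognormal fixation-duration
#'   parameters (ms), `jitter_sd` positional jitter (px).
#' @param time_limit_ms trial time cap (default 30,000).
#' @param master_seed integer seed; every run with the same config is
#'   bit-identical.
#' @return an object of class `bg_sim_config`.
#' @export
simulation_config <- function(n_participants = 24,
                              strategy_mixture = list(),
                              answer_noise = 0.05,
                              answer_rounding = c("one_decimal", "integer"),
                              gaze_params = list(),
                              time_limit_ms = 30000,
                              master_seed = 1L) {
  stopifnot(n_participants >= 1, answer_noise >= 0, answer_noise <= 1,
            time_limit_ms > 0)
  defaults <- list(
    "marginal.probability"          = c(correct = 0.80, quantity_confusion = 0.20),
    "marginal.natural_frequency"    = c(correct = 0.90, quantity_confusion = 0.10),
    "conjoint.probability"          = c(correct = 0.70, quantity_confusion = 0.30),
    "conjoint.natural_frequency"    = c(correct = 0.70, quantity_confusion = 0.30),
    "conditional.probability"       = c(correct = 0.60, quantity_confusion = 0.40),
    "conditional.natural_frequency" = c(correct = 0.80, quantity_confusion = 0.20),
    "bayesian.probability" = c(correct = 0.20, fisherian = 0.35,
                               joint_occurrence = 0.30,
                               likelihood_subtraction = 0.05,
                               evidence_only = 0.05, base_rate_only = 0.05),
    "bayesian.natural_frequency" = c(correct = 0.50, fisherian = 0.20,
                                     joint_occurrence = 0.20,
                                     pre_bayes = 0.05, base_rate_only = 0.05))
  mixture <- utils::modifyList(defaults, strategy_mixture)
  for (key in names(mixture)) {
    v <- mixture[[key]]
    if (abs(sum(v) - 1) > 1e-9 || any(v < 0)) {
      stop("strategy_mixture[['", key, "']] must be a probability vector",
           call. = FALSE)
    }
  }
  gp_default <- list(n_question = 3, n_exec = 18, relevant_weight = 4,
                     revisit_prob = 0.3, revisit_prob_bayesian = 0.5,
                     dur_meanlog = log(250), dur_sdlog = 0.35,
                     jitter_sd = 15, saccade_gap_ms = 20)
  gp <- utils::modifyList(gp_default, gaze_params)
  structure(
    list(n_participants = as.integer(n_participants),
         contexts = list(
           list(context_id = "mammography", visualization = "tree"),
           list(context_id = "economics", visualization = "table")),
         strategy_mixture = mixture,
         answer_noise = answer_noise,
         answer_rounding = match.arg(answer_rounding),
         gaze_params = gp,
         time_limit_ms = time_limit_ms,
         master_seed = as.integer(master_seed)),
    class = "bg_sim_config")
}

# per-participant derived substream seeds (order-independent across
# participants); kept below 2^31
participant_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(master_seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  s
}

shuffle_block_queries <- function(context_id) {
  qs <- design_queries(context_id)
  cls <- vapply(qs, `[[`, "", "inference_class")
  nonb <- which(cls != "bayesian")
  bay <- which(cls == "bayesian")
  qs[c(sample(nonb), sample(bay))]
}

#' Simulate the trial plan
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to the config's master seed).
#' @return data.frame with one row per trial: `participant_id`, `block`,
#'   `trial_index` (1-20), `context_id`, `visualization`, `query_code`,
#'   `inference_class`, `format`.
#' @examples
#' plan <- simulate_design(simulation_config(n_participants = 2), seed = 7)
#' nrow(plan)   # 40
#' @export
simulate_design <- function(config, seed = config$master_seed) {
  stopifnot(inherits(config, "bg_sim_config"))
  seeds <- participant_seeds(seed, config$n_participants)
  rows <- lapply(seq_len(config$n_participants), function(p) {
    set.seed(seeds[p])
    idx <- 0L
    do.call(rbind, lapply(seq_along(config$contexts), function(bi) {
      ctx <- config$contexts[[bi]]
      qs <- shuffle_block_queries(ctx$context_id)
      out <- do.call(rbind, lapply(qs, function(q) {
        idx <<- idx + 1L
        data.frame(participant_id = sprintf("P%02d", p), block = bi,
                   trial_index = idx, context_id = ctx$context_id,
                   visualization = ctx$visualization,
                   query_code = q$code, inference_class = q$inference_class,
                   format = q$format, stringsAsFactors = FALSE)
      }))
      out
    }))
  })
  do.call(rbind, rows)
}

round_answer <- function(ans, rounding) {
  if (ans$format != "probability") return(ans)
  digits <- if (rounding == "one_decimal") 1 else 0
  probability_answer(round(100 * ans$value, digits) / 100)
}

#' Simulate one numeric answer
#'
#' With probability `1 - noise` the strategy's predicted answer (probability
#' answers rounded per `rounding` to mimic spoken responses); otherwise a
#' distractor drawn uniformly from the other quantities' answers.
#'
#' @param strat a [strategy()] or name.
#' @param s a [scenario()].
#' @param query an [inference_query()].
#' @param noise distractor probability in `[0, 1]`.
#' @param rounding `"one_decimal"`, `"integer"` or `"none"`.
#' @return a `bg_answer`. Uses R's RNG; seed upstream for reproducibility.
#' @export
simulate_answer <- function(strat, s, query, noise = 0,
                            rounding = c("one_decimal", "integer", "none")) {
  rounding <- match.arg(rounding)
  pred <- predict_answer(strat, s, query)
  if (rounding != "none") pred <- round_answer(pred, rounding)
  if (noise > 0 && stats::runif(1) < noise) {
    others <- setdiff(all_quantities(), query$code)
    alts <- list()
    for (q2 in others) {
      a <- tryCatch(answer_query(s, inference_query(q2, query$format)),
                    bg_undefined_conditional = function(e) NULL)
      if (is.null(a)) next
      if (rounding != "none") a <- round_answer(a, rounding)
      if (answer_key(a) != answer_key(pred)) alts[[length(alts) + 1L]] <- a
    }
    if (length(alts)) return(alts[[sample.int(length(alts), 1)]])
  }
  pred
}

#' Simulate a strategy-conditioned fixation sequence
#'
#' Four phases: (1) initial fixations on the question AOI; (2) an
#' orientation sweep visiting every AOI top-to-bottom / left-to-right;
#' (3) execution fixations concentrated (by `relevant_weight`) on the AOIs
#' whose symbols the latent strategy's formula references, with Gaussian
#' positional jitter around AOI centers (some land on whitespace);
#' (4) a possible question revisit, more likely for Bayesian queries.
#' Durations are lognormal and the sequence is truncated to the time limit.
#'
#' @param strat a [strategy()] or name.
#' @param s a [scenario()] (unused by the geometry but kept for signature
#'   symmetry with [simulate_answer()]).
#' @param query an [inference_query()].
#' @param layout a [build_layout()] result (format must match the query's).
#' @param gaze_params see [simulation_config()].
#' @param time_limit_ms trial cap.
#' @return data.frame `t_start`, `duration`, `x`, `y` (ms / px); first
#'   fixation is inside the question AOI and the last ends before the cap.
#' @export
simulate_gaze <- function(strat, s, query, layout,
                          gaze_params = simulation_config()$gaze_params,
                          time_limit_ms = 30000) {
  gp <- gaze_params
  a <- layout$aois
  centers <- data.frame(aoi_id = a$aoi_id,
                        cx = (a$x0 + a$x1) / 2, cy = (a$y0 + a$y1) / 2)
  non_q <- a[a$aoi_id != layout$question_id, , drop = FALSE]
  reading <- non_q$aoi_id[order(non_q$y0, non_q$x0)]
  rel <- tryCatch(
    layout$aois$aoi_id[match(formula_symbols(strat, query, layout),
                             layout$aois$symbol)],
    error = function(e) relevant_aois(query, layout))
  rel <- rel[!is.na(rel)]
  w <- ifelse(non_q$aoi_id %in% rel, gp$relevant_weight, 1)
  n_exec <- max(1L, stats::rpois(1, gp$n_exec))
  exec <- sample(non_q$aoi_id, n_exec, replace = TRUE, prob = w)
  p_revisit <- if (query$inference_class == "bayesian") {
    gp$revisit_prob_bayesian
  } else {
    gp$revisit_prob
  }
  revisit <- if (stats::runif(1) < p_revisit) {
    c(rep(layout$question_id, 2), sample(rel, min(2, length(rel))))
  } else {
    character(0)
  }
  seq_ids <- c(rep(layout$question_id, gp$n_question), reading, exec, revisit)
  n <- length(seq_ids)
  ctr <- centers[match(seq_ids, centers$aoi_id), ]
  x <- pmin(pmax(stats::rnorm(n, ctr$cx, gp$jitter_sd), 0),
            layout$canvas$width - 1e-6)
  y <- pmin(pmax(stats::rnorm(n, ctr$cy, gp$jitter_sd), 0),
            layout$canvas$height - 1e-6)
  # question-phase fixations are clamped into the question AOI so every
  # trial's scan path starts on the requested inference
  qrect <- a[a$aoi_id == layout$question_id, ]
  is_q <- seq_ids == layout$question_id
  x[is_q] <- pmin(pmax(x[is_q], qrect$x0), qrect$x1 - 1e-6)
  y[is_q] <- pmin(pmax(y[is_q], qrect$y0), qrect$y1 - 1e-6)
  dur <- stats::rlnorm(n, gp$dur_meanlog, gp$dur_sdlog)
  t_start <- cumsum(c(0, dur[-n] + gp$saccade_gap_ms))
  keep <- t_start + dur <= time_limit_ms
  data.frame(t_start = t_start[keep], duration = dur[keep],
             x = x[keep], y = y[keep])
}

draw_strategy <- function(mixture_key, config) {
  mix <- config$strategy_mixture[[mixture_key]]
  nm <- sample(names(mix), 1, prob = mix)
  if (nm == "quantity_confusion") {
    # a uniformly drawn other quantity; the concrete quantity is resolved
    # per trial against the query in simulate_experiment()
    return(nm)
  }
  nm
}

#' Simulate the full experiment
#'
#' Draws a latent strategy per trial from the configured mixtures, then
#' generates the numeric answer and (optionally) the strategy-conditioned
#' fixation sequence for every trial of every participant. Bit-identical
#' for identical config (participants use derived substreams of the master
#' seed, so per-participant results do not depend on simulation order).
#'
#' @param config a [simulation_config()].
#' @param seed overrides the config's master seed.
#' @param gaze also simulate fixation logs (default TRUE; answers-only runs
#'   are much faster for classifier studies).
#' @return an object of class `bg_dataset`: list with `answers`,
#'   `fixations` (NULL if `gaze = FALSE`), `truth` (latent strategy per
#'   trial), `scenarios`, `config`, `seed`.
#' @examples
#' ds <- simulate_experiment(simulation_config(n_participants = 2), gaze = FALSE)
#' nrow(ds$answers)   # 40
#' @export
simulate_experiment <- function(config = simulation_config(),
                                seed = config$master_seed, gaze = TRUE) {
  stopifnot(inherits(config, "bg_sim_config"))
  scen <- list(mammography = builtin_scenario("mammography"),
               economics = builtin_scenario("economics"))
  layouts <- list()
  for (ctx in config$contexts) {
    for (fmt in c("probability", "natural_frequency")) {
      layouts[[paste(ctx$visualization, fmt)]] <-
        build_layout(ctx$visualization, fmt)
    }
  }
  seeds <- participant_seeds(seed, config$n_participants)
  ans_rows <- list(); fix_rows <- list(); truth_rows <- list()
  for (p in seq_len(config$n_participants)) {
    set.seed(seeds[p])
    pid <- sprintf("P%02d", p)
    idx <- 0L
    for (bi in seq_along(config$contexts)) {
      ctx <- config$contexts[[bi]]
      s <- scen[[ctx$context_id]]
      qs <- shuffle_block_queries(ctx$context_id)
      for (q in qs) {
        idx <- idx + 1L
        key <- paste(q$inference_class, q$format, sep = ".")
        nm <- draw_strategy(key, config)
        strat <- if (nm == "quantity_confusion") {
          strategy("quantity_confusion",
                   quantity = sample(setdiff(all_quantities(), q$code), 1))
        } else {
          strategy(nm)
        }
        ans <- simulate_answer(strat, s, q, config$answer_noise,
                               config$answer_rounding)
        fx <- NULL
        if (gaze) {
          lay <- layouts[[paste(ctx$visualization, q$format)]]
          fx <- simulate_gaze(strat, s, q, lay, config$gaze_params,
                              config$time_limit_ms)
        }
        ans_rows[[length(ans_rows) + 1L]] <- data.frame(
          participant_id = pid, context_id = ctx$context_id,
          trial_index = idx, query_code = q$code,
          inference_class = q$inference_class, format = q$format,
          visualization = ctx$visualization,
          answer_prob = if (ans$format == "probability") 100 * ans$value
                        else NA_real_,
          answer_num = if (ans$format == "probability") NA_real_
                       else ans$numerator,
          answer_den = if (ans$format == "probability") NA_real_
                       else ans$denominator,
          response_time_ms = if (is.null(fx) || !nrow(fx)) NA_real_
                             else max(fx$t_start + fx$duration),
          stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          participant_id = pid, trial_index = idx,
          context_id = ctx$context_id, query_code = q$code,
          format = q$format, strategy = format(strat),
          stringsAsFactors = FALSE)
        if (gaze && nrow(fx)) {
          fix_rows[[length(fix_rows) + 1L]] <- data.frame(
            participant_id = pid, context_id = ctx$context_id,
            trial_index = idx, query_code = q$code, format = q$format,
            visualization = ctx$visualization,
            t_start_ms = fx$t_start, duration_ms = fx$duration,
            x_px = fx$x, y_px = fx$y, stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(
    list(answers = do.call(rbind, ans_rows),
         fixations = if (gaze) do.call(rbind, fix_rows),
         truth = do.call(rbind, truth_rows),
         scenarios = scen, config = config, seed = seed),
    class = "bg_dataset")
}

#' @export
print.bg_dataset <- function(x, ...) {
  cat(sprintf("<simulated dataset> %d participants, %d trials%s (seed %d)\n",
              x$config$n_participants, nrow(x$answers),
              if (is.null(x$fixations)) ", answers only"
              else sprintf(", %d fixations", nrow(x$fixations)),
              x$seed))
  invisible(x)
}

#' Write a simulated dataset as CSV logs
#'
#' Writes `answers.csv`, `truth.csv`, `fixations.csv` (if present) and the
#' scenario JSON files into `dir`, in the same dialects [load_dataset()]
#' consumes. Output is byte-identical for identical datasets.
#'
#' @param ds a `bg_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "bg_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ds$answers, file.path(dir, "answers.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(ds$fixations)) {
    utils::write.csv(ds$fixations, file.path(dir, "fixations.csv"),
                     row.names = FALSE)
  }
  for (nm in names(ds$scenarios)) {
    write_scenario_json(ds$scenarios[[nm]], file.path(dir, paste0(nm, ".json")))
  }
  invisible(dir)
}
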