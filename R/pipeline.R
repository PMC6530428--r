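#' Load an answer/fixation dataset from CSV logs
#'
#' Reads the answer-log and fixation-log dialects written by
#' [write_dataset()] and validates them row by row: required columns,
#' known query codes, answer fields consistent with the stated format.
#' Violations are reported together with their row numbers.
#'
#' @param answer_csv path to the answer log.
#' @param fixation_csv optional path to the fixation log.
#' @param scenarios named list of [scenario()] objects, or paths to scenario
#'   JSON files; defaults to the two built-in contexts.
#' @return a `bg_dataset` (without a latent truth table).
#' @export
load_dataset <- function(answer_csv, fixation_csv = NULL, scenarios = NULL) {
  if (is.null(scenarios)) {
    scenarios <- list(mammography = builtin_scenario("mammography"),
                      economics = builtin_scenario("economics"))
  } else if (is.character(scenarios)) {
    scen <- lapply(scenarios, read_scenario_json)
    scenarios <- stats::setNames(scen, vapply(scen, `[[`, "", "context_id"))
  }
  answers <- utils::read.csv(answer_csv, stringsAsFactors = FALSE)
  req <- c("participant_id", "context_id", "trial_index", "query_code",
           "format")
  missing <- setdiff(req, names(answers))
  if (length(missing)) {
    stop("answer log is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  problems <- character(0)
  for (i in seq_len(nrow(answers))) {
    r <- answers[i, ]
    ok_code <- tryCatch({parse_quantity(r$query_code); TRUE},
                        error = function(e) FALSE)
    if (!ok_code) {
      problems <- c(problems, sprintf("row %d: unknown query code '%s'",
                                      i, r$query_code))
      next
    }
    if (!r$context_id %in% names(scenarios)) {
      problems <- c(problems, sprintf("row %d: unknown context '%s'",
                                      i, r$context_id))
    }
    if (!r$format %in% c("probability", "natural_frequency")) {
      problems <- c(problems, sprintf("row %d: unknown format '%s'",
                                      i, r$format))
    } else if (r$format == "probability") {
      if (is.null(answers$answer_prob) || is.na(r$answer_prob)) {
        problems <- c(problems,
                      sprintf("row %d: probability query without answer_prob", i))
      }
    } else {
      has_pair <- !is.null(answers$answer_num) && !is.null(answers$answer_den) &&
        !is.na(r$answer_num) && !is.na(r$answer_den)
      if (!has_pair) {
        problems <- c(problems,
                      sprintf("row %d: frequency query without answer_num/answer_den", i))
      }
    }
  }
  if (length(problems)) {
    stop("answer log validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  fixations <- NULL
  if (!is.null(fixation_csv)) {
    fixations <- utils::read.csv(fixation_csv, stringsAsFactors = FALSE)
    freq <- c("participant_id", "context_id", "trial_index", "query_code",
              "format", "t_start_ms", "duration_ms", "x_px", "y_px")
    missing <- setdiff(freq, names(fixations))
    if (length(missing)) {
      stop("fixation log is missing columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(answers = answers, fixations = fixations, truth = NULL,
                 scenarios = scenarios, config = NULL, seed = NULL),
            class = "bg_dataset")
}

fnv1a_hash <- function(x) {
  # tiny stable config fingerprint for the report manifest (31-bit
  # polynomial hash; collisions are harmless here)
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis report
#'
#' Classifies every answered trial, then assembles the descriptive tables:
#' solution rates by (visualization, format, inference class), the Bayesian
#' error tally, AOI indicator tables per distinct (query, visualization,
#' format), and heat maps per query stratified by classification outcome
#' (correct vs each major error). Deterministic given identical inputs.
#'
#' @param ds a `bg_dataset` from [simulate_experiment()] or [load_dataset()].
#' @param cfg a [classifier_config()].
#' @param heatmaps compute stratified heat maps (needs fixation logs).
#' @param grid_step,sigma heat-map resolution (coarser than the
#'   [gaze_heatmap()] defaults to keep full-cohort reports quick).
#' @return an object of class `bg_report`: list with `classified`,
#'   `solution_rates`, `error_tally`, `aoi_tables`, `heatmaps`, `meta`.
#' @export
run_report <- function(ds, cfg = classifier_config(), heatmaps = TRUE,
                       grid_step = 16, sigma = 30) {
  stopifnot(inherits(ds, "bg_dataset"))
  if (is.null(ds$answers) || !nrow(ds$answers)) {
    stop("empty dataset", call. = FALSE)
  }
  classified <- classify_answers(ds$answers, ds$scenarios, cfg)
  strata <- unique(classified[c("visualization", "format", "inference_class")])
  solution_rates <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    st <- strata[i, ]
    sub <- classified[classified$visualization == st$visualization &
                        classified$format == st$format &
                        classified$inference_class == st$inference_class, ]
    data.frame(st, n = nrow(sub), n_correct = sum(sub$correct),
               solution_rate = mean(sub$correct), row.names = NULL)
  }))
  tally <- tally_errors(classified)
  aoi_tables <- list()
  hm <- list()
  if (!is.null(ds$fixations) && nrow(ds$fixations)) {
    fx <- ds$fixations
    keys <- unique(classified[c("query_code", "visualization", "format")])
    for (i in seq_len(nrow(keys))) {
      k <- keys[i, ]
      lay <- build_layout(k$visualization, k$format)
      sel <- fx$query_code == k$query_code & fx$visualization == k$visualization &
        fx$format == k$format
      sub <- fx[sel, , drop = FALSE]
      if (!nrow(sub)) next
      trials <- split(data.frame(t_start = sub$t_start_ms,
                                 duration = sub$duration_ms,
                                 x = sub$x_px, y = sub$y_px),
                      sub$participant_id)
      key <- sprintf("%s|%s|%s", k$query_code, k$visualization, k$format)
      aoi_tables[[key]] <- aoi_indicators(trials, lay)
      if (heatmaps) {
        cls <- classified[classified$query_code == k$query_code &
                            classified$visualization == k$visualization &
                            classified$format == k$format, ]
        cls$stratum <- ifelse(cls$correct, "correct", cls$assigned)
        hm_strata <- list()
        for (st in unique(cls$stratum)) {
          pids <- cls$participant_id[cls$stratum == st]
          stf <- sub[sub$participant_id %in% pids, , drop = FALSE]
          hm_strata[[st]] <- gaze_heatmap(
            data.frame(x = stf$x_px, y = stf$y_px, duration = stf$duration_ms),
            lay$canvas, grid_step = grid_step, sigma = sigma)
          attr(hm_strata[[st]], "n_trials") <- length(pids)
        }
        hm[[key]] <- hm_strata
      }
    }
  }
  structure(
    list(classified = classified, solution_rates = solution_rates,
         error_tally = tally, aoi_tables = aoi_tables, heatmaps = hm,
         meta = list(
           n_trials = nrow(classified),
           seed = ds$seed,
           config_hash = fnv1a_hash(list(ds$config, cfg)),
           package_version = as.character(utils::packageVersion("bayesgaze")))),
    class = "bg_report")
}

#' @export
print.bg_report <- function(x, ...) {
  cat(sprintf("<report> %d trials, %d errors on Bayesian items\n",
              x$meta$n_trials, x$error_tally$n_errors))
  cat("\nSolution rates:\n")
  sr <- x$solution_rates
  sr$solution_rate <- sprintf("%.1f%%", 100 * sr$solution_rate)
  print(sr, row.names = FALSE)
  cat("\n")
  print(x$error_tally)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Diffable artifacts: CSV tables (`classified.csv`, `solution_rates.csv`,
#' `error_tally.csv`, `aoi_<key>.csv`), heat maps as CSV matrices and plain
#' PGM images, and a JSON manifest with the run metadata.
#'
#' @param report a `bg_report`.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "bg_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$classified, file.path(dir, "classified.csv"),
                   row.names = FALSE)
  utils::write.csv(report$solution_rates, file.path(dir, "solution_rates.csv"),
                   row.names = FALSE)
  utils::write.csv(report$error_tally$counts, file.path(dir, "error_tally.csv"),
                   row.names = FALSE)
  utils::write.csv(report$error_tally$summary,
                   file.path(dir, "error_tally_summary.csv"), row.names = FALSE)
  safe <- function(key) gsub("[^A-Za-z0-9]+", "_", key)
  for (key in names(report$aoi_tables)) {
    utils::write.csv(as.data.frame(report$aoi_tables[[key]]),
                     file.path(dir, sprintf("aoi_%s.csv", safe(key))),
                     row.names = FALSE)
  }
  for (key in names(report$heatmaps)) {
    for (st in names(report$heatmaps[[key]])) {
      base <- sprintf("heatmap_%s_%s", safe(key), safe(st))
      write_heatmap_csv(report$heatmaps[[key]][[st]],
                        file.path(dir, paste0(base, ".csv")))
      write_heatmap_pgm(report$heatmaps[[key]][[st]],
                        file.path(dir, paste0(base, ".pgm")))
    }
  }
  jsonlite::write_json(report$meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
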