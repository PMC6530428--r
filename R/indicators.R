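#' A recorded trial
#'
#' One participant answering one query while their fixations were recorded.
#' Fixations must be time-ordered and non-overlapping, and fit inside the
#' trial time limit.
#'
#' @param participant_id identifier.
#' @param query an [inference_query()].
#' @param visualization `"tree"` or `"table"`.
#' @param fixations data.frame with `t_start` (ms from trial onset),
#'   `duration` (ms, > 0), `x`, `y` (px).
#' @param answer a `bg_answer` or `NULL`.
#' @param time_limit_ms trial cap (default 30,000 ms).
#' @return an object of class `bg_trial`.
#' @export
trial <- function(participant_id, query, visualization, fixations,
                  answer = NULL, time_limit_ms = 30000) {
  stopifnot(is.data.frame(fixations),
            all(c("t_start", "duration", "x", "y") %in% names(fixations)))
  if (nrow(fixations)) {
    stopifnot(all(fixations$duration > 0))
    if (is.unsorted(fixations$t_start)) {
      stop("fixations must be sorted by t_start", call. = FALSE)
    }
    ends <- fixations$t_start + fixations$duration
    if (any(ends > time_limit_ms + 1e-9)) {
      stop("fixations exceed the trial time limit", call. = FALSE)
    }
    if (nrow(fixations) > 1 &&
        any(fixations$t_start[-1] < ends[-length(ends)] - 1e-9)) {
      stop("fixations overlap in time", call. = FALSE)
    }
  }
  structure(list(participant_id = participant_id, query = query,
                 visualization = visualization, fixations = fixations,
                 answer = answer, time_limit_ms = time_limit_ms),
            class = "bg_trial")
}

#' AOI performance indicators
#'
#' The per-AOI descriptives used to summarize scanning behavior over a set
#' of trials that share one layout and query:
#'
#' * `order_in_sequence` — mean over trials of the rank of the AOI's first
#'   visit in the collapsed scan path (trials that never visit it are
#'   excluded; an AOI never visited at all is reported as `NA`).
#' * `dwell_time_s` — summed fixation durations in seconds.
#' * `dwell_time_pct` — dwell time as a share of all fixation time pooled
#'   over trials (per-trial averaging available via `per_trial = TRUE`);
#'   AOI shares plus whitespace sum to 100.
#' * `fixation_count` — number of fixations.
#' * `hit_ratio` — fraction of trials with at least one fixation in the AOI.
#'
#' @param trials list of [trial()] objects (or of labeled fixation
#'   data.frames) sharing `layout`.
#' @param layout a [build_layout()] result.
#' @param per_trial compute dwell percentages per trial, then average,
#'   instead of pooling (default FALSE).
#' @return data.frame (class `bg_aoi_indicators`) with one row per AOI plus
#'   a whitespace row.
#' @export
aoi_indicators <- function(trials, layout, per_trial = FALSE) {
  stopifnot(inherits(layout, "bg_aoi_layout"))
  if (!length(trials)) stop("aoi_indicators() needs at least one trial",
                            call. = FALSE)
  labeled <- lapply(trials, function(tr) {
    fx <- if (inherits(tr, "bg_trial")) tr$fixations else tr
    assign_fixations(fx, layout)
  })
  ids <- c(layout$aois$aoi_id, "whitespace")
  total_time <- sum(vapply(labeled, function(fx) sum(fx$duration), numeric(1)))
  ranks <- lapply(labeled, function(fx) {
    sp <- scanpath(fx$aoi)
    match(ids, sp)
  })
  rank_mat <- do.call(cbind, ranks)
  out <- do.call(rbind, lapply(seq_along(ids), function(i) {
    id <- ids[i]
    dwell <- vapply(labeled, function(fx) sum(fx$duration[fx$aoi == id]),
                    numeric(1))
    count <- vapply(labeled, function(fx) sum(fx$aoi == id), numeric(1))
    pct <- if (per_trial) {
      tt <- vapply(labeled, function(fx) sum(fx$duration), numeric(1))
      mean(ifelse(tt > 0, 100 * dwell / tt, 0))
    } else {
      if (total_time > 0) 100 * sum(dwell) / total_time else 0
    }
    rk <- rank_mat[i, ]
    data.frame(aoi_id = id,
               order_in_sequence = if (all(is.na(rk))) NA_real_
                                   else mean(rk, na.rm = TRUE),
               dwell_time_s = sum(dwell) / 1000,
               dwell_time_pct = pct,
               fixation_count = as.integer(sum(count)),
               hit_ratio = mean(count > 0))
  }))
  rownames(out) <- NULL
  class(out) <- c("bg_aoi_indicators", "data.frame")
  attr(out, "n_trials") <- length(trials)
  out
}

#' @export
print.bg_aoi_indicators <- function(x, digits = 3, ...) {
  cat(sprintf("<AOI indicators> %d trials\n", attr(x, "n_trials")))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
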