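#' Screen canvas specification
#'
#' @param width,height canvas size in pixels. Defaults match the study
#'   display (1280 x 1024). Origin is top-left, y increases downward.
#' @return an object of class `bg_canvas`.
#' @export
canvas_spec <- function(width = 1280, height = 1024) {
  stopifnot(width > 0, height > 0)
  structure(list(width = width, height = height), class = "bg_canvas")
}

# rectangle helper: half-open [x0, x1) x [y0, y1)
rect_row <- function(aoi_id, role, cx, cy, w, h, symbol) {
  data.frame(aoi_id = aoi_id, role = role,
             x0 = cx - w / 2, y0 = cy - h / 2,
             x1 = cx + w / 2, y1 = cy + h / 2,
             symbol = symbol, stringsAsFactors = FALSE)
}

#' AOI layouts for the four stimulus variants
#'
#' Builds the parametric AOI partition of one stimulus screen. Published
#' semantics live in the symbol map (which AOI carries which quantity
#' symbol); the pixel geometry itself is a documented package default, as
#' the original stimuli's exact geometry is not available.
#'
#' * tree + frequency: 7 equal-sized node AOIs (symbols A-G, counts in the
#'   nodes) + 1 bigger question AOI = 8 AOIs.
#' * tree + probability: 7 equal-sized node-plus-branch AOIs (the branch
#'   segment carries the probability; symbols root, b-g) + question = 8.
#' * table (either format): 4 inner cells + 4 event-label cells + 2
#'   marginal cells + 1 total cell = 11 equal-sized AOIs + question = 12.
#'   Cell symbols are D/E/F/G (frequency) or h/i/j/k (probability); margins
#'   B/C or b/c; total A (frequency) or the unit total (probability).
#'
#' Whitespace is the complement of all AOIs, never an explicit rectangle.
#' All rectangles are half-open `[x0, x1) x [y0, y1)` so every pixel has a
#' unique owner.
#'
#' @param visualization `"tree"` or `"table"`.
#' @param format `"probability"` or `"natural_frequency"`.
#' @param canvas a [canvas_spec()].
#' @return an object of class `bg_aoi_layout` with fields `visualization`,
#'   `format`, `canvas`, `aois` (data.frame aoi_id, role, x0, y0, x1, y1,
#'   symbol) and `question_id`.
#' @examples
#' nrow(build_layout("tree", "natural_frequency")$aois)   # 8
#' nrow(build_layout("table", "probability")$aois)        # 12
#' @export
build_layout <- function(visualization = c("tree", "table"),
                         format = c("probability", "natural_frequency"),
                         canvas = canvas_spec()) {
  visualization <- match.arg(visualization)
  format <- match.arg(format)
  stopifnot(inherits(canvas, "bg_canvas"))
  sx <- canvas$width / 1280
  sy <- canvas$height / 1024
  question <- data.frame(aoi_id = "question", role = "question",
                         x0 = 40 * sx, y0 = 20 * sy,
                         x1 = 1240 * sx, y1 = 140 * sy,
                         symbol = "question", stringsAsFactors = FALSE)
  if (visualization == "tree") {
    freq <- format == "natural_frequency"
    role <- if (freq) "node" else "node_plus_branch"
    w <- (if (freq) 180 else 200) * sx
    h <- (if (freq) 90 else 130) * sy
    # node_plus_branch AOIs extend upward to take in the branch segment
    dy <- if (freq) 0 else 20 * sy
    centers <- list(
      root = c(640, 260), nA = c(320, 500), nnA = c(960, 500),
      l11 = c(160, 740), l10 = c(480, 740), l01 = c(800, 740),
      l00 = c(1120, 740))
    syms <- if (freq) c("A", "B", "C", "D", "E", "F", "G")
            else c("root", "b", "c", "d", "e", "f", "g")
    rows <- Map(function(ctr, sym) {
      rect_row(sym, role, ctr[1] * sx, ctr[2] * sy - dy, w, h, sym)
    }, centers, syms)
    aois <- rbind(question, do.call(rbind, rows))
  } else {
    freq <- format == "natural_frequency"
    cellsym <- if (freq) c("D", "F", "E", "G") else c("h", "j", "i", "k")
    marsym <- if (freq) c("B", "C", "A") else c("b", "c", "total")
    w <- 170 * sx; h <- 90 * sy
    colx <- c(lab = 325, A = 515, nA = 705) * sx
    rowy <- c(lab = 345, B = 455, nB = 565, mar = 675) * sy
    aois <- rbind(
      question,
      rect_row("label_A",  "event_label_cell", colx["A"],  rowy["lab"], w, h, "label_A"),
      rect_row("label_nA", "event_label_cell", colx["nA"], rowy["lab"], w, h, "label_nA"),
      rect_row("label_B",  "event_label_cell", colx["lab"], rowy["B"],  w, h, "label_B"),
      rect_row("label_nB", "event_label_cell", colx["lab"], rowy["nB"], w, h, "label_nB"),
      rect_row(cellsym[1], "cell", colx["A"],  rowy["B"],  w, h, cellsym[1]),
      rect_row(cellsym[2], "cell", colx["nA"], rowy["B"],  w, h, cellsym[2]),
      rect_row(cellsym[3], "cell", colx["A"],  rowy["nB"], w, h, cellsym[3]),
      rect_row(cellsym[4], "cell", colx["nA"], rowy["nB"], w, h, cellsym[4]),
      rect_row(marsym[1], "marginal_cell", colx["A"],  rowy["mar"], w, h, marsym[1]),
      rect_row(marsym[2], "marginal_cell", colx["nA"], rowy["mar"], w, h, marsym[2]),
      rect_row(marsym[3], "marginal_cell", colx["lab"], rowy["mar"], w, h, marsym[3]))
  }
  rownames(aois) <- NULL
  structure(list(visualization = visualization, format = format,
                 canvas = canvas, aois = aois, question_id = "question"),
            class = "bg_aoi_layout")
}

#' @export
print.bg_aoi_layout <- function(x, ...) {
  cat(sprintf("<AOI layout> %s / %s: %d AOIs + whitespace\n",
              x$visualization, x$format, nrow(x$aois)))
  print(x$aois, row.names = FALSE)
  invisible(x)
}

#' Export a layout as JSON
#'
#' @param layout a [build_layout()] result.
#' @param path output file.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(
    list(visualization = layout$visualization, format = layout$format,
         canvas = unclass(layout$canvas), aois = layout$aois),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- formula symbols --------------------------------------------------------

# symbols (AOI ids) read by the correct strategy for `query` on `layout`;
# generalizes to any cataloged strategy for Bayesian queries so the gaze
# simulator can condition fixation targets on the latent strategy
formula_symbols <- function(strat, query, layout) {
  if (is.character(strat)) strat <- strategy(strat)
  q <- query$quantity
  freq <- layout$format == "natural_frequency"
  tree <- layout$visualization == "tree"
  # symbol lookups by event pattern
  cellsym <- function(a_pos, b_pos) {
    if (freq) c("D", "E", "F", "G")[2 - b_pos + 2 * (1 - a_pos)]
    else if (tree) NA_character_
    else c("h", "i", "j", "k")[2 - b_pos + 2 * (1 - a_pos)]
  }
  marsym_a <- function(pos) {
    if (freq) { if (pos) "B" else "C" } else { if (pos) "b" else "c" }
  }
  totalsym <- if (freq) "A" else if (tree) "root" else "total"
  branch_cond <- function(a_pos, b_pos) {  # tree-probability branch d/e/f/g
    c("d", "e", "f", "g")[2 - b_pos + 2 * (1 - a_pos)]
  }
  # correct-strategy symbol sets by inference class
  marginal_syms <- function(qq) {
    if (!is.na(qq$a_pos)) {
      if (freq) c(marsym_a(qq$a_pos), totalsym) else marsym_a(qq$a_pos)
    } else {
      if (freq) c(cellsym(TRUE, qq$b_pos), cellsym(FALSE, qq$b_pos), totalsym)
      else if (tree) c("b", branch_cond(TRUE, qq$b_pos),
                       "c", branch_cond(FALSE, qq$b_pos))
      else c(cellsym(TRUE, qq$b_pos), cellsym(FALSE, qq$b_pos))
    }
  }
  correct_syms <- function(qq) {
    switch(qq$kind,
      marginal = marginal_syms(qq),
      conjoint = {
        if (freq) c(cellsym(qq$a_pos, qq$b_pos), totalsym)
        else if (tree) c(marsym_a(qq$a_pos), branch_cond(qq$a_pos, qq$b_pos))
        else cellsym(qq$a_pos, qq$b_pos)
      },
      conditional = {
        if (qq$inference_class == "conditional") {
          if (freq) c(cellsym(qq$a_pos, qq$b_pos), marsym_a(qq$a_pos))
          else if (tree) branch_cond(qq$a_pos, qq$b_pos)
          else c(cellsym(qq$a_pos, qq$b_pos), marsym_a(qq$a_pos))
        } else {  # bayesian: cell(X,Y) vs cell(notX,Y)
          if (tree && !freq) c("b", branch_cond(TRUE, qq$b_pos),
                               "c", branch_cond(FALSE, qq$b_pos))
          else c(cellsym(qq$a_pos, qq$b_pos), cellsym(!qq$a_pos, qq$b_pos))
        }
      })
  }
  if (strat$name == "correct") return(unique(correct_syms(q)))
  if (strat$name == "quantity_confusion") {
    return(unique(correct_syms(parse_quantity(strat$quantity))))
  }
  if (strat$name == "complement_misread") {
    mis <- inference_query(complement_code(query$code, strat$misread),
                           query$format, query$context_id)
    return(formula_symbols(strat$wrapped, mis, layout))
  }
  if (q$inference_class != "bayesian") {
    stop("strategy ", strat$name, " has no formula for a non-Bayesian query")
  }
  tx <- q$a_pos; cy <- q$b_pos
  syms <- switch(strat$name,
    joint_occurrence = {
      if (freq) c(cellsym(tx, cy), totalsym)
      else if (tree) c(marsym_a(tx), branch_cond(tx, cy))
      else cellsym(tx, cy)
    },
    fisherian = {
      if (tree && !freq) branch_cond(tx, cy)
      else c(cellsym(tx, cy), marsym_a(tx))
    },
    likelihood_subtraction = ,
    likelihood_addition = ,
    cpr_fpr_ratio = {
      if (tree && !freq) c(branch_cond(tx, cy), branch_cond(!tx, cy))
      else c(cellsym(tx, cy), marsym_a(tx), cellsym(!tx, cy), marsym_a(!tx))
    },
    base_rate_only = {
      if (freq) c(marsym_a(tx), totalsym) else marsym_a(tx)
    },
    evidence_only = {
      if (tree && !freq) c("b", branch_cond(TRUE, cy), "c", branch_cond(FALSE, cy))
      else if (freq) c(cellsym(TRUE, cy), cellsym(FALSE, cy), totalsym)
      else c(cellsym(TRUE, cy), cellsym(FALSE, cy))
    },
    pre_bayes = c(marsym_a(tx), cellsym(tx, cy), cellsym(!tx, cy)))
  unique(syms)
}

#' AOIs relevant to answering a query correctly
#'
#' The AOIs whose symbols appear in the correct strategy's formula for the
#' query, including the reference-set symbol for frequency answers.
#'
#' @param query an [inference_query()]; its format must match the layout's.
#' @param layout a [build_layout()] result.
#' @return character vector of AOI ids.
#' @examples
#' lay <- build_layout("tree", "natural_frequency")
#' relevant_aois(inference_query("P(notB)", "natural_frequency"), lay)
#' # "E" "G" "A"
#' @export
relevant_aois <- function(query, layout) {
  stopifnot(inherits(query, "bg_query"), inherits(layout, "bg_aoi_layout"))
  syms <- formula_symbols("correct", query, layout)
  missing <- setdiff(syms, layout$aois$symbol)
  if (length(missing)) {
    stop("symbols not mapped in layout: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  layout$aois$aoi_id[match(syms, layout$aois$symbol)]
}

# --- fixation assignment and scan paths -------------------------------------

#' Assign fixations to AOIs
#'
#' Point-in-rectangle assignment on half-open rectangles; fixations outside
#' every AOI (including out-of-canvas points) are labeled `"whitespace"`.
#'
#' @param fixations data.frame with columns `x`, `y` (pixels; also accepts
#'   `x_px`/`y_px`).
#' @param layout a [build_layout()] result.
#' @return the input with an `aoi` column appended.
#' @export
assign_fixations <- function(fixations, layout) {
  stopifnot(is.data.frame(fixations), inherits(layout, "bg_aoi_layout"))
  x <- fixations$x %||% fixations$x_px
  y <- fixations$y %||% fixations$y_px
  if (is.null(x) || is.null(y)) stop("fixations need x/y (or x_px/y_px) columns")
  a <- layout$aois
  aoi <- rep("whitespace", length(x))
  for (i in seq_len(nrow(a))) {
    inside <- x >= a$x0[i] & x < a$x1[i] & y >= a$y0[i] & y < a$y1[i]
    aoi[inside] <- a$aoi_id[i]
  }
  fixations$aoi <- aoi
  fixations
}

#' Collapse labeled fixations into a scan path
#'
#' Consecutive fixations on the same AOI collapse into one visit;
#' whitespace is retained as an explicit token.
#'
#' @param labels character vector of AOI labels in time order (or a labeled
#'   fixation data.frame from [assign_fixations()]).
#' @return character vector of visited AOI ids.
#' @examples
#' scanpath(c("question", "question", "A", "A", "B"))  # question A B
#' @export
scanpath <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$aoi
  if (!length(labels)) return(character(0))
  labels[c(TRUE, labels[-1] != labels[-length(labels)])]
}
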