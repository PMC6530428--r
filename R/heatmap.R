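#' Duration-weighted fixation heat map
#'
#' Aggregates fixations (optionally across participants) into an intensity
#' grid over the canvas: each fixation deposits a 2-D Gaussian kernel
#' centered at its position, weighted by its duration. The kernel is
#' normalized on the grid, so the unnormalized grid's total mass equals the
#' summed fixation durations exactly — grids are therefore additive across
#' participants and strata.
#'
#' @param fixations data.frame with `x`, `y` (or `x_px`/`y_px`) and
#'   `duration` (ms) columns; zero rows give an all-zero grid.
#' @param canvas a [canvas_spec()].
#' @param grid_step grid cell edge in pixels (default 4).
#' @param sigma Gaussian kernel standard deviation in pixels (default 30).
#' @param normalize scale the grid to maximum 1 (default FALSE).
#' @return an object of class `bg_heatmap`: a list with `grid` (matrix,
#'   rows = y, cols = x), `grid_step`, `sigma`, `canvas`, `normalized`,
#'   `total_mass`.
#' @examples
#' hm <- gaze_heatmap(data.frame(x = 640, y = 512, duration = 200))
#' hm$total_mass   # 200
#' @export
gaze_heatmap <- function(fixations, canvas = canvas_spec(), grid_step = 4,
                         sigma = 30, normalize = FALSE) {
  stopifnot(sigma > 0, grid_step >= 1)
  nx <- ceiling(canvas$width / grid_step)
  ny <- ceiling(canvas$height / grid_step)
  gx <- (seq_len(nx) - 0.5) * grid_step
  gy <- (seq_len(ny) - 0.5) * grid_step
  grid <- matrix(0, nrow = ny, ncol = nx)
  x <- fixations$x %||% fixations$x_px
  y <- fixations$y %||% fixations$y_px
  dur <- fixations$duration %||% fixations$duration_ms
  for (i in seq_len(nrow(fixations))) {
    kx <- stats::dnorm(gx, x[i], sigma)
    ky <- stats::dnorm(gy, y[i], sigma)
    dep <- outer(ky, kx)
    ssum <- sum(dep)
    if (ssum > 0) grid <- grid + dep * (dur[i] / ssum)
  }
  total <- sum(grid)
  if (normalize && max(grid) > 0) grid <- grid / max(grid)
  structure(list(grid = grid, grid_step = grid_step, sigma = sigma,
                 canvas = canvas, normalized = normalize,
                 total_mass = total),
            class = "bg_heatmap")
}

#' @export
print.bg_heatmap <- function(x, ...) {
  cat(sprintf("<heat map> %d x %d grid (step %d px, sigma %g px), mass %.1f%s\n",
              nrow(x$grid), ncol(x$grid), x$grid_step, x$sigma, x$total_mass,
              if (x$normalized) " (max-normalized)" else ""))
  invisible(x)
}

#' @param x a `bg_heatmap`.
#' @param ... passed to [graphics::image()].
#' @rdname gaze_heatmap
#' @export
plot.bg_heatmap <- function(x, ...) {
  # flip so the plot matches screen coordinates (origin top-left)
  g <- t(x$grid[rev(seq_len(nrow(x$grid))), , drop = FALSE])
  graphics::image(
    x = (seq_len(nrow(g)) - 0.5) * x$grid_step,
    y = (seq_len(ncol(g)) - 0.5) * x$grid_step,
    z = g, col = grDevices::hcl.colors(64, "inferno"),
    xlab = "x (px)", ylab = "y (px, bottom-up)", useRaster = TRUE, ...)
  invisible(x)
}

#' Heat-map exports
#'
#' `write_heatmap_csv()` writes the intensity matrix as a plain CSV (rows =
#' grid rows, top of screen first). `write_heatmap_pgm()` writes a plain
#' (P2, ASCII) grayscale PGM image scaled to 0-255.
#'
#' @param hm a `bg_heatmap`.
#' @param path output file.
#' @export
write_heatmap_csv <- function(hm, path) {
  utils::write.table(hm$grid, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_heatmap_csv
#' @export
write_heatmap_pgm <- function(hm, path) {
  g <- hm$grid
  mx <- max(g)
  lev <- if (mx > 0) round(255 * g / mx) else g
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(g), nrow(g)), "255"), con)
  apply(lev, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}
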