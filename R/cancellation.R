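#' Cancellation sheet
#'
#' Geometry of a paper-and-pencil cancellation task: target positions among
#' distractors on a sheet, in sheet millimeters with the origin at the
#' bottom-left corner. The standard layout has 40 targets among 240
#' distractors.
#'
#' @param targets Data.frame or matrix with columns/cols `x`, `y` (mm).
#' @param distractors Same layout; may have zero rows.
#' @param width,height Sheet dimensions in mm.
#' @return An object of class `cancellation_sheet`.
#' @seealso [default_sheet()], [coc()]
#' @export
cancellation_sheet <- function(targets, distractors, width, height) {
  as_xy <- function(m, nm) {
    m <- as.data.frame(m)
    if (!all(c("x", "y") %in% names(m))) {
      if (ncol(m) >= 2L) names(m)[1:2] <- c("x", "y")
      else stop(nm, " must have x and y columns", call. = FALSE)
    }
    m[, c("x", "y")]
  }
  targets <- as_xy(targets, "targets")
  distractors <- as_xy(distractors, "distractors")
  if (width <= 0 || height <= 0) {
    stop("sheet dimensions must be positive", call. = FALSE)
  }
  inb <- function(m) all(m$x >= 0 & m$x <= width & m$y >= 0 & m$y <= height)
  if (!inb(targets) || !inb(distractors)) {
    stop("all positions must lie within the sheet bounds", call. = FALSE)
  }
  if (nrow(targets) < 1L) stop("sheet needs at least one target",
                               call. = FALSE)
  structure(list(targets = targets, distractors = distractors,
                 width = width, height = height),
            class = "cancellation_sheet")
}

#' @export
print.cancellation_sheet <- function(x, ...) {
  cat(sprintf("<cancellation_sheet> %d targets, %d distractors, %g x %g mm\n",
              nrow(x$targets), nrow(x$distractors), x$width, x$height))
  invisible(x)
}

#' Default synthetic cancellation sheet
#'
#' A synthetic stand-in for a 40-target / 240-distractor cancellation
#' sheet: targets on a regular 8-column x 5-row grid, distractors filling
#' the remaining cells of a 24-column x 10-row layout mirrored left-right
#' about the sheet center (A4 landscape, 297 x 210 mm). Its published
#' counterpart's exact geometry is not reproduced; only the counts and the
#' left-right symmetry matter for the statistic.
#'
#' @return A [cancellation_sheet()].
#' @export
default_sheet <- function() {
  width <- 297; height <- 210
  ncol_all <- 24L; nrow_all <- 10L
  xs <- width * (seq_len(ncol_all) - 0.5) / ncol_all
  # 240 distractors: the full 24 x 10 grid of cell centers
  dist_grid <- expand.grid(col = seq_len(ncol_all), row = seq_len(nrow_all))
  distr <- data.frame(x = xs[dist_grid$col],
                      y = height * (dist_grid$row - 0.5) / nrow_all)
  # 40 targets: every 3rd column (8 columns, symmetric about the center)
  # on 5 rows interleaved between the distractor rows
  tcols <- seq(2L, 23L, by = 3L)
  trows <- c(1L, 3L, 5L, 7L, 9L)
  tgt_grid <- expand.grid(col = tcols, row = trows)
  targets <- data.frame(x = xs[tgt_grid$col],
                        y = height * tgt_grid$row / nrow_all)
  cancellation_sheet(targets, distr, width, height)
}

# Normalized horizontal coordinate of each target: sheet center -> 0,
# leftmost target column -> -1, rightmost -> +1, linear (piecewise about
# the center so asymmetric sheets still map onto [-1, 1]).
normalized_target_x <- function(sheet) {
  x <- sheet$targets$x
  cx <- sheet$width / 2
  dev <- x - cx
  left_span <- cx - min(x)
  right_span <- max(x) - cx
  xt <- numeric(length(x))
  neg <- dev < 0
  xt[neg] <- if (left_span > 0) dev[neg] / left_span else 0
  xt[!neg] <- if (right_span > 0) dev[!neg] / right_span else 0
  xt
}

#' Center of Cancellation
#'
#' The CoC summarises the spatial distribution of the marked targets on a
#' cancellation sheet as the mean normalized horizontal deviation from the
#' sheet center, in `[-1, 1]`: 0 means no lateral bias, positive values a
#' rightward shift of the marks (left-sided omissions). A CoC at or above
#' 0.081 is classified as significant left-sided neglect. Each target's
#' normalized coordinate is linear in its horizontal position with the
#' sheet center at 0 and the extreme target columns at -1 and +1; the raw
#' (millimeter) mean deviation is returned alongside.
#'
#' @param sheet A [cancellation_sheet()].
#' @param marks Integer indices of the marked targets (>= 1 mark).
#' @return List of class `coc_result`: `coc`, `n_marked`,
#'   `significant_left_neglect` (`coc >= 0.081`), `raw_mean_deviation_mm`.
#' @examples
#' sh <- default_sheet()
#' coc(sh, seq_len(40))$coc # 0 on the symmetric default sheet
#' @export
coc <- function(sheet, marks) {
  stopifnot(inherits(sheet, "cancellation_sheet"))
  marks <- as.integer(marks)
  if (length(marks) == 0L) {
    stop("CoC is undefined for an empty mark set (0 would mean 'no bias',",
         " not 'no data')", call. = FALSE)
  }
  if (anyDuplicated(marks) || any(is.na(marks)) || any(marks < 1L) ||
      any(marks > nrow(sheet$targets))) {
    stop("marks must be unique valid target indices", call. = FALSE)
  }
  xt <- normalized_target_x(sheet)
  value <- mean(xt[marks])
  structure(
    list(coc = value, n_marked = length(marks),
         significant_left_neglect = value >= 0.081,
         raw_mean_deviation_mm =
           mean(sheet$targets$x[marks]) - sheet$width / 2),
    class = "coc_result"
  )
}

#' @export
print.coc_result <- function(x, ...) {
  cat(sprintf("<coc_result> CoC %.3f (%d marks)%s\n", x$coc, x$n_marked,
              if (x$significant_left_neglect)
                " - significant left-sided neglect" else ""))
  invisible(x)
}

#' Simulate a cancellation performance for a biased patient
#'
#' Links the simulator's lateral-bias parameter to cancellation behaviour:
#' a target at normalized horizontal coordinate `x` is marked with
#' probability `1 - lambda * (1 - x) / 2`, clamped to `[0, 1]` — leftward
#' targets are increasingly omitted as `lambda` grows, while the rightmost
#' column is always marked. If every draw fails, the rightmost target is
#' forced so the mark set is never empty.
#'
#' @param lambda Lateral bias in `[0, 1]`.
#' @param sheet A [cancellation_sheet()] (default [default_sheet()]).
#' @return Integer vector of marked target indices.
#' @export
simulate_cancellation <- function(lambda, sheet = default_sheet()) {
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(inherits(sheet, "cancellation_sheet"))
  xt <- normalized_target_x(sheet)
  p <- pmin(pmax(1 - lambda * (1 - xt) / 2, 0), 1)
  marked <- which(stats::runif(length(p)) < p)
  if (length(marked) == 0L) marked <- which.max(xt)
  marked
}
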