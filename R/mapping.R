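#' Retinotopic grid specification
#'
#' A regular 1-degree grid over retinotopic space with cell edges at integer
#' degrees.  Half-widths are rounded up to the next integer so the field
#' rectangle is always covered; samples falling outside the grid extent are
#' dropped (and tallied).
#'
#' @param half_x,half_y Grid half-extent in degrees (defaults 24 and 13.5,
#'   matching the stimulus field).
#' @param min_count Minimum samples for a cell to count as sampled
#'   (default 1).
#' @param flip_sign If `TRUE`, use `p - s` instead of the default `s - p`
#'   retinotopic convention (stimulus position relative to the fovea).
#' @return An object of class `grid_spec`.
#' @export
field_grid <- function(half_x = 24, half_y = 13.5, min_count = 1,
                       flip_sign = FALSE) {
  stopifnot(half_x > 0, half_y > 0, min_count >= 1)
  ex <- as.integer(ceiling(half_x))
  ey <- as.integer(ceiling(half_y))
  structure(list(ex = ex, ey = ey, nx = 2L * ex, ny = 2L * ey,
                 cell_size = 1, min_count = as.integer(min_count),
                 flip_sign = flip_sign,
                 x_centers = seq(-ex + 0.5, ex - 0.5, by = 1),
                 y_centers = seq(-ey + 0.5, ey - 0.5, by = 1)),
            class = "grid_spec")
}

.accumulate_cells <- function(rx, ry, flags, grid) {
  ix <- floor(rx) + grid$ex + 1
  iy <- floor(ry) + grid$ey + 1
  ok <- ix >= 1 & ix <= grid$nx & iy >= 1 & iy <= grid$ny &
    is.finite(rx) & is.finite(ry)
  dropped <- sum(!ok)
  idx <- (ix[ok] - 1L) * grid$ny + iy[ok]   # column-major, rows = y
  counts <- matrix(0, grid$ny, grid$nx)
  flagged <- matrix(0, grid$ny, grid$nx)
  tc <- tabulate(idx, nbins = grid$ny * grid$nx)
  counts[] <- tc
  f <- flags[ok]
  if (any(f == 1L)) {
    tf <- tabulate(idx[f == 1L], nbins = grid$ny * grid$nx)
    flagged[] <- tf
  }
  list(counts = counts, flagged = flagged, dropped = dropped)
}

.new_field_map <- function(counts, flagged, dropped, grid) {
  values <- flagged / counts
  values[counts < grid$min_count] <- NA_real_
  structure(list(values = values, counts = counts, flagged = flagged,
                 sampled_mask = counts >= grid$min_count,
                 dropped = dropped, grid = grid),
            class = "field_map")
}

#' Back-project binarized flags into a visual field map
#'
#' Each sample contributes its 0/1 flag to the grid cell containing its
#' retinotopic coordinate `(B_x, B_y) = (s_x - p_x, s_y - p_y)`; a cell's
#' value is the fraction of its samples flagged as loss.  Multiple records
#' accumulate into a single map.
#'
#' @param flags A `binary_series` or a list of them (one per record).
#' @param records A `tracking_record` or a list of them, aligned with
#'   `flags`.
#' @param grid A [field_grid()].
#' @return An object of class `field_map` with `values` (NA where
#'   unsampled), `counts`, `flagged`, `sampled_mask`, `dropped` and `grid`.
#' @export
backproject <- function(flags, records, grid = field_grid()) {
  stopifnot(inherits(grid, "grid_spec"))
  if (inherits(flags, "binary_series")) flags <- list(flags)
  if (inherits(records, "tracking_record")) records <- list(records)
  stopifnot(length(flags) == length(records))
  counts <- matrix(0, grid$ny, grid$nx)
  flagged <- matrix(0, grid$ny, grid$nx)
  dropped <- 0
  for (i in seq_along(records)) {
    rec <- records[[i]]
    fl <- flags[[i]]$flags
    if (length(fl) != length(rec$s_x)) {
      stop("flags and record are not aligned sample-for-sample",
           call. = FALSE)
    }
    sgn <- if (grid$flip_sign) -1 else 1
    rx <- sgn * (rec$s_x - rec$p_x)
    ry <- sgn * (rec$s_y - rec$p_y)
    acc <- .accumulate_cells(rx, ry, fl, grid)
    counts <- counts + acc$counts
    flagged <- flagged + acc$flagged
    dropped <- dropped + acc$dropped
  }
  .new_field_map(counts, flagged, dropped, grid)
}

#' Back-project sample subsets (internal support for decimated predictions)
#'
#' @param rx,ry Retinotopic coordinates of the retained samples.
#' @param flags 0/1 vector aligned with `rx`.
#' @param grid A [field_grid()].
#' @return A `field_map`.
#' @keywords internal
#' @export
backproject_samples <- function(rx, ry, flags, grid = field_grid()) {
  acc <- .accumulate_cells(rx, ry, as.integer(flags), grid)
  .new_field_map(acc$counts, acc$flagged, acc$dropped, grid)
}

#' Merge field maps cell-wise
#'
#' Adds per-cell counts, so pooling records before mapping equals merging
#' per-record maps.
#'
#' @param ... `field_map`s on the same grid.
#' @return A `field_map`.
#' @export
merge_maps <- function(...) {
  maps <- list(...)
  if (length(maps) == 1 && is.list(maps[[1]]) &&
      !inherits(maps[[1]], "field_map")) {
    maps <- maps[[1]]
  }
  stopifnot(length(maps) >= 1)
  grid <- maps[[1]]$grid
  counts <- Reduce(`+`, lapply(maps, `[[`, "counts"))
  flagged <- Reduce(`+`, lapply(maps, `[[`, "flagged"))
  dropped <- sum(vapply(maps, `[[`, numeric(1), "dropped"))
  .new_field_map(counts, flagged, dropped, grid)
}

#' Ground-truth visual field map
#'
#' Back-projects the a-priori occlusion flags of one or more records.  The
#' reconstruction step is still required (rather than drawing the defect
#' geometry directly) so that ground truth and reconstruction share the same
#' spatial sampling.
#'
#' @param records A `tracking_record` or list of them.
#' @param grid A [field_grid()].
#' @return A `field_map`.
#' @export
ground_truth_map <- function(records, grid = field_grid()) {
  if (inherits(records, "tracking_record")) records <- list(records)
  flags <- lapply(records, function(r) binary_series(r$occluded))
  backproject(flags, records, grid)
}

#' Coverage-corrected mean deviation
#'
#' `MD = sum(T over sampled cells) / n`, where `n` is the total number of
#' grid cells.  Equivalent to the mean over sampled cells scaled by the
#' fraction of the field covered, so incomplete coverage cannot inflate the
#' index.
#'
#' @param map A `field_map`.
#' @return A scalar in `[0, 1]`.
#' @export
mean_deviation <- function(map) {
  stopifnot(inherits(map, "field_map"))
  n <- length(map$values)
  if (n == 0) stop("empty grid", call. = FALSE)
  s <- map$values[map$sampled_mask]
  if (length(s) == 0) return(0)
  sum(s) / n
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf(
    "<field_map> %dx%d cells, %d sampled, %d samples (%d dropped), MD=%.4f\n",
    x$grid$ny, x$grid$nx, sum(x$sampled_mask), sum(x$counts), x$dropped,
    mean_deviation(x)))
  invisible(x)
}
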