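# Per-track motility statistics: mean speed, local displacement,
# exploration (distinct sites visited), and the per-cohort summary table.

# Euclidean step lengths between consecutive points of one track.
step_lengths <- function(tr) {
  xy <- as.matrix(tr[coord_cols(tr)])
  if (nrow(xy) < 2) return(numeric(0))
  sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
}

#' Track mean speed
#'
#' Total path length (sum of consecutive Euclidean displacements) divided
#' by total elapsed time (last minus first timepoint), in um/min — the
#' "track mean speed" convention of Imaris-style exports. Gaps contribute
#' their true elapsed time to the denominator.
#'
#' @param track a single-track data.frame (`t`, `x`, `y`, optionally `z`),
#'   e.g. one element of [split_tracks()].
#' @return Mean speed in um/min.
#' @export
track_mean_speed <- function(track) {
  if (nrow(track) < 2) {
    ivm_stop("ivm_track_too_short", "mean speed needs at least 2 points")
  }
  sum(step_lengths(track)) / (track$t[nrow(track)] - track$t[1])
}

#' Local displacement over a fixed time window
#'
#' For each point whose time `t` has a matching successor at `t + window`
#' (within half a frame interval, to survive small export jitter), the
#' Euclidean distance between the two positions. With
#' `window = frame_interval` this is exactly the per-step displacement
#' sequence; with `window` equal to the track duration it is the single
#' net start-to-end displacement.
#'
#' @inheritParams track_mean_speed
#' @param window window length, minutes (>= one frame interval).
#' @param frame_interval minutes between frames (sets the matching
#'   tolerance `frame_interval / 2`).
#' @return Numeric vector of displacements (um); empty if no pairs match.
#' @export
local_displacement <- function(track, window, frame_interval) {
  if (!is.numeric(window) || window < frame_interval) {
    ivm_stop("ivm_invalid_window", "window must be at least one frame interval")
  }
  tol <- frame_interval / 2
  xy <- as.matrix(track[coord_cols(track)])
  out <- numeric(0)
  for (i in seq_len(nrow(track))) {
    dtm <- abs(track$t - (track$t[i] + window))
    j <- which.min(dtm)
    if (length(j) == 1 && dtm[j] <= tol && j > i) {
      out <- c(out, sqrt(sum((xy[j, ] - xy[i, ])^2)))
    }
  }
  out
}

#' Distinct sites visited
#'
#' Counts the unique grid cells containing at least one track point, where
#' a point's cell is the tuple of `floor(coordinate / grid)` per axis
#' (half-open cells with origin at 0). A proxy for how much of the
#' surrounding tissue space a cell explores.
#'
#' @inheritParams track_mean_speed
#' @param grid cell edge length, um (> 0); default 10 um, roughly one cell
#'   diameter.
#' @return Integer count of occupied cells.
#' @export
distinct_sites_visited <- function(track, grid = 10) {
  if (!is.numeric(grid) || length(grid) != 1 || grid <= 0) {
    ivm_stop("ivm_invalid_grid", "grid must be a single positive number")
  }
  cells <- floor(as.matrix(track[coord_cols(track)]) / grid)
  nrow(unique(cells))
}

#' Per-track motility summary table
#'
#' One row per track: point count, duration, path length, mean speed, net
#' start-to-end displacement, straightness (net displacement / path length,
#' defined as 0 for zero-length paths) and distinct sites visited. Rows are
#' ordered by `track_id`, so the table is invariant to input track order.
#'
#' @param ts a [trackset] whose tracks all have >= 2 points.
#' @param grid grid size for [distinct_sites_visited()], um.
#' @param window optional [local_displacement()] window (minutes); when
#'   given, a `mean_local_displacement` column is added (NA for tracks
#'   shorter than the window).
#' @return data.frame with columns `track_id`, `n_points`, `duration`,
#'   `path_length`, `mean_speed`, `net_displacement`, `straightness`,
#'   `distinct_sites` (plus `mean_local_displacement` if `window` given).
#' @export
cohort_stats_table <- function(ts, grid = 10, window = NULL) {
  stopifnot(is_trackset(ts))
  dt <- frame_interval(ts)
  trs <- split_tracks(ts)
  trs <- trs[order(names(trs))]
  rows <- lapply(names(trs), function(id) {
    tr <- trs[[id]]
    if (nrow(tr) < 2) {
      ivm_stop("ivm_track_too_short",
               paste0("track '", id, "' has fewer than 2 points"))
    }
    steps <- step_lengths(tr)
    path <- sum(steps)
    xy <- as.matrix(tr[coord_cols(tr)])
    net <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
    row <- data.frame(track_id = id,
                      n_points = nrow(tr),
                      duration = tr$t[nrow(tr)] - tr$t[1],
                      path_length = path,
                      mean_speed = path / (tr$t[nrow(tr)] - tr$t[1]),
                      net_displacement = net,
                      straightness = if (path > 0) net / path else 0,
                      distinct_sites = distinct_sites_visited(tr, grid))
    if (!is.null(window)) {
      ld <- if (tr$t[nrow(tr)] - tr$t[1] >= window) {
        local_displacement(tr, window, dt)
      } else numeric(0)
      row$mean_local_displacement <- if (length(ld) > 0) mean(ld) else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
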