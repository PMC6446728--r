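# Readers/writers for track tables and cluster-intensity tables, plus the
# quality filter applied before any statistics.

#' Read a track table
#'
#' Parses a CSV of time-stamped cell positions into a [trackset]. Two
#' dialects are supported:
#'
#' * `"plain"`: header `track_id,t,x,y[,z]` with optional label columns
#'   `disease`, `stage`, `epoch`.
#' * `"imaris"`: an Imaris-style spots export — leading metadata lines are
#'   skipped until a header line containing `"Position X"` is found, and
#'   columns `Position X`/`Position Y`/`Position Z`, `Time` and `TrackID`
#'   are mapped to `x`/`y`/`z`, `t` and `track_id`.
#'
#' Units are declared, never converted: time must already be in minutes and
#' positions in micrometres (an Imaris export whose `Time` column is a frame
#' index must be converted by the caller first). Rows may appear in any
#' order; points are sorted by time within track. Duplicate
#' `(track_id, t)` rows raise `ivm_duplicate_timepoint` rather than being
#' deduplicated, since they signal a broken export.
#'
#' @param path CSV file path.
#' @param dialect `"plain"` or `"imaris"`.
#' @param frame_interval minutes between frames; inferred as the modal time
#'   step when `NULL`.
#' @param verbose log parse counts to standard error.
#' @return A [trackset].
#' @seealso [write_tracks()], [filter_tracks()]
#' @export
read_tracks <- function(path, dialect = c("plain", "imaris"),
                        frame_interval = NULL, verbose = TRUE) {
  dialect <- match.arg(dialect)
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    ivm_stop("ivm_missing_file", paste0("file not found: ", path))
  }
  if (dialect == "plain") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    h <- grep("Position X", lines, fixed = TRUE)
    if (length(h) == 0) {
      ivm_stop("ivm_missing_column",
               "imaris dialect: no header line containing 'Position X'")
    }
    df <- utils::read.csv(text = paste(lines[h[1]:length(lines)], collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = FALSE)
    map <- c("Position X" = "x", "Position Y" = "y", "Position Z" = "z",
             "Time" = "t", "TrackID" = "track_id")
    hit <- intersect(names(map), names(df))
    need <- c("Position X", "Position Y", "Time", "TrackID")
    miss <- setdiff(need, hit)
    if (length(miss) > 0) {
      ivm_stop("ivm_missing_column",
               paste0("imaris dialect: missing column(s): ", paste(miss, collapse = ", ")))
    }
    df <- df[hit]
    names(df) <- unname(map[hit])
  }
  need <- c("track_id", "t", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    ivm_stop("ivm_missing_column",
             paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  for (cc in c("t", "x", "y", if ("z" %in% names(df)) "z")) {
    v <- df[[cc]]
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !is.na(v))) {
      ivm_stop("ivm_nonnumeric", paste0("non-numeric values in column '", cc, "'"))
    }
    df[[cc]] <- num
  }
  ts <- trackset(df, frame_interval = frame_interval,
                 provenance = paste0("read_tracks(", basename(path), ", dialect=", dialect, ")"))
  if (verbose) {
    message(sprintf("read_tracks: %d tracks / %d points from %s (frame interval %g min)",
                    n_tracks(ts), nrow(ts), basename(path), frame_interval(ts)))
  }
  ts
}

# RFC-4180 field quoting: quote only fields containing comma/quote/newline.
rfc4180 <- function(v) {
  v <- as.character(v)
  needs <- grepl("[\",\n\r]", v)
  v[needs] <- paste0("\"", gsub("\"", "\"\"", v[needs]), "\"")
  v
}

# Full-precision numeric formatting so CSV round trips are lossless.
num17 <- function(x) sprintf("%.17g", x)

#' Write a track table
#'
#' Writes the plain-dialect CSV (`track_id,t,x,y[,z]` plus any label
#' columns). Numeric columns are written at full double precision, so
#' `read_tracks(write_tracks(ts))` reproduces every id, time and coordinate
#' exactly. The `z` column appears iff the trackset is 3D.
#'
#' @param ts a non-empty [trackset].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(is_trackset(ts))
  if (nrow(ts) == 0) ivm_stop("ivm_empty_trackset", "refusing to write an empty trackset")
  df <- as.data.frame(ts)
  cols <- lapply(names(df), function(nm) {
    if (is.numeric(df[[nm]])) num17(df[[nm]]) else rfc4180(df[[nm]])
  })
  lines <- c(paste(rfc4180(names(df)), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")  # fixed newline convention for determinism
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Quality-filter tracks
#'
#' Drops tracks with fewer than `min_points` points or any inter-point time
#' gap exceeding `max_gap` frame intervals. Defaults (5 points, 2 frames)
#' guarantee that retained tracks support an MSD fit over at least 4 lags.
#' When the trackset carries epoch labels, the gap rule is applied within
#' each epoch: the pre/post injection gap is part of the imaging design,
#' not a tracking dropout.
#'
#' @param ts a [trackset].
#' @param min_points minimum points per retained track (>= 2).
#' @param max_gap largest allowed gap, in multiples of the frame interval
#'   (`Inf` disables the gap rule).
#' @param verbose log in/out counts to standard error.
#' @return The filtered [trackset] (possibly empty, with a warning).
#' @export
filter_tracks <- function(ts, min_points = 5, max_gap = 2, verbose = TRUE) {
  stopifnot(is_trackset(ts))
  if (min_points < 2) ivm_stop("ivm_invalid_filter", "min_points must be >= 2")
  dt <- frame_interval(ts)
  ok <- vapply(split_tracks(ts), function(tr) {
    gaps <- if ("epoch" %in% names(tr)) {
      unlist(lapply(split(tr$t, tr$epoch), diff), use.names = FALSE)
    } else {
      diff(tr$t)
    }
    nrow(tr) >= min_points &&
      (is.infinite(max_gap) || all(gaps <= max_gap * dt + 1e-9))
  }, logical(1))
  keep_ids <- names(ok)[ok]
  out <- trackset(as.data.frame(ts)[ts$track_id %in% keep_ids, , drop = FALSE],
                  frame_interval = dt, provenance = attr(ts, "provenance"))
  if (verbose) {
    message(sprintf("filter_tracks: kept %d of %d tracks (min_points=%g, max_gap=%g)",
                    length(keep_ids), length(ok), min_points, max_gap))
  }
  if (length(keep_ids) == 0) warning("filter_tracks: no tracks passed the filter")
  out
}

#' Read a cluster-intensity table
#'
#' Parses a CSV with header `region_id,mfi_before,mfi_after`: the mean
#' fluorescence intensity of the same regions before and after treatment,
#' as used for paired before/after cluster-size analysis.
#'
#' @param path CSV file path.
#' @return data.frame with columns `region_id` (character), `mfi_before`,
#'   `mfi_after` (non-negative numeric).
#' @export
read_cluster_intensity <- function(path) {
  if (!file.exists(path)) ivm_stop("ivm_missing_file", paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("region_id", "mfi_before", "mfi_after"), names(df))
  if (length(miss) > 0) {
    ivm_stop("ivm_missing_column",
             paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  for (cc in c("mfi_before", "mfi_after")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) ivm_stop("ivm_nonnumeric", paste0("non-numeric values in '", cc, "'"))
    if (any(v < 0)) ivm_stop("ivm_invalid_intensity", "intensities must be >= 0")
    df[[cc]] <- v
  }
  df$region_id <- as.character(df$region_id)
  df[c("region_id", "mfi_before", "mfi_after")]
}
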