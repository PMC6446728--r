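# Track table parsing, writing, and quality filtering.

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

test_that("plain CSV parses into tracks with time-sorted points", {
  f <- write_lines_tmp(c(
    "track_id,t,x,y",
    "a,0,0,0", "a,3,1,0", "a,6,2,0",
    "b,3,5,5", "b,0,4,5", "b,6,6,5"))  # b rows shuffled
  ts <- read_tracks(f, verbose = FALSE)
  expect_s3_class(ts, "trackset")
  expect_equal(n_tracks(ts), 2)
  expect_equal(nrow(ts), 6)
  expect_equal(frame_interval(ts), 3)
  expect_equal(track_dims(ts), 2)
  b <- split_tracks(ts)$b
  expect_equal(b$t, c(0, 3, 6))
  expect_equal(b$x, c(4, 5, 6))

  # row order in the file is irrelevant
  f2 <- write_lines_tmp(c(
    "track_id,t,x,y",
    "b,6,6,5", "a,6,2,0", "b,0,4,5",
    "a,0,0,0", "b,3,5,5", "a,3,1,0"))
  expect_equal(read_tracks(f2, verbose = FALSE), ts, ignore_attr = "provenance")
})

test_that("imaris-like dialect skips metadata and maps columns", {
  f <- write_lines_tmp(c(
    "Track Spots", "==========", "some,unrelated,metadata",
    "Position X,Position Y,Position Z,Time,TrackID",
    "1,2,3,0,10", "2,3,4,3,10", "5,5,5,0,11", "5,6,5,3,11"))
  ts <- read_tracks(f, dialect = "imaris", verbose = FALSE)
  expect_equal(n_tracks(ts), 2)
  expect_equal(track_dims(ts), 3)
  expect_equal(split_tracks(ts)[["10"]]$z, c(3, 4))
})

test_that("parse failures raise distinct named errors", {
  expect_error(read_tracks(tempfile(), verbose = FALSE), class = "ivm_missing_file")
  f <- write_lines_tmp(c("track_id,t,y", "a,0,0", "a,3,1"))
  expect_error(read_tracks(f, verbose = FALSE), class = "ivm_missing_column")
  f <- write_lines_tmp(c("track_id,t,x,y", "a,0,0,0", "a,0,1,1"))
  expect_error(read_tracks(f, verbose = FALSE), class = "ivm_duplicate_timepoint")
  f <- write_lines_tmp(c("track_id,t,x,y", "a,0,oops,0", "a,3,1,0"))
  expect_error(read_tracks(f, verbose = FALSE), class = "ivm_nonnumeric")
  f <- write_lines_tmp(c("no imaris header here", "1,2,3"))
  expect_error(read_tracks(f, dialect = "imaris", verbose = FALSE),
               class = "ivm_missing_column")
})

test_that("write -> read round trip is lossless for randomized tracksets", {
  for (seed in 1:5) {
    ts <- random_trackset(n_tracks = 3, n_points = 5,
                          dims = sample(2:3, 1), seed = seed)
    f <- tempfile(fileext = ".csv")
    write_tracks(ts, f)
    back <- read_tracks(f, verbose = FALSE)
    expect_equal(back, ts, ignore_attr = "provenance", tolerance = 0)
  }
})

test_that("written schema includes z exactly when the trackset is 3D", {
  f2 <- tempfile(); f3 <- tempfile()
  write_tracks(random_trackset(dims = 2, seed = 1), f2)
  write_tracks(random_trackset(dims = 3, seed = 1), f3)
  expect_false(grepl("\\bz\\b", readLines(f2)[1]))
  expect_true(grepl("\\bz\\b", readLines(f3)[1]))
})

test_that("writing an empty trackset is refused", {
  ts <- random_trackset(seed = 1)
  empty <- trackset(as.data.frame(ts)[0, ], frame_interval = 3)
  expect_error(write_tracks(empty, tempfile()), class = "ivm_empty_trackset")
})

test_that("filter_tracks applies point-count and gap rules", {
  mk <- function(id, t) data.frame(track_id = id, t = t, x = seq_along(t), y = 0)
  ts <- trackset(rbind(mk("short", c(0, 3, 6)),
                       mk("long", seq(0, 27, by = 3)),
                       mk("gappy", c(0, 3, 6, 15, 18))),
                 frame_interval = 3)
  kept <- quiet_filter(ts, min_points = 5, max_gap = 2)
  expect_equal(track_ids(kept), "long")  # short fails n, gappy has a 3-frame gap

  # min_points = 2, max_gap = Inf is the identity on >=2-point tracks
  expect_equal(as.data.frame(quiet_filter(ts, 2, Inf)), as.data.frame(ts))

  # idempotence and subset property
  once <- quiet_filter(ts, 5, 2)
  twice <- quiet_filter(once, 5, 2)
  expect_equal(as.data.frame(twice), as.data.frame(once))
  expect_true(all(track_ids(once) %in% track_ids(ts)))

  expect_warning(quiet_filter(ts, min_points = 20), "no tracks passed")
})

test_that("cluster-intensity tables parse and validate", {
  f <- write_lines_tmp(c("region_id,mfi_before,mfi_after",
                         "r1,100,80", "r2,150,150.5"))
  rec <- read_cluster_intensity(f)
  expect_equal(rec$region_id, c("r1", "r2"))
  expect_equal(rec$mfi_after, c(80, 150.5))
  f <- write_lines_tmp(c("region_id,mfi_before", "r1,1"))
  expect_error(read_cluster_intensity(f), class = "ivm_missing_column")
  f <- write_lines_tmp(c("region_id,mfi_before,mfi_after", "r1,-1,2"))
  expect_error(read_cluster_intensity(f), class = "ivm_invalid_intensity")
})
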