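# Independent oracles and fixture builders, kept deliberately naive:
# brute-force double loops and textbook formulas, never the package's own
# code paths.

# O(n^2) all-pairs TA-MSD: loop over every ordered point pair, bin by
# nearest integer lag multiple, average.
brute_tamsd <- function(track, frame_interval, max_lag_fraction = 0.25) {
  cc <- c("x", "y", if ("z" %in% names(track)) "z")
  xy <- as.matrix(track[cc])
  n <- nrow(track)
  duration <- track$t[n] - track$t[1]
  kmax <- floor(max_lag_fraction * duration / frame_interval + 1e-9)
  sums <- counts <- rep(0, kmax)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tau <- track$t[j] - track$t[i]
      k <- round(tau / frame_interval)
      if (k >= 1 && k <= kmax && abs(tau - k * frame_interval) <= frame_interval / 4) {
        sums[k] <- sums[k] + sum((xy[j, ] - xy[i, ])^2)
        counts[k] <- counts[k] + 1
      }
    }
  }
  keep <- counts > 0
  data.frame(lag = (seq_len(kmax) * frame_interval)[keep],
             msd = (sums / pmax(counts, 1))[keep],
             n_pairs = counts[keep])
}

# Textbook two-sided t statistics evaluated directly from the formulas.
student_t_direct <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

welch_t_direct <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

paired_t_direct <- function(before, after) {
  d <- after - before
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Random-walk test track on the frame grid, optionally with dropped frames
# (gaps). Plain data.frame, built without any package code.
random_track <- function(n_points, frame_interval = 3, dims = 2,
                         gaps = 0, id = "trk") {
  n_grid <- n_points + gaps
  tt <- (seq_len(n_grid) - 1) * frame_interval
  pos <- apply(matrix(rnorm(n_grid * dims), n_grid, dims), 2, cumsum)
  keep <- sort(c(1, sample(2:n_grid, n_points - 1)))
  df <- data.frame(track_id = id, t = tt[keep],
                   x = pos[keep, 1], y = pos[keep, 2])
  if (dims == 3) df$z <- pos[keep, 3]
  df
}

# Small multi-track trackset with random coordinates (full double range).
random_trackset <- function(n_tracks = 4, n_points = 6, dims = 2, seed = 1) {
  set.seed(seed)
  pieces <- lapply(seq_len(n_tracks), function(i) {
    random_track(n_points, dims = dims, id = sprintf("cell_%02d", i))
  })
  trackset(do.call(rbind, pieces), frame_interval = 3)
}

quiet_filter <- function(...) suppressMessages(filter_tracks(...))
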