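# Synthetic trajectory cohorts with known motion regimes, emulating a
# paired pre/post-drug intravital timelapse design. All generators are
# exact (no Euler discretization error): Brownian and ballistic steps are
# sampled from their exact step distributions, fractional Brownian motion
# from the exact fractional-Gaussian-noise covariance, and the persistent
# random walk from the exact joint update of an Ornstein-Uhlenbeck velocity
# and its integral.

#' Imaging design for a paired pre/post-drug timelapse
#'
#' Defaults emulate a typical intravital protocol: positions timelapsed
#' every 3 min for 90 min, then — 15 min after drug injection — for a
#' further 180 min at the same rate. The injection gap is a time offset
#' between epochs; no frames are sampled during it.
#'
#' @param frame_interval minutes between frames.
#' @param pre_duration,post_duration epoch durations in minutes; each must
#'   be a whole number of frame intervals.
#' @param gap_duration minutes between the last pre frame and the first
#'   post frame.
#' @return A list of class `imaging_design`.
#' @export
imaging_design <- function(frame_interval = 3, pre_duration = 90,
                           gap_duration = 15, post_duration = 180) {
  d <- list(frame_interval = frame_interval, pre_duration = pre_duration,
            gap_duration = gap_duration, post_duration = post_duration)
  if (any(!vapply(d, function(v) is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0,
                  logical(1)))) {
    ivm_stop("ivm_invalid_design", "all design durations must be single positive numbers")
  }
  for (ep in c("pre_duration", "post_duration")) {
    k <- d[[ep]] / frame_interval
    if (abs(k - round(k)) > 1e-9) {
      ivm_stop("ivm_invalid_design",
               paste0(ep, " must be a whole number of frame intervals"))
    }
  }
  structure(d, class = "imaging_design")
}

#' Motion models for trajectory simulation
#'
#' @param kind one of `"brownian"`, `"fbm"`, `"prw"`, `"ballistic"`,
#'   `"stationary"`.
#' @param D Brownian diffusion coefficient, um^2/min (per-axis increment
#'   variance over a step of dt minutes is `2*D*dt`).
#' @param H Hurst exponent in (0,1) for fractional Brownian motion; the
#'   ensemble MSD grows as `tau^(2H)`.
#' @param K fBm generalized coefficient, um^2/min^(2H): per-axis
#'   `E[X(t)^2] = K * t^(2H)`.
#' @param speed for `"prw"`, the per-axis stationary velocity s.d. s
#'   (um/min) of the Ornstein-Uhlenbeck velocity process; for
#'   `"ballistic"`, the constant speed along a fixed random heading.
#' @param persistence PRW persistence time P (minutes). The PRW ensemble
#'   MSD follows the Furth relation
#'   `2*d*s^2*P*(tau - P*(1 - exp(-tau/P)))`.
#' @return A list of class `motion_model`.
#' @export
motion_model <- function(kind = c("brownian", "fbm", "prw", "ballistic", "stationary"),
                         D = NULL, H = NULL, K = NULL,
                         speed = NULL, persistence = NULL) {
  kind <- match.arg(kind)
  num1 <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v)
  m <- switch(kind,
    brownian = {
      if (!num1(D) || D < 0) ivm_stop("ivm_invalid_model", "brownian: D must be >= 0")
      list(D = D)
    },
    fbm = {
      if (!num1(H) || H <= 0 || H >= 1) {
        ivm_stop("ivm_invalid_model", "fbm: H must lie strictly in (0, 1)")
      }
      if (!num1(K) || K <= 0) ivm_stop("ivm_invalid_model", "fbm: K must be > 0")
      list(H = H, K = K)
    },
    prw = {
      if (!num1(speed) || speed < 0) ivm_stop("ivm_invalid_model", "prw: speed must be >= 0")
      if (!num1(persistence) || persistence <= 0) {
        ivm_stop("ivm_invalid_model", "prw: persistence must be > 0")
      }
      list(speed = speed, persistence = persistence)
    },
    ballistic = {
      if (!num1(speed) || speed < 0) {
        ivm_stop("ivm_invalid_model", "ballistic: speed must be >= 0")
      }
      list(speed = speed)
    },
    stationary = list()
  )
  structure(c(list(kind = kind), m), class = "motion_model")
}

#' Furth mean-squared displacement of a persistent random walk
#'
#' Closed-form ensemble MSD of a d-dimensional PRW whose per-axis velocity
#' is a stationary Ornstein-Uhlenbeck process with s.d. `speed` and
#' correlation time `persistence`: ballistic (`~ d*s^2*tau^2`) for
#' `tau << P`, diffusive for `tau >> P`.
#'
#' @param tau lag(s), minutes.
#' @inheritParams motion_model
#' @param dims dimensionality (2 or 3).
#' @return MSD values (um^2), same length as `tau`.
#' @export
furth_msd <- function(tau, speed, persistence, dims = 2) {
  2 * dims * speed^2 * persistence * (tau - persistence * (1 - exp(-tau / persistence)))
}

# --- increment sampling engine ------------------------------------------

# Per-model precomputation shared by all tracks of a cohort.
prep_motion <- function(model, n_steps, dt) {
  switch(model$kind,
    brownian = list(sd = sqrt(2 * model$D * dt)),
    fbm = {
      # exact fGn covariance: C[i,j] = K*dt^(2H)/2 * (|k+1|^2H - 2|k|^2H + |k-1|^2H)
      H2 <- 2 * model$H
      k <- 0:n_steps
      g <- model$K * dt^H2 / 2 * (abs(k + 1)^H2 - 2 * abs(k)^H2 + abs(k - 1)^H2)
      C <- g[abs(outer(seq_len(n_steps), seq_len(n_steps), "-")) + 1]
      dim(C) <- c(n_steps, n_steps)
      list(R = chol(C))
    },
    prw = {
      s <- model$speed; P <- model$persistence; a <- exp(-dt / P)
      var_v <- s^2 * (1 - a^2)
      cov_xv <- s^2 * P * (1 - a)^2
      var_x <- s^2 * P^2 * (2 * dt / P - 3 + 4 * a - a^2)
      S <- matrix(c(var_x, cov_xv, cov_xv, var_v), 2, 2)
      M <- if (s > 0) t(chol(S)) else matrix(0, 2, 2)
      list(a = a, P = P, s = s, M = M)
    },
    ballistic = list(step = model$speed * dt),
    stationary = list()
  )
}

# One track's increments (n_steps x dims), consuming the current RNG stream.
draw_increments <- function(model, prep, n_steps, dims) {
  switch(model$kind,
    brownian = matrix(stats::rnorm(n_steps * dims, sd = prep$sd), n_steps, dims),
    fbm = crossprod(prep$R, matrix(stats::rnorm(n_steps * dims), n_steps, dims)),
    prw = {
      v <- stats::rnorm(dims, sd = prep$s)   # stationary initial velocity
      inc <- matrix(0, n_steps, dims)
      drift <- prep$P * (1 - prep$a)
      for (j in seq_len(n_steps)) {
        e <- prep$M %*% matrix(stats::rnorm(2 * dims), 2, dims)
        inc[j, ] <- v * drift + e[1, ]
        v <- v * prep$a + e[2, ]
      }
      inc
    },
    ballistic = {
      u <- stats::rnorm(dims)
      nu <- sqrt(sum(u^2))
      u <- if (nu > 0) u / nu else c(1, numeric(dims - 1))
      matrix(rep(prep$step * u, each = n_steps), n_steps, dims)
    },
    stationary = matrix(0, n_steps, dims)
  )
}

# Deterministic per-track seed substreams: the master seed drives a single
# sample without replacement, so track i always gets the same substream
# regardless of how many tracks are simulated after it.
track_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

track_id_labels <- function(n) sprintf("track_%04d", seq_len(n))

# Shared single-epoch engine behind simulate_brownian/fbm/prw/ballistic.
simulate_tracks <- function(model, n_tracks, n_frames, frame_interval, dims, seed) {
  if (!is.numeric(n_frames) || n_frames < 2) {
    ivm_stop("ivm_invalid_design", "n_frames must be >= 2")
  }
  if (!is.numeric(n_tracks) || n_tracks < 1) {
    ivm_stop("ivm_invalid_design", "n_tracks must be >= 1")
  }
  if (!dims %in% c(2, 3)) ivm_stop("ivm_invalid_design", "dims must be 2 or 3")
  n_steps <- n_frames - 1
  prep <- prep_motion(model, n_steps, frame_interval)
  seeds <- track_seeds(seed, n_tracks)
  ids <- track_id_labels(n_tracks)
  tt <- (seq_len(n_frames) - 1) * frame_interval
  pieces <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    set.seed(seeds[i])
    inc <- draw_increments(model, prep, n_steps, dims)
    pos <- rbind(0, apply(inc, 2, cumsum))
    df <- data.frame(track_id = ids[i], t = tt,
                     x = pos[, 1], y = pos[, 2])
    if (dims == 3) df$z <- pos[, 3]
    pieces[[i]] <- df
  }
  trackset(do.call(rbind, pieces), frame_interval = frame_interval,
           provenance = sprintf("simulate_tracks(kind=%s, n=%d, seed=%d)",
                                model$kind, as.integer(n_tracks), as.integer(seed)))
}

#' Simulate Brownian trajectories
#'
#' Independent Gaussian increments per axis with variance
#' `2 * D * frame_interval` per step, so the ensemble MSD is
#' `2 * dims * D * tau`.
#'
#' @param n_tracks number of tracks.
#' @param n_frames frames per track (>= 2).
#' @param frame_interval minutes between frames.
#' @param dims 2 or 3.
#' @param D diffusion coefficient, um^2/min.
#' @param seed master seed; identical seeds give bit-identical tracksets.
#' @return A [trackset].
#' @export
simulate_brownian <- function(n_tracks, n_frames, frame_interval = 3, dims = 2,
                              D = 1, seed = 1) {
  simulate_tracks(motion_model("brownian", D = D),
                  n_tracks, n_frames, frame_interval, dims, seed)
}

#' Simulate fractional Brownian motion trajectories
#'
#' Each axis is an exact fractional Brownian motion with Hurst exponent
#' `H`: increments are stationary fractional Gaussian noise sampled via a
#' Cholesky factorization of the exact covariance implied by
#' `E[X(t)^2] = K * t^(2H)`. The ensemble MSD is `dims * K * tau^(2H)`,
#' i.e. anomalous exponent `alpha = 2H` (subdiffusive for H < 1/2,
#' superdiffusive for H > 1/2).
#'
#' @inheritParams simulate_brownian
#' @inheritParams motion_model
#' @return A [trackset].
#' @export
simulate_fbm <- function(n_tracks, n_frames, frame_interval = 3, dims = 2,
                         H = 0.5, K = 1, seed = 1) {
  simulate_tracks(motion_model("fbm", H = H, K = K),
                  n_tracks, n_frames, frame_interval, dims, seed)
}

#' Simulate persistent-random-walk trajectories
#'
#' The velocity follows a stationary Ornstein-Uhlenbeck process (per-axis
#' s.d. `speed`, correlation time `persistence`) and positions integrate it
#' exactly: each frame advances position and velocity with the exact joint
#' Gaussian update, so the ensemble MSD matches the Furth relation (see
#' [furth_msd()]) with no step-size bias — ballistic at lags well below the
#' persistence time, diffusive well above it.
#'
#' @inheritParams simulate_brownian
#' @inheritParams motion_model
#' @return A [trackset].
#' @export
simulate_prw <- function(n_tracks, n_frames, frame_interval = 3, dims = 2,
                         speed = 1, persistence = 9, seed = 1) {
  simulate_tracks(motion_model("prw", speed = speed, persistence = persistence),
                  n_tracks, n_frames, frame_interval, dims, seed)
}

#' Simulate ballistic trajectories
#'
#' Constant speed along a per-track fixed heading drawn uniformly on the
#' circle/sphere; the ensemble MSD is exactly `speed^2 * tau^2`
#' (anomalous exponent 2).
#'
#' @inheritParams simulate_brownian
#' @inheritParams motion_model
#' @return A [trackset].
#' @export
simulate_ballistic <- function(n_tracks, n_frames, frame_interval = 3, dims = 2,
                               speed = 1, seed = 1) {
  simulate_tracks(motion_model("ballistic", speed = speed),
                  n_tracks, n_frames, frame_interval, dims, seed)
}

#' Add localization noise to a trackset
#'
#' Adds independent zero-mean Gaussian jitter (s.d. `noise_sd` um) to every
#' coordinate, modeling spot-centroid localization error. For otherwise
#' stationary points this raises the MSD by `2 * dims * noise_sd^2` at
#' every positive lag. The input trackset is not modified.
#'
#' @param ts a [trackset].
#' @param noise_sd localization s.d. in um (>= 0; 0 is the identity).
#' @param seed master seed (per-track substreams, as in the simulators).
#' @return A new [trackset].
#' @export
add_localization_noise <- function(ts, noise_sd, seed = 1) {
  stopifnot(is_trackset(ts))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    ivm_stop("ivm_invalid_model", "noise_sd must be a single number >= 0")
  }
  if (noise_sd == 0) return(ts)
  ids <- track_ids(ts)
  seeds <- track_seeds(seed, length(ids))
  df <- as.data.frame(ts)
  cc <- coord_cols(df)
  for (i in seq_along(ids)) {
    rows <- which(df$track_id == ids[i])
    set.seed(seeds[i])
    df[rows, cc] <- df[rows, cc] +
      matrix(stats::rnorm(length(rows) * length(cc), sd = noise_sd),
             length(rows), length(cc))
  }
  trackset(df, frame_interval = frame_interval(ts),
           provenance = paste0(attr(ts, "provenance"),
                               sprintf(" + noise(sd=%g, seed=%d)", noise_sd, as.integer(seed))))
}

#' Specify a paired pre/post-drug cohort
#'
#' @param design an [imaging_design()].
#' @param dims 2 or 3.
#' @param n_tracks number of cells.
#' @param pre_model,post_model [motion_model()]s for the two epochs.
#' @param mobilized_fraction fraction of cells mobilized (lost from the
#'   imaging volume) at drug time; `floor(mobilized_fraction * n_tracks)`
#'   seeded-random cells get no post-epoch points.
#' @param noise_sd localization noise s.d. (um), applied last.
#' @param seed master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(design = imaging_design(), dims = 3, n_tracks = 100,
                        pre_model = motion_model("brownian", D = 1),
                        post_model = pre_model,
                        mobilized_fraction = 0, noise_sd = 0, seed = 1) {
  if (!inherits(design, "imaging_design")) {
    ivm_stop("ivm_invalid_spec", "design must be an imaging_design()")
  }
  if (!inherits(pre_model, "motion_model") || !inherits(post_model, "motion_model")) {
    ivm_stop("ivm_invalid_spec", "pre_model/post_model must be motion_model()s")
  }
  if (!dims %in% c(2, 3)) ivm_stop("ivm_invalid_spec", "dims must be 2 or 3")
  if (!is.numeric(n_tracks) || n_tracks < 1) ivm_stop("ivm_invalid_spec", "n_tracks must be >= 1")
  if (!is.numeric(mobilized_fraction) || mobilized_fraction < 0 || mobilized_fraction > 1) {
    ivm_stop("ivm_invalid_spec", "mobilized_fraction must lie in [0, 1]")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    ivm_stop("ivm_invalid_spec", "noise_sd must be >= 0")
  }
  structure(list(design = design, dims = as.integer(dims),
                 n_tracks = as.integer(n_tracks),
                 pre_model = pre_model, post_model = post_model,
                 mobilized_fraction = mobilized_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a paired pre/post-drug cohort
#'
#' Each cell receives a pre-epoch trajectory from `pre_model`, sampled every
#' `frame_interval` over `pre_duration` (t = 0 ... pre_duration). Unless
#' mobilized, it then continues from its last pre position under
#' `post_model` over `post_duration`, with the first post frame offset by
#' `gap_duration` (the injection gap; no frames are sampled during it).
#' Mobilized cells — a seeded random subset of size
#' `floor(mobilized_fraction * n_tracks)` — have no post-epoch points.
#' Localization noise is applied last. Points carry `epoch` labels
#' (`"pre"`/`"post"`).
#'
#' @param spec a [cohort_spec()].
#' @return A [trackset] with an `epoch` column.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    ivm_stop("ivm_invalid_spec", "spec must be a cohort_spec()")
  }
  d <- spec$design
  dt <- d$frame_interval
  n_pre <- as.integer(round(d$pre_duration / dt)) + 1L
  n_post <- as.integer(round(d$post_duration / dt)) + 1L
  t_pre <- (seq_len(n_pre) - 1) * dt
  t_post <- d$pre_duration + d$gap_duration + (seq_len(n_post) - 1) * dt
  prep_pre <- prep_motion(spec$pre_model, n_pre - 1L, dt)
  prep_post <- prep_motion(spec$post_model, n_post - 1L, dt)

  set.seed(spec$seed)
  seeds <- sample.int(2147483646L, spec$n_tracks)
  n_mob <- floor(spec$mobilized_fraction * spec$n_tracks)
  mobilized <- if (n_mob > 0) sample.int(spec$n_tracks, n_mob) else integer(0)

  ids <- track_id_labels(spec$n_tracks)
  pieces <- vector("list", spec$n_tracks)
  for (i in seq_len(spec$n_tracks)) {
    set.seed(seeds[i])
    inc <- draw_increments(spec$pre_model, prep_pre, n_pre - 1L, spec$dims)
    pos <- rbind(0, apply(inc, 2, cumsum))
    tt <- t_pre
    epoch <- rep("pre", n_pre)
    if (!(i %in% mobilized)) {
      inc2 <- draw_increments(spec$post_model, prep_post, n_post - 1L, spec$dims)
      start <- pos[nrow(pos), ]
      pos2 <- rbind(start, sweep(apply(inc2, 2, cumsum), 2, start, "+"))
      pos <- rbind(pos, pos2)
      tt <- c(tt, t_post)
      epoch <- c(epoch, rep("post", n_post))
    }
    if (spec$noise_sd > 0) {
      pos <- pos + matrix(stats::rnorm(length(pos), sd = spec$noise_sd),
                          nrow(pos), ncol(pos))
    }
    df <- data.frame(track_id = ids[i], t = tt, x = pos[, 1], y = pos[, 2])
    if (spec$dims == 3) df$z <- pos[, 3]
    df$epoch <- epoch
    pieces[[i]] <- df
  }
  trackset(do.call(rbind, pieces), frame_interval = dt,
           provenance = sprintf("simulate_cohort(pre=%s, post=%s, n=%d, mobilized=%g, seed=%d)",
                                spec$pre_model$kind, spec$post_model$kind,
                                spec$n_tracks, spec$mobilized_fraction, spec$seed))
}
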