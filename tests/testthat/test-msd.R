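# TA-MSD estimation, the MSD/lag transform, exponent fitting and regime
# classification.

test_that("TA-MSD of simple tracks matches hand-derived values", {
  # unit-step ballistic 1D: msd = (1, 4, 9) at lags (1, 2, 3)
  tr <- data.frame(track_id = "u", t = 0:3, x = 0:3, y = 0)
  m <- track_tamsd(tr, 1, max_lag_fraction = 1)
  expect_equal(m$lag, 1:3)
  expect_equal(m$msd, c(1, 4, 9))
  expect_equal(m$n_pairs, c(3, 2, 1))

  still <- data.frame(track_id = "s", t = (0:9) * 3, x = 2, y = -1)
  expect_true(all(track_tamsd(still, 3, 1)$msd == 0))

  expect_error(track_tamsd(tr[1:2, ], 1), class = "ivm_track_too_short")
})

test_that("TA-MSD equals the brute-force all-pairs oracle, with gaps", {
  set.seed(41)
  for (rep in 1:10) {
    tr <- random_track(20, frame_interval = 3, dims = sample(2:3, 1),
                       gaps = sample(0:6, 1))
    for (mlf in c(0.25, 1)) {
      got <- as.data.frame(track_tamsd(tr, 3, mlf))
      want <- brute_tamsd(tr, 3, mlf)
      expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("MSD is invariant under rigid motions of the field of view", {
  set.seed(42)
  tr <- random_track(15, dims = 2)
  m0 <- track_tamsd(tr, 3, 1)
  th <- runif(1, 0, 2 * pi)
  rot <- tr
  rot$x <- cos(th) * tr$x - sin(th) * tr$y + 100
  rot$y <- sin(th) * tr$x + cos(th) * tr$y + 7
  expect_equal(track_tamsd(rot, 3, 1)$msd, m0$msd)
})

test_that("ensemble MSD pools pairs across tracks", {
  set.seed(43)
  tr <- random_track(12, id = "one")
  ts1 <- trackset(tr, frame_interval = 3)
  # singleton ensemble = the track's own curve
  expect_equal(as.data.frame(ensemble_msd(ts1, 1, min_pairs = 1))[c("lag", "msd")],
               as.data.frame(track_tamsd(tr, 3, 1))[c("lag", "msd")],
               ignore_attr = TRUE)

  # duplicating a track leaves the curve unchanged
  tr2 <- tr; tr2$track_id <- "two"
  ts2 <- trackset(rbind(tr, tr2), frame_interval = 3)
  expect_equal(ensemble_msd(ts2, 1, 1)$msd, ensemble_msd(ts1, 1, 1)$msd)

  # heterogeneous lengths: equals brute-force pooled pairs
  tr3 <- random_track(30, id = "three", gaps = 3)
  ts3 <- trackset(rbind(tr, tr3), frame_interval = 3)
  got <- as.data.frame(ensemble_msd(ts3, 1, min_pairs = 1))
  b1 <- brute_tamsd(tr, 3, 1); b3 <- brute_tamsd(tr3, 3, 1)
  pool <- merge(b1, b3, by = "lag", all = TRUE)
  pool[is.na(pool)] <- 0
  want_msd <- (pool$msd.x * pool$n_pairs.x + pool$msd.y * pool$n_pairs.y) /
    (pool$n_pairs.x + pool$n_pairs.y)
  expect_equal(got$msd, want_msd, tolerance = 1e-12)
  expect_equal(got$n_pairs, pool$n_pairs.x + pool$n_pairs.y)
})

test_that("min_pairs drops thinly supported lags from the ensemble", {
  set.seed(44)
  tr <- random_track(12)
  ts <- trackset(tr, frame_interval = 3)
  m <- ensemble_msd(ts, max_lag_fraction = 1, min_pairs = 5)
  expect_true(all(m$n_pairs >= 5))
})

test_that("msd_over_lag divides by lag and encodes alpha - 1 as slope", {
  tau <- (1:10) * 3
  for (alpha in c(0.5, 1, 2)) {
    cv <- msd_curve(tau, 2.5 * tau^alpha)
    tf <- msd_over_lag(cv)
    expect_equal(tf$msd, 2.5 * tau^(alpha - 1))
    slope <- unname(coef(lm(log(tf$msd) ~ log(tf$lag)))[2])
    expect_equal(slope, alpha - 1, tolerance = 1e-9)
  }
  expect_error(msd_over_lag(new_curve <- structure(
    data.frame(lag = c(0, 3), msd = 1, n_pairs = 1),
    class = c("msd_curve", "data.frame"))), class = "ivm_invalid_lag")
})

test_that("exponent fitting recovers exact power laws and calls regimes", {
  tau <- (1:8) * 3
  f2 <- fit_anomalous_exponent(msd_curve(tau, 0.7 * tau^2))
  expect_equal(f2$alpha, 2, tolerance = 1e-9)
  expect_equal(f2$regime, "superdiffusive")
  f1 <- fit_anomalous_exponent(msd_curve(tau, 4 * tau))
  expect_equal(f1$alpha, 1, tolerance = 1e-9)
  expect_equal(f1$regime, "diffusive")
  expect_equal(f1$log_coeff, log(4), tolerance = 1e-9)
  f05 <- fit_anomalous_exponent(msd_curve(tau, tau^0.5))
  expect_equal(f05$regime, "subdiffusive")

  # fit range restriction and the <3-lags error
  fr <- fit_anomalous_exponent(msd_curve(tau, 0.7 * tau^2), fit_lags = c(3, 12))
  expect_equal(fr$fit_lags, c(3, 12))
  expect_equal(fr$n_lags, 4)
  expect_error(fit_anomalous_exponent(msd_curve(tau, 0.7 * tau^2), fit_lags = c(3, 6)),
               class = "ivm_fit_too_few_lags")
  expect_warning(
    expect_error(fit_anomalous_exponent(msd_curve((1:3) * 3, c(0, 0, 1))),
                 class = "ivm_fit_too_few_lags"),
    "non-positive")
})

test_that("standard-error-aware regime calls stay diffusive within 2 se", {
  tau <- (1:8) * 3
  set.seed(45)
  noisy <- 4 * tau^1.12 * exp(rnorm(8, sd = 0.15))
  f <- fit_anomalous_exponent(msd_curve(tau, noisy), se_aware = TRUE)
  if (abs(f$alpha - 1) <= 2 * f$alpha_se) expect_equal(f$regime, "diffusive")
  strict <- fit_anomalous_exponent(msd_curve(tau, 4 * tau^1.5))
  expect_equal(strict$regime, "superdiffusive")
})

test_that("Brownian ensembles fit alpha near 1", {
  ts <- simulate_brownian(200, 31, 3, 2, D = 1, seed = 46)
  fit <- fit_anomalous_exponent(ensemble_msd(ts))
  expect_gt(fit$alpha, 0.9); expect_lt(fit$alpha, 1.1)
  expect_equal(fit$regime, "diffusive")
})

test_that("cohort MSD reports state the regime shift between epochs", {
  pre_b <- simulate_brownian(200, 31, 3, 2, D = 1, seed = 47)
  post_b <- simulate_brownian(200, 31, 3, 2, D = 1, seed = 48)
  same <- cohort_msd_report(pre_b, post_b)
  expect_equal(same$pre$fit$regime, same$post$fit$regime)

  post_ball <- simulate_ballistic(200, 31, 3, 2, speed = 1, seed = 49)
  shift <- cohort_msd_report(pre_b, post_ball)
  expect_equal(shift$shift, "diffusive -> superdiffusive")

  pre_fbm <- simulate_fbm(300, 31, 3, 2, H = 0.35, K = 1, seed = 50)
  shift2 <- cohort_msd_report(pre_fbm, post_b)  # alpha = 0.7 vs 1
  expect_equal(shift2$shift, "subdiffusive -> diffusive")
})
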