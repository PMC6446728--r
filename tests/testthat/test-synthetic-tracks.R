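# Synthetic trajectory generators: exactness of the sampled motion models,
# seeding contracts, and the paired-cohort design.

test_that("generators are deterministic and use per-track substreams", {
  a <- simulate_brownian(10, 5, 3, 2, D = 1, seed = 11)
  b <- simulate_brownian(10, 5, 3, 2, D = 1, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, simulate_brownian(10, 5, 3, 2, D = 1, seed = 12)))

  # track i's trajectory does not depend on how many tracks follow it
  small <- simulate_brownian(3, 5, 3, 2, D = 1, seed = 11)
  expect_equal(as.data.frame(a)[a$track_id %in% track_ids(small), ],
               as.data.frame(small), ignore_attr = TRUE)
})

test_that("zero diffusivity yields stationary tracks", {
  ts <- simulate_brownian(5, 10, 3, 3, D = 0, seed = 1)
  expect_true(all(ts$x == 0 & ts$y == 0 & ts$z == 0))
})

test_that("model parameter validation raises named errors", {
  expect_error(simulate_brownian(5, 10, D = -1), class = "ivm_invalid_model")
  expect_error(simulate_brownian(5, 1, D = 1), class = "ivm_invalid_design")
  expect_error(simulate_fbm(5, 10, H = 1.2), class = "ivm_invalid_model")
  expect_error(simulate_fbm(5, 10, H = 0), class = "ivm_invalid_model")
  expect_error(simulate_prw(5, 10, speed = 1, persistence = 0),
               class = "ivm_invalid_model")
  expect_error(add_localization_noise(simulate_brownian(2, 5), -1),
               class = "ivm_invalid_model")
})

test_that("fBm with H = 1/2 has uncorrelated increments", {
  ts <- simulate_fbm(100, 101, frame_interval = 1, dims = 2, H = 0.5, K = 2, seed = 5)
  inc <- unlist(lapply(split_tracks(ts), function(tr) {
    c(diff(tr$x), diff(tr$y))
  }), use.names = FALSE)  # 2 x 10^4 increments
  g0 <- var(inc)
  expect_equal(g0, 2, tolerance = 0.05)  # K * dt^(2H) = 2
  for (k in 1:3) {
    acv <- mean(inc[-(1:k)] * inc[seq_len(length(inc) - k)])
    expect_lt(abs(acv) / g0, 0.05)
  }
})

test_that("fBm increment covariance matches the fGn closed form", {
  H <- 0.8; K <- 1; dt <- 3; n_steps <- 10
  ts <- simulate_fbm(10000, n_steps + 1, dt, dims = 2, H = H, K = K, seed = 6)
  inc <- do.call(rbind, lapply(split_tracks(ts), function(tr) {
    rbind(diff(tr$x), diff(tr$y))
  }))  # 20000 realizations x 10 steps
  emp <- crossprod(inc) / nrow(inc)
  k <- 0:n_steps
  g <- K * dt^(2 * H) / 2 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  theo <- g[abs(outer(1:n_steps, 1:n_steps, "-")) + 1]
  dim(theo) <- c(n_steps, n_steps)
  expect_lt(max(abs(emp - theo)), 0.05 * g[1])  # entrywise, 5% of the variance scale
})

test_that("fBm with H = 0.25 recovers ensemble exponent near 2H", {
  ts <- simulate_fbm(500, 31, 3, 2, H = 0.25, K = 1, seed = 8)
  fit <- fit_anomalous_exponent(ensemble_msd(ts))
  expect_equal(fit$alpha, 0.5, tolerance = 0.2)  # alpha = 2H, +/- 0.1 absolute
  expect_gt(fit$alpha, 0.4); expect_lt(fit$alpha, 0.6)
})

test_that("Furth relation has ballistic and diffusive limits", {
  s <- 2; P <- 9; d <- 2
  # tau << P: MSD ~ d * s^2 * tau^2
  tau <- c(0.01, 0.02)
  expect_equal(furth_msd(tau, s, P, d), d * s^2 * tau^2, tolerance = 1e-3)
  # tau >> P: local log-log slope -> 1
  tau <- c(1e5, 2e5)
  slope <- diff(log(furth_msd(tau, s, P, d))) / diff(log(tau))
  expect_equal(slope, 1, tolerance = 1e-3)
})

test_that("PRW ensemble MSD matches the Furth closed form", {
  s <- 2; P <- 9
  ts <- simulate_prw(300, 31, 3, 2, speed = s, persistence = P, seed = 9)
  m <- ensemble_msd(ts, max_lag_fraction = 1 / 3)
  expect_true(all(abs(m$msd / furth_msd(m$lag, s, P, 2) - 1) < 0.05))
})

test_that("localization noise is additive Gaussian jitter with exact contracts", {
  ts <- simulate_brownian(20, 10, 3, 2, D = 1, seed = 3)
  expect_identical(add_localization_noise(ts, 0, seed = 1), ts)  # sd 0: identity
  n1 <- add_localization_noise(ts, 0.5, seed = 4)
  expect_identical(n1, add_localization_noise(ts, 0.5, seed = 4))
  expect_false(identical(n1, ts))
  expect_true(all(ts$x == simulate_brownian(20, 10, 3, 2, D = 1, seed = 3)$x))

  # stationary points + noise: ensemble MSD = 2 * d * sigma^2 at every lag
  still <- simulate_brownian(300, 21, 3, 2, D = 0, seed = 5)
  noisy <- add_localization_noise(still, 1.5, seed = 6)
  m <- ensemble_msd(noisy, max_lag_fraction = 0.5)
  expect_true(all(abs(m$msd / (2 * 2 * 1.5^2) - 1) < 0.1))
})

test_that("paired cohorts follow the imaging design", {
  spec <- cohort_spec(n_tracks = 6, dims = 3,
                      pre_model = motion_model("brownian", D = 1),
                      mobilized_fraction = 0.5, noise_sd = 0, seed = 2)
  ts <- simulate_cohort(spec)
  expect_identical(ts, simulate_cohort(spec))  # determinism
  pre <- epoch_subset(ts, "pre"); post <- epoch_subset(ts, "post")
  expect_equal(n_tracks(pre), 6)
  expect_equal(n_tracks(post), 3)  # floor(0.5 * 6) mobilized
  for (tr in split_tracks(pre)) {
    expect_equal(range(tr$t), c(0, 90))
    expect_equal(length(tr$t), 31)  # every 3 min over 90 min
  }
  for (tr in split_tracks(post)) {
    expect_equal(range(tr$t), c(105, 285))  # 15-min gap, then 180 min
    expect_equal(length(tr$t), 61)
  }
  # post tracks continue from the last pre position
  id <- track_ids(post)[1]
  pre1 <- split_tracks(pre)[[id]]; post1 <- split_tracks(post)[[id]]
  expect_equal(unlist(post1[1, c("x", "y", "z")]),
               unlist(pre1[31, c("x", "y", "z")]), ignore_attr = TRUE)
})

test_that("fully mobilized cohorts have no post-epoch points", {
  ts <- simulate_cohort(cohort_spec(n_tracks = 4, mobilized_fraction = 1, seed = 1))
  expect_false("post" %in% ts$epoch)
})

test_that("identical pre/post generators give matching epoch MSD curves", {
  spec <- cohort_spec(n_tracks = 400, dims = 2,
                      pre_model = motion_model("brownian", D = 1),
                      mobilized_fraction = 0, noise_sd = 0, seed = 7)
  ts <- simulate_cohort(spec)
  m_pre <- ensemble_msd(epoch_subset(ts, "pre"))
  m_post <- ensemble_msd(epoch_subset(ts, "post"))
  shared <- intersect(m_pre$lag, m_post$lag)
  a <- m_pre$msd[match(shared, m_pre$lag)]
  b <- m_post$msd[match(shared, m_post$lag)]
  expect_true(all(abs(a / b - 1) < 0.15))  # same generator both epochs
})
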