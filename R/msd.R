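# Time-averaged mean-squared displacement (TA-MSD), the MSD/lag log-log
# representation, anomalous-exponent fitting and motion-regime calls.

new_msd_curve <- function(lag, msd, n_pairs, source) {
  structure(data.frame(lag = lag, msd = msd, n_pairs = n_pairs),
            source = source, class = c("msd_curve", "data.frame"))
}

#' Construct an MSD curve
#'
#' Builds an `msd_curve` from explicit values — useful for comparing fits
#' against closed-form curves such as `K * tau^alpha`.
#'
#' @param lag strictly increasing positive lags (minutes).
#' @param msd non-negative MSD values (um^2), one per lag.
#' @param n_pairs displacement-pair counts per lag (default 1).
#' @param source identifier (default `"manual"`).
#' @return An object of class `msd_curve`.
#' @export
msd_curve <- function(lag, msd, n_pairs = rep(1L, length(lag)), source = "manual") {
  if (length(lag) != length(msd) || length(lag) != length(n_pairs)) {
    ivm_stop("ivm_invalid_lag", "lag, msd and n_pairs must have equal length")
  }
  if (any(lag <= 0) || is.unsorted(lag, strictly = TRUE)) {
    ivm_stop("ivm_invalid_lag", "lags must be positive and strictly increasing")
  }
  if (any(msd < 0) || any(n_pairs < 1)) {
    ivm_stop("ivm_invalid_lag", "msd must be >= 0 and n_pairs >= 1")
  }
  new_msd_curve(lag, msd, n_pairs, source)
}

#' Time-averaged MSD of one track
#'
#' For each lag `tau = k * frame_interval` up to
#' `max_lag_fraction * duration`, the average squared Euclidean
#' displacement over all (overlapping) point pairs separated by `tau`.
#' Pairs spanning a gap are included whenever both endpoints exist; lags
#' with no pairs are omitted. This is the maximal-pair time-average
#' estimator standard in single-particle tracking.
#'
#' @param track a single-track data.frame (`t`, `x`, `y`, optionally `z`)
#'   with >= 3 points, e.g. one element of [split_tracks()].
#' @param frame_interval minutes between frames.
#' @param max_lag_fraction largest lag as a fraction of track duration, in
#'   (0, 1]; default 0.25 (long lags average few pairs and are noisy).
#' @return An `msd_curve`: data.frame with columns `lag` (min), `msd`
#'   (um^2) and `n_pairs`.
#' @export
track_tamsd <- function(track, frame_interval, max_lag_fraction = 0.25) {
  if (nrow(track) < 3) {
    ivm_stop("ivm_track_too_short", "TA-MSD needs at least 3 points")
  }
  if (!is.numeric(max_lag_fraction) || max_lag_fraction <= 0 || max_lag_fraction > 1) {
    ivm_stop("ivm_invalid_lag_fraction", "max_lag_fraction must lie in (0, 1]")
  }
  rel <- track$t - track$t[1]
  idx <- round(rel / frame_interval)
  if (any(abs(rel - idx * frame_interval) > frame_interval / 4)) {
    warning("track times are off the frame grid; lags use nearest-frame matching")
  }
  xy <- as.matrix(track[coord_cols(track)])
  duration <- rel[length(rel)]
  kmax <- floor(max_lag_fraction * duration / frame_interval + 1e-9)
  lag <- msd <- np <- numeric(0)
  for (k in seq_len(max(kmax, 0))) {
    j <- match(idx + k, idx)
    ok <- !is.na(j)
    if (!any(ok)) next
    d2 <- rowSums((xy[j[ok], , drop = FALSE] - xy[ok, , drop = FALSE])^2)
    lag <- c(lag, k * frame_interval)
    msd <- c(msd, mean(d2))
    np <- c(np, sum(ok))
  }
  if (length(lag) == 0) {
    ivm_stop("ivm_track_too_short", "no lag has any displacement pair")
  }
  new_msd_curve(lag, msd, np, source = as.character(track$track_id[1]))
}

#' Ensemble time-averaged MSD of a trackset
#'
#' Per lag, the pair-count-weighted mean of per-track TA-MSD values —
#' equivalently, the pooled mean over all displacement pairs from all
#' tracks. An unweighted per-track mean (`weighting = "tracks"`) is
#' available for sensitivity analysis. Lags supported by fewer than
#' `min_pairs` pooled pairs are dropped (variance control for the fit).
#'
#' @param ts a [trackset]; tracks with < 3 points are skipped.
#' @param max_lag_fraction see [track_tamsd()].
#' @param min_pairs minimum pooled pair count per retained lag.
#' @param weighting `"pairs"` (pooled, default) or `"tracks"`.
#' @return An `msd_curve` with `source = "ensemble"`.
#' @export
ensemble_msd <- function(ts, max_lag_fraction = 0.25, min_pairs = 10,
                         weighting = c("pairs", "tracks")) {
  stopifnot(is_trackset(ts))
  weighting <- match.arg(weighting)
  dt <- frame_interval(ts)
  curves <- list()
  for (tr in split_tracks(ts)) {
    if (nrow(tr) < 3) next
    curves[[length(curves) + 1]] <- track_tamsd(tr, dt, max_lag_fraction)
  }
  if (length(curves) == 0) {
    ivm_stop("ivm_track_too_short", "no track is long enough for a TA-MSD")
  }
  all <- do.call(rbind, lapply(curves, as.data.frame))
  lags <- sort(unique(all$lag))
  msd <- np <- numeric(length(lags))
  for (i in seq_along(lags)) {
    sub <- all[all$lag == lags[i], ]
    np[i] <- sum(sub$n_pairs)
    msd[i] <- if (weighting == "pairs") {
      sum(sub$msd * sub$n_pairs) / np[i]
    } else {
      mean(sub$msd)
    }
  }
  keep <- np >= min_pairs
  if (!any(keep)) ivm_stop("ivm_track_too_short", "no lag reaches min_pairs pooled pairs")
  new_msd_curve(lags[keep], msd[keep], np[keep], source = "ensemble")
}

#' MSD-over-lag transform
#'
#' Divides each MSD value by its lag (units um^2/min). On log-log axes the
#' local slope of this transform is `alpha - 1`: flat for Brownian motion,
#' rising for superdiffusion, falling for subdiffusion — the standard
#' diffusivity-diagnostic representation of track ensembles.
#'
#' @param curve an `msd_curve` with all lags > 0.
#' @return An `msd_curve`-shaped data.frame whose `msd` column holds
#'   `msd/lag` values.
#' @export
msd_over_lag <- function(curve) {
  stopifnot(inherits(curve, "msd_curve"))
  if (any(curve$lag <= 0)) ivm_stop("ivm_invalid_lag", "all lags must be > 0")
  out <- new_msd_curve(curve$lag, curve$msd / curve$lag, curve$n_pairs,
                       source = attr(curve, "source"))
  attr(out, "transform") <- "msd_over_lag"
  out
}

regime_call <- function(alpha, alpha_se, thresholds = c(0.9, 1.1), se_aware = FALSE) {
  if (se_aware && is.finite(alpha_se) && abs(alpha - 1) <= 2 * alpha_se) {
    return("diffusive")
  }
  if (alpha < thresholds[1]) "subdiffusive"
  else if (alpha > thresholds[2]) "superdiffusive"
  else "diffusive"
}

#' Fit the anomalous-diffusion exponent
#'
#' Ordinary least squares of `log(msd)` on `log(lag)` (natural logs) over
#' the requested lag range: the slope is the anomalous exponent `alpha`
#' (1 Brownian, < 1 subdiffusive, > 1 superdiffusive, 2 ballistic), with
#' its regression standard error. Zero-MSD lags (possible for stationary
#' tracks) are excluded with a warning rather than clamped. The regime
#' call uses explicit thresholds (default: subdiffusive below 0.9,
#' superdiffusive above 1.1); `se_aware = TRUE` additionally keeps the
#' call at "diffusive" unless `|alpha - 1| > 2 * alpha_se`.
#'
#' @param curve an `msd_curve`.
#' @param fit_lags optional `c(min, max)` lag range (minutes) to fit over;
#'   default: all retained lags.
#' @param thresholds length-2 regime thresholds around 1.
#' @param se_aware see above.
#' @return A list of class `alpha_fit`: `alpha`, `log_coeff` (intercept of
#'   the log-log fit, natural log), `alpha_se`, `fit_lags` (range used),
#'   `n_lags`, `regime`.
#' @export
fit_anomalous_exponent <- function(curve, fit_lags = NULL,
                                   thresholds = c(0.9, 1.1), se_aware = FALSE) {
  stopifnot(inherits(curve, "msd_curve"))
  df <- as.data.frame(curve)
  if (!is.null(fit_lags)) {
    df <- df[df$lag >= fit_lags[1] & df$lag <= fit_lags[2], , drop = FALSE]
  }
  if (any(df$msd <= 0)) {
    warning("dropping lags with non-positive MSD from the exponent fit")
    df <- df[df$msd > 0, , drop = FALSE]
  }
  if (nrow(df) < 3) {
    ivm_stop("ivm_fit_too_few_lags", "exponent fit needs at least 3 positive-MSD lags")
  }
  fit <- stats::lm(log(msd) ~ log(lag), data = df)
  alpha <- unname(stats::coef(fit)[2])
  # exact power laws fit perfectly; suppress summary.lm's zero-residual warning
  alpha_se <- unname(suppressWarnings(sqrt(diag(stats::vcov(fit))))[2])
  structure(list(alpha = alpha,
                 log_coeff = unname(stats::coef(fit)[1]),
                 alpha_se = alpha_se,
                 fit_lags = range(df$lag),
                 n_lags = nrow(df),
                 regime = regime_call(alpha, alpha_se, thresholds, se_aware)),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("<alpha_fit> alpha = %.4f (se %.4f), %s; %d lags in [%g, %g] min\n",
              x$alpha, x$alpha_se, x$regime, x$n_lags, x$fit_lags[1], x$fit_lags[2]))
  invisible(x)
}

#' Paired pre/post MSD report
#'
#' Computes, for each epoch's trackset, the ensemble TA-MSD, its
#' MSD-over-lag transform and the anomalous-exponent fit, and states the
#' motion-regime shift (e.g. "diffusive -> superdiffusive") between
#' epochs — the diffusivity comparison made for cells tracked before and
#' after drug exposure.
#'
#' @param pre,post [trackset]s for the two epochs (non-empty).
#' @param max_lag_fraction,min_pairs,weighting see [ensemble_msd()].
#' @param thresholds,se_aware see [fit_anomalous_exponent()].
#' @return A list of class `msd_report` with elements `pre`, `post` (each
#'   `list(msd, over_lag, fit)`) and `shift` (character).
#' @export
cohort_msd_report <- function(pre, post, max_lag_fraction = 0.25, min_pairs = 10,
                              weighting = "pairs", thresholds = c(0.9, 1.1),
                              se_aware = FALSE) {
  one <- function(ts) {
    if (nrow(ts) == 0) ivm_stop("ivm_empty_trackset", "epoch trackset is empty")
    msd <- ensemble_msd(ts, max_lag_fraction, min_pairs, weighting)
    list(msd = msd, over_lag = msd_over_lag(msd),
         fit = fit_anomalous_exponent(msd, thresholds = thresholds, se_aware = se_aware))
  }
  a <- one(pre); b <- one(post)
  structure(list(pre = a, post = b,
                 shift = paste(a$fit$regime, "->", b$fit$regime)),
            class = "msd_report")
}

#' @export
print.msd_report <- function(x, ...) {
  cat("<msd_report>\n  pre : "); print(x$pre$fit)
  cat("  post: "); print(x$post$fit)
  cat("  regime shift:", x$shift, "\n")
  invisible(x)
}

#' Log-log MSD plot
#'
#' Convenience base-graphics plot of an `msd_curve` on log-log axes.
#'
#' @param x an `msd_curve`.
#' @param ... passed to [graphics::plot()].
#' @importFrom graphics plot
#' @export
plot.msd_curve <- function(x, ...) {
  ylab <- if (identical(attr(x, "transform"), "msd_over_lag")) {
    "MSD / lag (um^2/min)"
  } else "MSD (um^2)"
  graphics::plot(x$lag, x$msd, log = "xy", xlab = "lag (min)", ylab = ylab, ...)
  invisible(x)
}
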