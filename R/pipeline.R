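# End-to-end orchestration: a declarative analysis configuration, a runner
# that produces per-cohort statistics, MSD reports and comparisons, and a
# fully reproducible on-disk report (stats/, msd/, compare/, manifest.json).

#' Build an analysis configuration
#'
#' @param cohorts named list; each element is either
#'   `list(path = <track CSV>, dialect = "plain")` or
#'   `list(spec = cohort_spec(...))` for simulation. A cohort whose points
#'   carry both `"pre"` and `"post"` epoch labels is analyzed per epoch.
#' @param filter list: `min_points`, `max_gap` (see [filter_tracks()]).
#' @param grid grid size (um) for [distinct_sites_visited()].
#' @param window optional local-displacement window (min) added to the
#'   stats tables.
#' @param msd list: `max_lag_fraction`, `min_pairs`, `weighting`,
#'   `thresholds`, `se_aware` (see [ensemble_msd()] and
#'   [fit_anomalous_exponent()]).
#' @param comparisons list of comparison plans:
#'   `list(kind = "epochs", cohort =, metric =, variant =)`,
#'   `list(kind = "unpaired", a =, b =, metric =, variant =)` (two cohort
#'   names) or `list(kind = "paired_intensity", path = <CSV>)`.
#' @param out_dir report directory (created on write).
#' @param seed integer recorded in the provenance block; simulation seeds
#'   live inside each `cohort_spec`.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(cohorts, filter = list(min_points = 5, max_gap = 2),
                            grid = 10, window = NULL,
                            msd = list(max_lag_fraction = 0.25, min_pairs = 10,
                                       weighting = "pairs",
                                       thresholds = c(0.9, 1.1), se_aware = FALSE),
                            comparisons = list(), out_dir = NULL, seed = 1) {
  if (!is.list(cohorts) || length(cohorts) == 0 || is.null(names(cohorts)) ||
      any(!nzchar(names(cohorts)))) {
    ivm_stop("ivm_config", "cohorts must be a non-empty named list")
  }
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    has_path <- !is.null(co$path); has_spec <- !is.null(co$spec)
    if (has_path == has_spec) {
      ivm_stop("ivm_config",
               paste0("cohort '", nm, "' needs exactly one of path or spec"))
    }
    if (has_spec && !inherits(co$spec, "cohort_spec")) {
      ivm_stop("ivm_config", paste0("cohort '", nm, "': spec is not a cohort_spec"))
    }
  }
  defaults <- list(max_lag_fraction = 0.25, min_pairs = 10, weighting = "pairs",
                   thresholds = c(0.9, 1.1), se_aware = FALSE)
  msd <- utils::modifyList(defaults, msd)
  filter <- utils::modifyList(list(min_points = 5, max_gap = 2), filter)
  structure(list(cohorts = cohorts, filter = filter, grid = grid,
                 window = window, msd = msd, comparisons = comparisons,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

# Deterministic full-precision CSV writer (same conventions as write_tracks).
write_csv17 <- function(df, path) {
  cols <- lapply(names(df), function(nm) {
    if (is.numeric(df[[nm]])) num17(df[[nm]]) else rfc4180(df[[nm]])
  })
  lines <- c(paste(rfc4180(names(df)), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

write_json_det <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

comparison_as_list <- function(cr) {
  out <- unclass(cr)
  out
}

alpha_fit_as_list <- function(fit) unclass(fit)

# Strip classes recursively so a config echoes cleanly into JSON.
config_as_list <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, config_as_list)
    attributes(x) <- list(names = names(x))
  }
  x
}

load_cohort <- function(name, co, verbose) {
  if (!is.null(co$path)) {
    read_tracks(co$path, dialect = if (is.null(co$dialect)) "plain" else co$dialect,
                verbose = verbose)
  } else {
    simulate_cohort(co$spec)
  }
}

#' Run a configured analysis
#'
#' Executes the full pipeline for every cohort in the configuration:
#' load or simulate tracks, quality-filter, per-track statistics, ensemble
#' TA-MSD with exponent fit (per epoch when the cohort carries pre/post
#' labels, including the regime-shift statement), then the planned
#' comparisons. The run is deterministic given the configuration
#' (simulation seeds are part of each `cohort_spec`), so identical configs
#' yield byte-identical reports. When writing, all files are staged and
#' copied into `out_dir` only after every stage has succeeded, so a failed
#' run leaves no partial output.
#'
#' Report layout on disk: `stats/<cohort>[.<epoch>].csv`,
#' `msd/<cohort>[.<epoch>]_{msd.csv,fit.json}`,
#' `msd/<cohort>_report.json`, `compare/<k>_<kind>.json`,
#' `compare/summary.csv`, `manifest.json` (config echo, package version,
#' seed, per-file MD5 hashes).
#'
#' @param config an [analysis_config()].
#' @param write write the report to `config$out_dir` (default: only if an
#'   output directory is configured).
#' @param verbose log stage counts to standard error.
#' @return A list of class `analysis_report`: `stats` (named tables),
#'   `msd` (per-cohort curves/fits or `msd_report`s), `comparisons`,
#'   `provenance`.
#' @export
run_analysis <- function(config, write = !is.null(config$out_dir), verbose = FALSE) {
  if (!inherits(config, "analysis_config")) {
    ivm_stop("ivm_config", "config must be an analysis_config()")
  }
  # configuration errors surface before any computation
  for (nm in names(config$cohorts)) {
    p <- config$cohorts[[nm]]$path
    if (!is.null(p) && !file.exists(p)) {
      ivm_stop("ivm_config", paste0("cohort '", nm, "': input path not found: ", p))
    }
  }
  for (cp in config$comparisons) {
    if (identical(cp$kind, "paired_intensity") && !file.exists(cp$path)) {
      ivm_stop("ivm_config", paste0("paired_intensity input not found: ", cp$path))
    }
  }
  if (write && is.null(config$out_dir)) {
    ivm_stop("ivm_config", "write = TRUE requires config$out_dir")
  }

  m <- config$msd
  stats_tables <- list()
  msd_results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ivm_stop("ivm_stage_error", paste0("[", name, "] ", conditionMessage(e)))
    })
  }

  for (nm in names(config$cohorts)) {
    ts <- stage(paste0("load:", nm),
                load_cohort(nm, config$cohorts[[nm]], verbose))
    paired <- "epoch" %in% names(ts) && all(c("pre", "post") %in% unique(ts$epoch))
    if (paired) {
      eps <- list(pre = epoch_subset(ts, "pre"), post = epoch_subset(ts, "post"))
      eps <- lapply(eps, function(e) {
        stage(paste0("filter:", nm),
              filter_tracks(e, config$filter$min_points, config$filter$max_gap,
                            verbose = verbose))
      })
      for (ep in names(eps)) {
        stats_tables[[paste0(nm, ".", ep)]] <-
          stage(paste0("stats:", nm, ".", ep),
                cohort_stats_table(eps[[ep]], grid = config$grid,
                                   window = config$window))
      }
      msd_results[[nm]] <- stage(paste0("msd:", nm),
        cohort_msd_report(eps$pre, eps$post,
                          max_lag_fraction = m$max_lag_fraction,
                          min_pairs = m$min_pairs, weighting = m$weighting,
                          thresholds = m$thresholds, se_aware = m$se_aware))
    } else {
      tsf <- stage(paste0("filter:", nm),
                   filter_tracks(ts, config$filter$min_points, config$filter$max_gap,
                                 verbose = verbose))
      stats_tables[[nm]] <- stage(paste0("stats:", nm),
        cohort_stats_table(tsf, grid = config$grid, window = config$window))
      msd <- stage(paste0("msd:", nm),
        ensemble_msd(tsf, m$max_lag_fraction, m$min_pairs, m$weighting))
      msd_results[[nm]] <- list(
        msd = msd, over_lag = msd_over_lag(msd),
        fit = fit_anomalous_exponent(msd, thresholds = m$thresholds,
                                     se_aware = m$se_aware))
    }
  }

  comparisons <- list()
  for (k in seq_along(config$comparisons)) {
    cp <- config$comparisons[[k]]
    variant <- if (is.null(cp$variant)) "student" else cp$variant
    res <- stage(paste0("compare:", k), switch(cp$kind,
      epochs = compare_epochs(stats_tables[[paste0(cp$cohort, ".pre")]],
                              stats_tables[[paste0(cp$cohort, ".post")]],
                              metric = cp$metric, variant = variant),
      unpaired = compare_unpaired(stats_tables[[cp$a]][[cp$metric]],
                                  stats_tables[[cp$b]][[cp$metric]],
                                  variant = variant,
                                  group_names = c(cp$a, cp$b)),
      paired_intensity = compare_paired(read_cluster_intensity(cp$path)),
      ivm_stop("ivm_config", paste0("unknown comparison kind: ", cp$kind))))
    comparisons[[k]] <- list(plan = cp, result = res)
  }

  config_echo <- unclass(config)
  config_echo$out_dir <- NULL  # the analysis is independent of where it lands
  report <- structure(
    list(stats = stats_tables, msd = msd_results, comparisons = comparisons,
         provenance = list(config = config_as_list(config_echo),
                           package_version = as.character(utils::packageVersion("ivmtracks")),
                           seed = config$seed)),
    class = "analysis_report")
  if (write) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  stage_dir <- tempfile("ivm-report-")
  for (d in c("stats", "msd", "compare")) {
    dir.create(file.path(stage_dir, d), recursive = TRUE)
  }
  for (nm in names(report$stats)) {
    write_csv17(report$stats[[nm]], file.path(stage_dir, "stats", paste0(nm, ".csv")))
  }
  for (nm in names(report$msd)) {
    r <- report$msd[[nm]]
    if (inherits(r, "msd_report")) {
      for (ep in c("pre", "post")) {
        write_csv17(as.data.frame(r[[ep]]$msd),
                    file.path(stage_dir, "msd", paste0(nm, ".", ep, "_msd.csv")))
        write_json_det(alpha_fit_as_list(r[[ep]]$fit),
                       file.path(stage_dir, "msd", paste0(nm, ".", ep, "_fit.json")))
      }
      write_json_det(list(shift = r$shift,
                          pre_regime = r$pre$fit$regime,
                          post_regime = r$post$fit$regime),
                     file.path(stage_dir, "msd", paste0(nm, "_report.json")))
    } else {
      write_csv17(as.data.frame(r$msd),
                  file.path(stage_dir, "msd", paste0(nm, "_msd.csv")))
      write_json_det(alpha_fit_as_list(r$fit),
                     file.path(stage_dir, "msd", paste0(nm, "_fit.json")))
    }
  }
  if (length(report$comparisons) > 0) {
    summ <- list()
    for (k in seq_along(report$comparisons)) {
      cr <- report$comparisons[[k]]
      write_json_det(list(plan = config_as_list(cr$plan),
                          result = comparison_as_list(cr$result)),
                     file.path(stage_dir, "compare",
                               sprintf("%02d_%s.json", k, cr$plan$kind)))
      r <- cr$result
      summ[[k]] <- data.frame(comparison = k, kind = cr$plan$kind,
                              group_a = r$group_names[1], group_b = r$group_names[2],
                              n_a = r$n_per_group[1], n_b = r$n_per_group[2],
                              mean_a = r$means[1], mean_b = r$means[2],
                              test = r$test_name, statistic = r$statistic,
                              df = r$degrees_of_freedom, p_value = r$p_value,
                              stars = r$stars)
    }
    write_csv17(do.call(rbind, summ), file.path(stage_dir, "compare", "summary.csv"))
  }
  rel <- sort(list.files(stage_dir, recursive = TRUE))
  hashes <- unname(tools::md5sum(file.path(stage_dir, rel)))
  write_json_det(list(config = report$provenance$config,
                      package_version = report$provenance$package_version,
                      seed = report$provenance$seed,
                      files = as.list(stats::setNames(hashes, rel))),
                 file.path(stage_dir, "manifest.json"))
  # stage complete: move into place
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in sort(list.files(stage_dir, recursive = TRUE))) {
    dest <- file.path(out_dir, f)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    file.copy(file.path(stage_dir, f), dest, overwrite = TRUE)
  }
  unlink(stage_dir, recursive = TRUE)
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %d stats table(s), %d MSD result(s), %d comparison(s)\n",
              length(x$stats), length(x$msd), length(x$comparisons)))
  for (nm in names(x$msd)) {
    r <- x$msd[[nm]]
    if (inherits(r, "msd_report")) {
      cat(sprintf("  %s: regime shift %s\n", nm, r$shift))
    } else {
      cat(sprintf("  %s: alpha = %.3f (%s)\n", nm, r$fit$alpha, r$fit$regime))
    }
  }
  for (cr in x$comparisons) {
    r <- cr$result
    cat(sprintf("  %s vs %s (%s): p = %.4g %s\n", r$group_names[1],
                r$group_names[2], r$test_name, r$p_value, r$stars))
  }
  invisible(x)
}

#' Demonstration configurations
#'
#' Ready-made paired pre/post-drug scenarios with known ground truth:
#'
#' * `"aml-like"`: both epochs share a Brownian generator — speed and
#'   diffusive regime unchanged by the drug, emulating parenchymal AML
#'   cells whose migration is CXCR4-independent.
#' * `"tall-like"`: the post epoch switches to a slower ballistic
#'   generator — mean speed drops while the exponent rises to 2,
#'   emulating the chemoresistant T-ALL shift to superdiffusive motion
#'   under CXCR4 antagonism.
#'
#' Both use the default imaging design (3-min frames; 90-min pre epoch;
#' 180-min post epoch after a 15-min injection gap), 3D positions,
#' localization noise of 0.3 um and an illustrative mobilized fraction of
#' 0.25, and compare per-track mean speed between epochs.
#'
#' @param scenario `"aml-like"` or `"tall-like"`.
#' @param n_tracks cells per cohort.
#' @param seed master seed.
#' @param out_dir optional report directory.
#' @return An [analysis_config()] accepted by [run_analysis()].
#' @export
make_demo_config <- function(scenario = c("aml-like", "tall-like"),
                             n_tracks = 150, seed = 1, out_dir = NULL) {
  scenario <- match.arg(scenario)
  pre_model <- motion_model("brownian", D = 0.5)
  post_model <- switch(scenario,
    "aml-like" = pre_model,
    "tall-like" = motion_model("ballistic", speed = 0.3))
  spec <- cohort_spec(design = imaging_design(), dims = 3, n_tracks = n_tracks,
                      pre_model = pre_model, post_model = post_model,
                      mobilized_fraction = 0.25, noise_sd = 0.3, seed = seed)
  analysis_config(
    cohorts = stats::setNames(list(list(spec = spec)), scenario),
    comparisons = list(list(kind = "epochs", cohort = scenario,
                            metric = "mean_speed", variant = "student")),
    out_dir = out_dir, seed = seed)
}
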