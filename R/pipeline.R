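#' Experiment configuration
#'
#' Bundles everything needed to process a whole experiment: the test
#' protocol, analysis conventions, a drag baseline, and per-group trace
#' and geometry files.  All referenced paths are checked at
#' construction time, before any computation.
#'
#' @param groups Named list; each element is a list with `traces` and
#'   `geometries` (equal-length character vectors of file paths).
#' @param baseline Path to the drag-baseline trace CSV (or NULL).
#' @param protocol A [test_protocol()].
#' @param area_convention `"minimum"` (default) or `"mean"`.
#' @param stress_convention `"engineering"` (default) or `"true"`.
#' @param stats_method `"kw"` (default), `"anova"` or `"auto"`.
#' @param peak_smooth_s UTS peak smoothing, seconds (default 0).
#' @param seed Integer seed recorded in the report.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(groups, baseline = NULL,
                              protocol = test_protocol(),
                              area_convention = c("minimum", "mean"),
                              stress_convention = c("engineering", "true"),
                              stats_method = c("kw", "anova", "auto"),
                              peak_smooth_s = 0, seed = 1L) {
  area_convention <- match.arg(area_convention)
  stress_convention <- match.arg(stress_convention)
  stats_method <- match.arg(stats_method)
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("groups must be a named list with unique labels")
  for (lab in names(groups)) {
    grp <- groups[[lab]]
    if (length(grp$traces) != length(grp$geometries))
      stop(sprintf("group '%s': traces and geometries differ in length", lab))
    missing <- c(grp$traces, grp$geometries)
    missing <- missing[!file.exists(missing)]
    if (length(missing))
      stop(sprintf("group '%s': missing file(s): %s", lab,
                   paste(missing, collapse = ", ")))
  }
  if (!is.null(baseline) && !file.exists(baseline))
    stop("missing baseline file: ", baseline)
  structure(list(groups = groups, baseline = baseline, protocol = protocol,
                 area_convention = area_convention,
                 stress_convention = stress_convention,
                 stats_method = stats_method,
                 peak_smooth_s = peak_smooth_s, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Simulate a whole cohort to disk
#'
#' Writes per-specimen trace CSVs and geometry YAMLs plus one drag
#' baseline under `dir`, and returns a ready [experiment_config()].
#' Specimen moduli and strengths are drawn per group around the stated
#' means (10 % between-specimen CV).
#'
#' @param group_params Named list; each element a list with
#'   `linear_modulus` and `uts` (MPa group means), optional
#'   `toe_strain`.
#' @param n_per_group Rings per group.
#' @param dir Output directory (created).
#' @param protocol A [test_protocol()].
#' @param seed Integer seed.
#' @param noise_sd Load noise, mN (default 5).
#' @param drag_amplitude Drag, mN (default 2).
#' @param specimen_cv Between-specimen CV of modulus/strength (0.10).
#' @param ... Passed to [experiment_config()].
#' @return An `experiment_config`.
#' @export
simulate_cohort <- function(group_params, n_per_group, dir,
                            protocol = test_protocol(), seed = 1L,
                            noise_sd = 5, drag_amplitude = 2,
                            specimen_cv = 0.10, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  baseline <- gen_drag_baseline(protocol, drag_amplitude, seed = seed,
                                noise_sd = 0)
  bl_path <- file.path(dir, "baseline.csv")
  write_trace(baseline, bl_path)
  groups <- list()
  spec_seed <- seed
  for (lab in names(group_params)) {
    gp <- group_params[[lab]]
    toe <- if (is.null(gp$toe_strain)) 0.04 else gp$toe_strain
    traces <- geoms <- character(n_per_group)
    for (i in seq_len(n_per_group)) {
      spec_seed <- spec_seed + 1L
      fac <- withr::with_seed(spec_seed * 2L + 1L,
        stats::rnorm(2, 1, specimen_cv))
      E <- max(0.5, gp$linear_modulus * fac[1])
      uts <- max(0.1, gp$uts * fac[2])
      if (uts <= E * toe / 2) uts <- E * toe / 2 * 1.5
      w <- withr::with_seed(spec_seed * 2L, stats::runif(4, 0.55, 0.75))
      geom <- specimen_geometry(widths = w, heights = 0.9 * w)
      params <- constitutive_params(E, uts, toe_strain = toe,
                                    noise_sd = noise_sd,
                                    drag_amplitude = drag_amplitude,
                                    seed = spec_seed)
      tr <- gen_trace(params, geom, protocol)
      tr$specimen_id <- sprintf("%s_%02d", lab, i)
      traces[i] <- file.path(dir, sprintf("%s_%02d_trace.csv", lab, i))
      geoms[i] <- file.path(dir, sprintf("%s_%02d_geom.yaml", lab, i))
      write_trace(tr, traces[i])
      yaml::write_yaml(list(widths_mm = geom$widths,
                            heights_mm = geom$heights,
                            ring_diameter_mm = geom$ring_diameter), geoms[i])
    }
    groups[[lab]] <- list(traces = traces, geometries = geoms)
  }
  experiment_config(groups, baseline = bl_path, protocol = protocol,
                    seed = seed, ...)
}

#' Run a whole experiment
#'
#' Processes every specimen trace into mechanical endpoints, compares
#' groups per endpoint, computes the Spearman correlation matrix over
#' the endpoints, and assembles a structured report.  Specimens that
#' fail validation are excluded and logged; specimens without a
#' detected failure event are retained (flagged) for MTM but excluded
#' from UTS / failure-strain statistics.  More than 50 % exclusions is
#' a hard error.
#'
#' @param config An [experiment_config()].
#' @return Object of class `experiment_result`: `summary` (per-specimen
#'   data.frame), `comparisons` (named list of `group_comparison` per
#'   endpoint), `correlations` (`correlation_matrix`), `report` (list),
#'   `log` (character vector of decisions/exclusions).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  baseline <- if (is.null(config$baseline)) NULL
              else read_trace(config$baseline, is_baseline = TRUE)
  log <- c(sprintf("ringmech %s", as.character(utils::packageVersion("ringmech"))),
           sprintf("area_convention=%s stress_convention=%s stats_method=%s peak_smooth_s=%g seed=%d",
                   config$area_convention, config$stress_convention,
                   config$stats_method, config$peak_smooth_s, config$seed))
  rows <- list(); n_total <- 0L; n_excluded <- 0L
  for (lab in names(config$groups)) {
    grp <- config$groups[[lab]]
    for (i in seq_along(grp$traces)) {
      n_total <- n_total + 1L
      res <- tryCatch({
        tr <- read_trace(grp$traces[i])
        geom <- read_geometry(grp$geometries[i])
        row <- analyze_trace(tr, baseline, geom, config$protocol,
                             area_convention = config$area_convention,
                             stress_convention = config$stress_convention,
                             peak_smooth_s = config$peak_smooth_s)
        row$group <- lab
        row
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_excluded <- n_excluded + 1L
        log <- c(log, sprintf("EXCLUDED %s: %s", grp$traces[i],
                              conditionMessage(res)))
      } else {
        if (!res$failure_detected)
          log <- c(log, sprintf("FLAGGED %s: no failure event; kept for MTM only",
                                res$specimen_id))
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  if (n_excluded > 0.5 * n_total)
    stop(sprintf("more than half of specimens excluded (%d of %d); aborting",
                 n_excluded, n_total))
  if (length(rows) == 0) stop("no specimens analyzed")
  summary_df <- do.call(rbind, rows)

  endpoints <- c(uts_mpa = "uts_mpa", mtm_mpa = "mtm_mpa",
                 failure_strain = "failure_strain")
  comparisons <- list()
  for (ep in endpoints) {
    df <- data.frame(group = summary_df$group, value = summary_df[[ep]])
    if (ep != "mtm_mpa") df <- df[summary_df$failure_detected, , drop = FALSE]
    comparisons[[ep]] <- tryCatch(
      compare_groups(df, method = config$stats_method),
      error = function(e) {
        log <<- c(log, sprintf("STATS SKIPPED %s: %s", ep, conditionMessage(e)))
        NULL
      })
  }
  comparisons <- Filter(Negate(is.null), comparisons)

  corr_vars <- c("uts_mpa", "mtm_mpa", "failure_strain", "a0_mm2")
  correlations <- spearman_matrix(summary_df[summary_df$failure_detected,
                                             corr_vars, drop = FALSE])

  report <- list(version = as.character(utils::packageVersion("ringmech")),
                 config_hash = hash_config(config),
                 n_specimens = n_total, n_excluded = n_excluded,
                 area_convention = config$area_convention,
                 stress_convention = config$stress_convention,
                 stats_method = config$stats_method,
                 peak_smooth_s = config$peak_smooth_s,
                 onset_threshold_N = 0.005,
                 window_strain = 0.08,
                 alpha = 0.05,
                 seed = config$seed)
  structure(list(summary = summary_df, comparisons = comparisons,
                 correlations = correlations, report = report, log = log),
            class = "experiment_result")
}

# md5 of the serialized config (paths + conventions)
hash_config <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(config), tf, version = 2)
  unname(tools::md5sum(tf))
}

#' Write experiment results to a directory
#'
#' Produces `summary.csv`, `stats.json`, `correlations.csv`,
#' `report.md` and `log.txt`.  Re-running with the same config and
#' seed reproduces these files byte for byte.
#'
#' @param result An [run_experiment()] result.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_experiment_results <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  stats_out <- lapply(result$comparisons, function(cmp) {
    list(method = cmp$method, statistic = cmp$statistic,
         p_value = cmp$p_value,
         pairwise_p = as.data.frame(cmp$pairwise_p),
         letters = as.list(cmp$letters), alpha = cmp$alpha)
  })
  jsonlite::write_json(stats_out, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(result$correlations$rho),
                   file.path(dir, "correlations.csv"))
  rep <- result$report
  lines <- c("# Experiment report", "",
             sprintf("- package version: %s", rep$version),
             sprintf("- config hash: %s", rep$config_hash),
             sprintf("- specimens: %d (%d excluded)", rep$n_specimens, rep$n_excluded),
             sprintf("- conventions: %s area, %s stress", rep$area_convention,
                     rep$stress_convention),
             sprintf("- statistics: %s (alpha = %g)", rep$stats_method, rep$alpha),
             sprintf("- onset threshold: %g N; tangent window: %g strain",
                     rep$onset_threshold_N, rep$window_strain),
             sprintf("- peak smoothing: %g s", rep$peak_smooth_s),
             sprintf("- seed: %d", rep$seed))
  writeLines(lines, file.path(dir, "report.md"))
  writeLines(result$log, file.path(dir, "log.txt"))
  invisible(dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment: %d specimens analyzed (%d excluded), %d endpoint comparisons\n",
              nrow(x$summary), x$report$n_excluded, length(x$comparisons)))
  for (ep in names(x$comparisons)) {
    cmp <- x$comparisons[[ep]]
    cat(sprintf("  %-15s %s p = %.3g, letters: %s\n", ep, cmp$method,
                cmp$p_value,
                paste(sprintf("%s=%s", names(cmp$letters), cmp$letters),
                      collapse = " ")))
  }
  invisible(x)
}
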