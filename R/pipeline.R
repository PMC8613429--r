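#' Default pipeline run configuration
#'
#' One nested list with a section per stage. Unknown keys anywhere are
#' rejected before any stage runs; every random draw flows from the single
#' `seed` through fixed per-stage offsets recorded in the manifest.
#'
#' @param ... overrides, e.g. `run_config(seed = 7, simulate =
#'   list(n_control = 4))`.
#' @return validated nested list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = "typetrail_run",
    tz = "UTC",
    simulate = list(),            # generator_config() overrides
    features = list(cutoff = 8, min_transitions = 20L, min_keypresses = 20L,
                    min_tests = 6L, categories = "all"),
    assemble = list(period1_days = c(1L, 17L), period2_days = c(45L, 56L),
                    study_start_date = NULL, z_score_dummies = TRUE,
                    practice_units = "calendar"),
    model = list(models = c(1L, 2L, 3L), re_covariance = "unstructured",
                 restarts = 5L, tol = 1e-8),
    reliability = list(alpha = 0.05),
    report = list())
  user <- list(...)
  for (sec in intersect(names(user),
                        c("simulate", "features", "assemble", "model",
                          "reliability", "report"))) {
    if (sec == "simulate") {
      cfg$simulate <- user$simulate   # validated by generator_config later
    } else {
      cfg[[sec]] <- merge_options(cfg[[sec]], user[[sec]],
                                  paste0("config$", sec))
    }
    user[[sec]] <- NULL
  }
  cfg <- merge_options(cfg, user, "config")
  structure(cfg, class = "run_config")
}

stage_runner <- function(name, log, fun) {
  t0 <- Sys.time()
  res <- tryCatch(fun(), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log(sprintf("stage %-11s done in %.2f s", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the analysis pipeline end to end
#'
#' Stages: `simulate` (synthetic cohort to CSV), `features` (windows and
#' median IKD), `assemble` (model table), `model` (forward-fitted mixed
#' models, Wald tables, likelihood-ratio comparisons), `reliability` (ICCs
#' and paired t-tests) and `report` (human-readable summary and plots).
#' Each stage writes its artifact into `config$out_dir` plus a run log with
#' row counts in/out, drop reasons, seeds and resolved options; identical
#' config and seed give identical artifacts. On real data, skip `simulate`
#' and place the cohort CSVs in `out_dir` beforehand.
#'
#' @param config a [run_config()].
#' @param stages which stages to execute, in pipeline order.
#' @return the manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "features", "assemble",
                                    "model", "reliability", "report")) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  manifest <- list(seed = config$seed, stages = stages,
                   options = unclass(config), files = list(), counts = list())

  if ("simulate" %in% stages) {
    stage_runner("simulate", log, function() {
      gcfg <- do.call(generator_config,
                      c(config$simulate, list(seed = config$seed)))
      cohort <- generate_cohort(gcfg)
      paths <- write_cohort(cohort, config$out_dir)
      manifest$files$cohort <<- unname(paths)
      manifest$counts$subjects <<- nrow(cohort$roster)
      manifest$counts$keypresses <<- nrow(cohort$keypresses)
      manifest$counts$dtmt_records <<- nrow(cohort$dtmt)
      manifest$counts$mood_ratings <<- nrow(cohort$mood)
    })
  }

  cohort <- NULL
  get_cohort <- function() {
    if (is.null(cohort)) cohort <<- read_cohort(config$out_dir)
    cohort
  }

  if ("features" %in% stages) {
    stage_runner("features", log, function() {
      co <- get_cohort()
      fo <- config$features
      win <- build_windows(co$dtmt, config$tz)
      win <- compute_window_features(win, co$keypresses, cutoff = fo$cutoff,
                                     min_transitions = fo$min_transitions,
                                     categories = fo$categories)
      path <- file.path(config$out_dir, "windows.csv")
      write_windows(win, path)
      manifest$files$windows <<- path
      manifest$counts$windows <<- nrow(win)
      manifest$counts$windows_with_median_ikd <<- sum(!is.na(win$median_ikd_s))
    })
  }

  if ("assemble" %in% stages) {
    stage_runner("assemble", log, function() {
      co <- get_cohort()
      fo <- config$features
      win <- read_windows(file.path(config$out_dir, "windows.csv"))
      filt <- apply_inclusion_filters(win, fo$min_keypresses, fo$min_tests)
      for (nm in names(attr(filt, "drop_log"))) {
        log(sprintf("filter %s: %s", nm, attr(filt, "drop_log")[[nm]]))
      }
      ao <- config$assemble
      ao$tz <- config$tz
      tab <- build_model_table(filt$windows, co$dtmt, co$mood, co$roster, ao)
      dl <- attr(tab, "drop_log")
      log(sprintf("assemble: rows in %d, dropped (no IKD) %d, dropped (no mood) %d, rows out %d",
                  dl$rows_in, dl$dropped_missing_ikd, dl$dropped_missing_mood,
                  dl$rows_out))
      path <- file.path(config$out_dir, "model_table.csv")
      write_csv_exact(tab, path)
      manifest$files$model_table <<- path
      manifest$counts$model_rows <<- nrow(tab)
      manifest$counts$model_subjects <<- length(unique(tab$subject_id))
    })
  }

  if ("model" %in% stages) {
    stage_runner("model", log, function() {
      tab <- read_csv_checked(file.path(config$out_dir, "model_table.csv"),
                              c("subject_id", "log_dtmt_time"), "model table")
      mo <- config$model
      specs <- model_specs(mo$re_covariance)[paste0("model", mo$models)]
      needs_ymrs <- any(mo$models >= 4)
      fit_tab <- if (needs_ymrs) tab[!is.na(tab$ymrs_grand_z), ] else tab
      ff <- forward_fit(fit_tab, specs,
                        list(restarts = mo$restarts, tol = mo$tol,
                             seed = config$seed + 1000L))
      write_fits_json(ff, file.path(config$out_dir, "fits.json"))
      write_model_comparison(ff, file.path(config$out_dir,
                                           "model_comparison.csv"))
      write_coefficients(ff, file.path(config$out_dir, "coefficients.csv"))
      manifest$files$model <<- file.path(config$out_dir,
                                         c("fits.json", "model_comparison.csv",
                                           "coefficients.csv"))
      manifest$counts$models_fit <<- length(ff$fits)
    })
  }

  if ("reliability" %in% stages) {
    stage_runner("reliability", log, function() {
      co <- get_cohort()
      if (is.null(co$ptmt)) stop("no ptmt.csv with paper-test scores")
      rel <- reliability_report(co$dtmt, co$ptmt, config$reliability$alpha)
      write_csv_exact(rel$icc, file.path(config$out_dir, "reliability.csv"))
      write_csv_exact(rel$ttests, file.path(config$out_dir, "ttests.csv"))
      manifest$files$reliability <<- file.path(config$out_dir,
                                               c("reliability.csv",
                                                 "ttests.csv"))
    })
  }

  if ("report" %in% stages) {
    stage_runner("report", log, function() {
      path <- make_report(config$out_dir)
      manifest$files$report <<- path
    })
  }

  log_path <- file.path(config$out_dir, "run_log.json")
  jsonlite::write_json(list(seed = config$seed, log = log_lines),
                       log_path, auto_unbox = TRUE, pretty = TRUE)
  manifest$files$run_log <- log_path
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(manifest)
}

fit_to_list <- function(fit) {
  list(fixed_terms = fit$spec$fixed_terms,
       beta = as.list(fit$beta),
       se = as.list(stats::setNames(fit$se, names(fit$beta))),
       p = as.list(stats::setNames(fit$p_values, names(fit$beta))),
       re_cov = unclass(fit$re_cov),
       random_terms = fit$spec$random_terms,
       re_structure = fit$fallback %||% fit$spec$re_covariance,
       sigma2 = fit$sigma2,
       loglik = fit$loglik,
       deviance = fit$deviance,
       r2_marginal = fit$r2_marginal,
       r2_conditional = fit$r2_conditional,
       converged = fit$converged,
       n_obs = fit$n_obs, n_subjects = fit$n_subjects,
       n_params = fit$n_params)
}

write_fits_json <- function(ff, path) {
  jsonlite::write_json(lapply(ff$fits, fit_to_list), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

write_model_comparison <- function(ff, path) {
  dev <- vapply(ff$fits, function(f) f$deviance, numeric(1))
  df <- data.frame(model = names(ff$fits),
                   deviance = dev,
                   chi_square = c(NA, vapply(ff$lrt, `[[`, numeric(1),
                                             "chi_square")),
                   df_change = c(NA, vapply(ff$lrt, `[[`, numeric(1),
                                            "df_change")),
                   p_value = c(NA, vapply(ff$lrt, `[[`, numeric(1),
                                          "p_value")))
  write_csv_exact(df, path)
}

write_coefficients <- function(ff, path) {
  rows <- lapply(names(ff$fits), function(nm) {
    tab <- wald_fixed_effects(ff$fits[[nm]])
    tab$model <- nm
    tab
  })
  df <- do.call(rbind, rows)[, c("model", "term", "estimate", "se", "z", "p")]
  write_csv_exact(df, path)
}
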