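#' Read and write mortality-schedule CSVs
#'
#' The schedule dialect is a headed CSV with columns `age,qx` and optional
#' `exposure,deaths`, period decimal separator, UTF-8; lines starting with
#' `#` are provenance comments and ignored.  Rows are normalised to
#' ascending age on read; duplicate ages, probabilities outside `(0, 1)`
#' and `deaths > exposure` are reported with their row numbers and fail
#' hard.
#'
#' @param path File path.
#' @param schedule A [mortality_schedule].
#' @param comment Optional provenance comment line written above the
#'   header.
#' @return `read_schedule()`: a validated [mortality_schedule].
#'   `write_schedule()`: `path`, invisibly.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("age", "qx") %in% names(df))) {
    stop("schedule CSV must have columns age,qx: ", path)
  }
  problems <- character()
  if (anyNA(df$age) || any(df$age <= 0)) {
    problems <- c(problems, paste0("non-positive or missing age at row(s) ",
      paste(utils::head(which(is.na(df$age) | df$age <= 0), 5L), collapse = ", ")))
  }
  if (anyDuplicated(df$age)) {
    problems <- c(problems, paste0("duplicate age at row(s) ",
      paste(utils::head(which(duplicated(df$age)), 5L), collapse = ", ")))
  }
  bad_q <- which(is.na(df$qx) | df$qx <= 0 | df$qx >= 1)
  if (length(bad_q)) {
    problems <- c(problems, paste0("qx outside (0,1) at row(s) ",
      paste(utils::head(bad_q, 5L), collapse = ", ")))
  }
  if (!is.null(df$deaths) && !is.null(df$exposure)) {
    bad_d <- which(df$deaths > df$exposure)
    if (length(bad_d)) {
      problems <- c(problems, paste0("deaths > exposure at row(s) ",
        paste(utils::head(bad_d, 5L), collapse = ", ")))
    }
  }
  if (length(problems)) {
    stop("invalid schedule ", path, ":\n  ", paste(problems, collapse = "\n  "))
  }
  df <- df[order(df$age), , drop = FALSE]
  mortality_schedule(df$age, df$qx, exposure = df$exposure,
                     deaths = df$deaths)
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path, comment = NULL) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(as.data.frame(schedule), con, row.names = FALSE)
  invisible(path)
}

run_config_defaults <- function() {
  list(
    schedule_path = NULL,       # NULL: simulate with the synthetic block
    out_dir = ".",
    loss = "relative_sse",
    mode = "replication",
    grid = "quarterly",
    age_start = 45,
    age_end = 86,
    l0 = 160000,
    exposure_per_age = 1e4,
    gdp_per_capita = 17347,
    retirement_age = 67,
    currency = "EUR",
    age_of_diagnosis = 45,
    delay = 0,
    delay_unit = "years",
    health_policy = 0,
    delays = NULL,              # optional sweep, years
    bootstrap_replicates = 0,   # 0: skip the bootstrap
    seed = 1L,
    mean_age_rule = "death_weighted",
    truncate_yppll = TRUE,
    verbose = TRUE
  )
}

#' Pipeline run configuration
#'
#' Builds (or reads from a flat YAML file) the configuration of
#' [run_pipeline()].  Unknown keys are errors, so a misspelled
#' `retirement_age` cannot silently fall back to its default.  The
#' defaults reproduce the package's replication setting: reference
#' parameters as fitting start and synthetic truth, quarterly grid on
#' 45-86, initial cohort 160,000, retirement at 67, GDP per capita
#' 17,347, replication-mode propagation, bands 45-84.
#'
#' @param ... Named overrides of the default keys (see
#'   `run_config_defaults` in the source for the full list).
#' @param path For `read_run_config()`, a YAML file of flat key-value
#'   pairs.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(override)] <- override
  if (!is.null(cfg$schedule_path) && !file.exists(cfg$schedule_path)) {
    stop("schedule_path does not exist: ", cfg$schedule_path)
  }
  cfg$loss <- match.arg(cfg$loss, hp_loss_names())
  cfg$mode <- match.arg(cfg$mode, c("replication", "actuarial"))
  cfg$grid <- match.arg(cfg$grid, c("quarterly", "daily", "annual"))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(unclass(cfg))), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full delayed-access burden pipeline
#'
#' Orchestrates the stages: obtain a mortality schedule (read from
#' `schedule_path`, or simulated from the synthetic block of the config),
#' thin a daily grid to quarters, fit the HP law, optionally bootstrap,
#' propagate the cohort under the policy scenario, band the deaths, and
#' compute YLL, YPPLL and CPL (plus a delay sweep when `delays` is set).
#' Artifacts written to `out_dir`: `fit.json`, `lifetable.csv`,
#' `burden.csv`, `burden.json`, optionally `sweep.csv`, and `run_log.txt`
#' recording the seed, mode, package version and config hash.  Every CSV
#' and JSON artifact carries the config hash as provenance.  A stage
#' failure aborts with the stage name; artifacts already written are left
#' in place and the log flags the run incomplete.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with `fit`, `bootstrap` (or `NULL`),
#'   `report`, `sweep` (or `NULL`), `schedule` and `paths`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stamp <- paste0("hpburden config ", hash)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (isTRUE(config$verbose)) message(line)
  }
  cat("", file = log_path)
  logf("run start: seed %d, mode %s, loss %s, hpburden %s, config %s",
       config$seed, config$mode, config$loss,
       as.character(utils::packageVersion("hpburden")), hash)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf("run INCOMPLETE at stage '%s': %s", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  schedule <- stage("schedule", {
    if (!is.null(config$schedule_path)) {
      read_schedule(config$schedule_path)
    } else {
      simulate_schedule(synthetic_config(
        age_start = config$age_start, age_end = config$age_end,
        grid = config$grid, exposure_per_age = config$exposure_per_age,
        l0 = config$l0, seed = config$seed))
    }
  })
  if (max(diff(schedule$age)) < 0.25 - 1e-9) {
    schedule <- stage("quarterly_retention", to_quarterly_grid(schedule))
    logf("daily grid thinned to %d quarterly ages", nrow(schedule))
  }

  fit <- stage("fit", fit_hp(schedule, loss = config$loss))
  logf("fit: loss %.6g, converged %s, deviance %.4g (df %d, p %.4g)",
       fit$loss_value, fit$converged, fit$deviance, fit$df, fit$gof_pvalue)

  boot <- NULL
  if (config$bootstrap_replicates >= 100) {
    # sub-seed stream: seed + 1 is reserved for the bootstrap stage
    boot <- stage("bootstrap",
                  bootstrap_fit(schedule, loss = config$loss,
                                n_replicates = config$bootstrap_replicates,
                                seed = config$seed + 1L))
  }
  write_fit_report(fit, file.path(config$out_dir, "fit.json"),
                   bootstrap = boot, comment = stamp)

  scenario <- policy_scenario(config$age_of_diagnosis, delay = config$delay,
                              health_policy = config$health_policy,
                              delay_unit = config$delay_unit)
  report <- stage("burden", burden_report(
    fit$params, scenario, economics = economic_params(
      gdp_per_capita = config$gdp_per_capita,
      retirement_age = config$retirement_age,
      currency = config$currency),
    end_age = config$age_end, step = grid_step(config$grid), l0 = config$l0,
    mode = config$mode, mean_age_rule = config$mean_age_rule,
    truncate = config$truncate_yppll))
  logf("burden: YLL %.3f, YPPLL %.3f, CPL %.2f %s",
       report$yll_total, report$yppll_total, report$cpl_total,
       config$currency)

  stage("artifacts", {
    write_life_table(report$trajectory,
                     file.path(config$out_dir, "lifetable.csv"),
                     comment = stamp)
    write_burden_report(report,
                        csv_path = file.path(config$out_dir, "burden.csv"),
                        json_path = file.path(config$out_dir, "burden.json"),
                        comment = stamp)
  })

  sweep <- NULL
  if (!is.null(config$delays)) {
    sweep <- stage("sweep", delay_sweep(
      fit$params, scenario, delays = config$delays,
      economics = economic_params(gdp_per_capita = config$gdp_per_capita,
                                  retirement_age = config$retirement_age,
                                  currency = config$currency),
      end_age = config$age_end, step = grid_step(config$grid),
      l0 = config$l0, mode = config$mode,
      mean_age_rule = config$mean_age_rule,
      truncate = config$truncate_yppll))
    stage("artifacts", {
      con <- file(file.path(config$out_dir, "sweep.csv"), "w",
                  encoding = "UTF-8")
      writeLines(paste0("# ", stamp), con)
      utils::write.csv(as.data.frame(sweep), con, row.names = FALSE)
      close(con)
    })
  }
  logf("run complete")
  invisible(list(fit = fit, bootstrap = boot, report = report, sweep = sweep,
                 schedule = schedule,
                 paths = file.path(config$out_dir,
                                   c("fit.json", "lifetable.csv", "burden.csv",
                                     "burden.json", "run_log.txt"))))
}
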