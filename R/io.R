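# On-disk conventions: TSV for tables, JSON for structured results, YAML for
# configuration; all times on disk are in seconds, all rates per minute.

#' Write / read regional TAC tables
#'
#' TSV with columns `subject`, `region`, `frame_start_s`, `frame_dur_s`,
#' `activity_kBq_mL`. Reading validates the frame bookkeeping: frames must be
#' contiguous within each (subject, region) series and every region of a
#' subject must share one schedule.
#'
#' @param tacs a data frame in the column layout above (e.g. from
#'   [cohort_tacs]).
#' @param path file path.
#' @return `read_tac_table` returns a list with `tacs` (named list per
#'   subject of named lists per region of frame TACs) and `schedules` (named
#'   list per subject of [frame_schedule]).
#' @export
write_tac_table <- function(tacs, path) {
  need <- c("subject", "region", "frame_start_s", "frame_dur_s", "activity_kBq_mL")
  stopifnot(all(need %in% names(tacs)))
  write.table(tacs[need], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tac_table
#' @export
read_tac_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("subject", "region", "frame_start_s", "frame_dur_s", "activity_kBq_mL")
  if (!all(need %in% names(df)))
    stop("TAC table must have columns: ", paste(need, collapse = ", "))
  df$row <- seq_len(nrow(df)) + 1L  # file row numbers (header is row 1)
  tacs <- list()
  schedules <- list()
  for (subj in unique(df$subject)) {
    dsub <- df[df$subject == subj, ]
    sched <- NULL
    tacs[[subj]] <- list()
    for (rg in unique(dsub$region)) {
      dreg <- dsub[dsub$region == rg, ]
      gap <- dreg$frame_start_s[-1] -
        (dreg$frame_start_s[-nrow(dreg)] + dreg$frame_dur_s[-nrow(dreg)])
      if (nrow(dreg) > 1 && any(abs(gap) > 1e-6)) {
        bad <- which(abs(gap) > 1e-6)[1] + 1L
        stop(sprintf("non-contiguous frames for subject %s, region %s at file row %d (frame %d)",
                     subj, rg, dreg$row[bad], bad))
      }
      s <- frame_schedule(dreg$frame_dur_s, dreg$frame_start_s)
      if (is.null(sched)) sched <- s
      else if (nrow(s) != nrow(sched) || any(abs(s$start_s - sched$start_s) > 1e-6) ||
               any(abs(s$dur_s - sched$dur_s) > 1e-6))
        stop(sprintf("mixed frame schedules within subject %s (region %s)", subj, rg))
      tacs[[subj]][[rg]] <- dreg$activity_kBq_mL
    }
    schedules[[subj]] <- sched
  }
  list(tacs = tacs, schedules = schedules)
}

#' Write / read blood data tables
#'
#' Long TSV with columns `subject`, `series`, `time_s`, `value`, where
#' `series` is one of `whole_blood`, `p2wb_ratio`, `parent_fraction`.
#'
#' @param bloods named list of [blood_data] (names are subject ids), or a
#'   single `blood_data` (written under subject `"s1"`).
#' @param path file path.
#' @return `read_blood_tsv` returns a named list of [blood_data].
#' @export
write_blood_tsv <- function(bloods, path) {
  if (inherits(bloods, "blood_data")) bloods <- list(s1 = bloods)
  rows <- lapply(names(bloods), function(id) {
    b <- bloods[[id]]
    rbind(data.frame(subject = id, series = "whole_blood",
                     time_s = b$wb_time * 60, value = b$wb_activity),
          data.frame(subject = id, series = "p2wb_ratio",
                     time_s = b$sample_time * 60, value = b$plasma_to_wb_ratio),
          data.frame(subject = id, series = "parent_fraction",
                     time_s = b$sample_time * 60, value = b$parent_fraction))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_blood_tsv
#' @export
read_blood_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  need <- c("subject", "series", "time_s", "value")
  if (!all(need %in% names(df)))
    stop("blood table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (subj in unique(df$subject)) {
    d <- df[df$subject == subj, ]
    wb <- d[d$series == "whole_blood", ]
    rt <- d[d$series == "p2wb_ratio", ]
    pf <- d[d$series == "parent_fraction", ]
    if (!isTRUE(all.equal(rt$time_s, pf$time_s)))
      stop("ratio and parent-fraction samples must share times (subject ", subj, ")")
    out[[subj]] <- blood_data(wb_time = wb$time_s / 60, wb_activity = wb$value,
                              sample_time = rt$time_s / 60,
                              plasma_to_wb_ratio = rt$value,
                              parent_fraction = pf$value)
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' Emits `tacs.tsv`, `blood.tsv`, `truth.json` (ground-truth parameters for
#' recovery tests) and `config.yaml` into `dir`.
#'
#' @param cohort a [generate_cohort] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tac_table(cohort_tacs(cohort), file.path(dir, "tacs.tsv"))
  bloods <- setNames(lapply(cohort$subjects, `[[`, "blood"),
                     vapply(cohort$subjects, `[[`, "", "id"))
  write_blood_tsv(bloods, file.path(dir, "blood.tsv"))
  jsonlite::write_json(cohort_truth(cohort), file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  cfg <- unclass(cohort$config)
  cfg$seed <- cohort$seed
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Study configuration
#'
#' Bundles the cohort generator configuration, the fit options, the candidate
#' model list and the analysis model driving [run_pipeline]. Round-trips
#' losslessly through YAML via [write_study_config] / [read_study_config].
#'
#' @param cohort an [effect_config].
#' @param fit a [fit_options].
#' @param models names of the candidate models fitted for model selection
#'   (default all seven).
#' @param analysis_model the model whose regional estimates feed the group
#'   statistics.
#' @param seed integer seed for the whole pipeline.
#' @return a list of class `study_config`.
#' @export
study_config <- function(cohort = effect_config(), fit = fit_options(),
                         models = names(all_model_specs()),
                         analysis_model = "2T4k_VB", seed = 1) {
  vapply(models, function(m) model_name(parse_model_name(m)), "")
  parse_model_name(analysis_model)
  structure(list(cohort = cohort, fit = fit, models = models,
                 analysis_model = analysis_model, seed = seed),
            class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`.
#' @param path YAML file path.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- list(cohort = unclass(config$cohort),
            fit = unclass(config$fit),
            models = config$models,
            analysis_model = config$analysis_model,
            seed = config$seed)
  x$fit$fix_vb <- x$fit$fix_vb %||% "free"
  x$fit$seed <- x$fit$seed %||% "none"
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  fit <- x$fit
  if (identical(fit$fix_vb, "free")) fit$fix_vb <- NULL
  if (identical(fit$seed, "none")) fit$seed <- NULL
  study_config(cohort = do.call(effect_config, x$cohort),
               fit = do.call(fit_options, fit),
               models = x$models, analysis_model = x$analysis_model,
               seed = x$seed)
}
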