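#' Run the full study pipeline
#'
#' Simulate -> fit -> select -> compare. Generates the synthetic cohort,
#' tallies AIC model preference per subject on the volume-weighted whole-brain
#' TAC across the configured candidate models, fits the analysis model to
#' every regional TAC, and computes the group statistics: genotype contrasts,
#' patient-vs-control comparisons per region within genotype, the paired
#' lesion vs non-lesional white matter test, and the lesion-on-NAWM
#' regression for both outcome measures. No multiple-comparison correction is
#' applied anywhere, and the report says so.
#'
#' @param config a [study_config].
#' @param out optional output directory; when given, the cohort, the result
#'   tables (TSV), the full report (JSON) and a human-readable `report.txt`
#'   are written there.
#' @return a list of class `study_report` with elements `model_preference`,
#'   `regional_fits`, `group_tables`, `genotype_ratios`, `group_tests`,
#'   `lesion`, `notes` and `session`.
#' @export
run_pipeline <- function(config = study_config(), out = NULL) {
  stopifnot(inherits(config, "study_config"))
  cohort <- generate_cohort(config$cohort, seed = config$seed)
  specs <- lapply(config$models, parse_model_name)
  fopts <- config$fit
  if (is.null(fopts$seed)) fopts$seed <- config$seed + 1000L

  # model preference on the volume-weighted whole-brain TAC, one per subject
  pref <- lapply(seq_along(cohort$subjects), function(i) {
    s <- cohort$subjects[[i]]
    tac <- aggregate_rois(lapply(s$regions, `[[`, "tac"),
                          vapply(s$regions, function(r) unname(r$volume_cm3), 0))
    inp <- build_plasma_input(s$blood)
    fits <- lapply(seq_along(specs), function(j) {
      o <- fopts
      o$seed <- fopts$seed + i * 100L + j
      fit_model(tac, inp, specs[[j]], cohort$schedule, o)
    })
    sel <- select_model(fits)
    data.frame(subject = s$id, preferred = sel$name)
  })
  pref <- do.call(rbind, pref)
  tally <- as.data.frame(table(preferred = pref$preferred),
                         responseName = "n_subjects")

  # regional fits with the analysis model
  aspec <- parse_model_name(config$analysis_model)
  ropts <- fopts
  ropts$seed <- fopts$seed + 10000L
  res <- fit_cohort(cohort, aspec, ropts)

  has_bp <- aspec$family == "2T4k"
  measures <- if (has_bp) c("vt", "bpnd") else
    if (aspec$family == "1T2k") "vt" else "ki"

  group_tables <- lapply(setNames(measures, measures), function(v) {
    agg <- aggregate(res[[v]],
                     by = list(region = res$region, group = res$group,
                               genotype = res$genotype),
                     FUN = mean, na.rm = TRUE)
    names(agg)[4] <- paste0("mean_", v)
    agg
  })

  genotype_ratios <- lapply(setNames(intersect(measures, c("vt", "bpnd")),
                                     intersect(measures, c("vt", "bpnd"))),
                            function(v) genotype_contrast(res, v))

  # patient vs control within genotype, per region and measure (Mann-Whitney)
  group_tests <- list()
  for (v in intersect(measures, c("vt", "bpnd"))) {
    for (gt in unique(res$genotype)) {
      for (rg in setdiff(unique(res$region), "t2_lesion")) {
        ms <- res[res$genotype == gt & res$region == rg & res$group == "MS", v]
        hc <- res[res$genotype == gt & res$region == rg & res$group == "HC", v]
        if (length(ms) && length(hc)) {
          cr <- mann_whitney_u(ms[!is.na(ms)], hc[!is.na(hc)])
          group_tests[[length(group_tests) + 1L]] <- data.frame(
            measure = v, genotype = gt, region = rg,
            statistic = cr$statistic, p_value = cr$p_value, method = cr$method)
        }
      }
    }
  }
  group_tests <- if (length(group_tests)) do.call(rbind, group_tests) else NULL

  # lesion vs non-lesional white matter in patients: paired test + regression
  lesion <- NULL
  if (has_bp && "t2_lesion" %in% res$region) {
    ms <- res[res$group == "MS", ]
    wide <- merge(ms[ms$region == "nawm", c("subject", "vt", "bpnd")],
                  ms[ms$region == "t2_lesion", c("subject", "vt", "bpnd")],
                  by = "subject", suffixes = c("_nawm", "_lesion"))
    lesion <- list(
      wilcoxon_bpnd = wilcoxon_signed_rank(wide$bpnd_lesion - wide$bpnd_nawm),
      wilcoxon_vt = wilcoxon_signed_rank(wide$vt_lesion - wide$vt_nawm),
      regression_bpnd = if (nrow(wide) >= 3)
        paired_regression(wide$bpnd_nawm, wide$bpnd_lesion, ids = wide$subject),
      regression_vt = if (nrow(wide) >= 3)
        paired_regression(wide$vt_nawm, wide$vt_lesion, ids = wide$subject),
      pairs = wide)
  }

  report <- structure(list(
    model_preference = tally,
    subject_preference = pref,
    regional_fits = res,
    group_tables = group_tables,
    genotype_ratios = genotype_ratios,
    group_tests = group_tests,
    lesion = lesion,
    notes = c(paste("analysis model:", config$analysis_model),
              if (!has_bp) "analysis model has no reversible specific compartment: V_T/K_i outputs only, no BP_ND",
              "p-values are not corrected for multiple comparisons"),
    session = list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("tacfit")),
                   r_version = R.version.string)),
    class = "study_report")

  if (!is.null(out)) write_report(report, cohort, out)
  report
}

#' Write a study report bundle to disk
#'
#' Writes the cohort (TSV/JSON/YAML), the regional fit table, the
#' model-preference tally, the group-test table, a structured `report.json`
#' and a human-readable `report.txt`.
#'
#' @param report a [run_pipeline] result.
#' @param cohort the [generate_cohort] result the report was computed from.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(cohort, file.path(dir, "cohort"))
  write.table(report$regional_fits, file.path(dir, "fits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$model_preference, file.path(dir, "model_preference.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$group_tests))
    write.table(report$group_tests, file.path(dir, "group_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(
    model_preference = report$model_preference,
    genotype_ratios = lapply(report$genotype_ratios, function(g)
      list(table = g$table, mean_ratio = g$mean_ratio)),
    lesion = if (!is.null(report$lesion)) list(
      wilcoxon_bpnd_p = report$lesion$wilcoxon_bpnd$p_value,
      wilcoxon_vt_p = report$lesion$wilcoxon_vt$p_value,
      regression_bpnd = unclass(report$lesion$regression_bpnd),
      regression_vt = unclass(report$lesion$regression_vt)),
    notes = report$notes, session = report$session)
  jsonlite::write_json(json, file.path(dir, "report.json"), auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  sink(con)
  print(report)
  sink()
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("== model preference (AIC, whole-brain TAC) ==\n")
  print(x$model_preference, row.names = FALSE)
  cat("\n== genotype ratios (HAB/MAB, mean over regions) ==\n")
  for (v in names(x$genotype_ratios))
    cat(sprintf("  %-5s mean ratio = %.3f\n", v, x$genotype_ratios[[v]]$mean_ratio))
  if (!is.null(x$group_tests)) {
    cat("\n== patient vs control (Mann-Whitney, per region) ==\n")
    print(x$group_tests, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$lesion)) {
    cat("\n== lesion vs non-lesional white matter (patients) ==\n")
    reg <- function(r) if (is.null(r)) "" else
      sprintf("; slope %.2f +/- %.2f, R^2 = %.3f", r$slope, r$slope_se, r$r_squared)
    cat(sprintf("  BP_ND: Wilcoxon p = %.4g%s\n",
                x$lesion$wilcoxon_bpnd$p_value, reg(x$lesion$regression_bpnd)))
    cat(sprintf("  V_T  : Wilcoxon p = %.4g%s\n",
                x$lesion$wilcoxon_vt$p_value, reg(x$lesion$regression_vt)))
  }
  cat("\nnotes:\n")
  for (n in x$notes) cat(" -", n, "\n")
  invisible(x)
}
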