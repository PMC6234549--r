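REGION_CLASSES <- c("cortical_gm", "thalamic_gm", "cerebellar_wm", "nawm",
                    "t2_lesion")

#' Cohort effect configuration
#'
#' Parameters of the synthetic study generator. The defaults emulate a
#' two-genotype (high/medium affinity binder) case-control neuroinflammation
#' study: 8 patients (4 HAB / 4 MAB) and 7 controls (3 HAB / 4 MAB), a 1.6x
#' genotype effect on both the volume of distribution and the binding
#' potential, a +30% binding-potential elevation in HAB patients' grey and
#' non-lesional white matter, and a 2.4x binding-potential elevation of T2
#' lesions over the same subject's non-lesional white matter with matched
#' volume of distribution. See the methods vignette for how each default was
#' chosen.
#'
#' @param n_ms_hab,n_ms_mab,n_hc_hab,n_hc_mab subject counts per
#'   group x genotype cell.
#' @param genotype_vt_ratio true HAB/MAB ratio of `V_T` (fold).
#' @param genotype_bpnd_ratio true HAB/MAB ratio of `BP_ND` (fold).
#' @param ms_hab_bpnd_increase fractional `BP_ND` elevation of HAB patients
#'   over HAB controls in non-lesion tissue.
#' @param lesion_bpnd_multiplier lesion `BP_ND` as a multiple of the same
#'   subject's non-lesional white matter.
#' @param noise_level fractional TAC noise SD at the peak (reference) frame.
#' @param between_subject_cv between-subject lognormal coefficient of
#'   variation applied independently to the `V_T` and `BP_ND` channels.
#' @param region_vt_jitter lognormal SD of the within-subject regional `V_T`
#'   jitter (clamped so the within-subject spread stays well below 15%).
#' @param outlier_patient give the first patient an off-trend lesion (no
#'   binding-potential elevation), emulating a regression outlier.
#' @param delay_s true blood delay in seconds applied when generating TACs.
#' @return a list of class `effect_config`.
#' @export
effect_config <- function(n_ms_hab = 4, n_ms_mab = 4, n_hc_hab = 3, n_hc_mab = 4,
                          genotype_vt_ratio = 1.6, genotype_bpnd_ratio = 1.6,
                          ms_hab_bpnd_increase = 0.30,
                          lesion_bpnd_multiplier = 2.4,
                          noise_level = 0.03, between_subject_cv = 0.02,
                          region_vt_jitter = 0.02, outlier_patient = FALSE,
                          delay_s = 0) {
  counts <- c(n_ms_hab, n_ms_mab, n_hc_hab, n_hc_mab)
  if (any(counts < 0) || any(counts != round(counts)) || sum(counts) < 1)
    stop("subject counts must be non-negative integers with at least one subject")
  if (genotype_vt_ratio <= 0 || genotype_bpnd_ratio <= 0 ||
      lesion_bpnd_multiplier <= 0)
    stop("effect ratios must be positive")
  if (noise_level < 0) stop("noise level must be non-negative")
  structure(list(n_ms_hab = n_ms_hab, n_ms_mab = n_ms_mab,
                 n_hc_hab = n_hc_hab, n_hc_mab = n_hc_mab,
                 genotype_vt_ratio = genotype_vt_ratio,
                 genotype_bpnd_ratio = genotype_bpnd_ratio,
                 ms_hab_bpnd_increase = ms_hab_bpnd_increase,
                 lesion_bpnd_multiplier = lesion_bpnd_multiplier,
                 noise_level = noise_level,
                 between_subject_cv = between_subject_cv,
                 region_vt_jitter = region_vt_jitter,
                 outlier_patient = outlier_patient,
                 delay_s = delay_s),
            class = "effect_config")
}

# Ground-truth anchor: medium-affinity-binder non-lesional white matter.
# Plausible values for a second-generation TSPO tracer; no absolute rate
# constants are asserted against literature (see methods vignette).
ANCHOR <- list(K1 = 0.10, k2 = 0.15, k3 = 0.04, k4 = 0.04, vb = 0.05)

# Regional delivery (blood flow) multipliers applied to K1 and k2 jointly so
# that V_T is unaffected; grey matter is better perfused than white.
DELIVERY <- c(cortical_gm = 1.4, thalamic_gm = 1.5, cerebellar_wm = 1.0,
              nawm = 1.0, t2_lesion = 1.0)

ROI_VOLUMES <- c(cortical_gm = 250, thalamic_gm = 15, cerebellar_wm = 25,
                 nawm = 350)  # cm^3, typical large-ROI sizes

#' Generate a synthetic study cohort
#'
#' Builds subjects with genotype/group labels, per-subject arterial input
#' functions (parametric bolus + ratio + parent-fraction models, sampled into
#' [blood_data]), per-region ground-truth kinetic parameters realising the
#' configured effects, and noisy frame TACs on the default 19-frame schedule
#' generated from the reversible two-tissue + blood volume model.
#' Deterministic given `seed`.
#'
#' Effect construction: the binding-potential channel scales `k3`
#' multiplicatively (genotype, disease, lesion effects); the
#' volume-of-distribution channel scales the non-displaceable volume `K1/k2`
#' through `K1`, with the genotype `K1` multiplier solved so the configured
#' `V_T` ratio holds exactly despite the `k3` change. Disease effects (the
#' diffuse patient elevation and the lesion multiplier) raise `BP_ND` at
#' constant `V_T`: the non-displaceable volume shrinks as specific binding
#' grows, so the large non-displaceable compartment masks the disease signal
#' in `V_T` while `BP_ND` carries it in full.
#'
#' @param config an [effect_config].
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_cohort`: list with `subjects`,
#'   `schedule`, `config`, `seed`. Each subject carries `id`, `group`
#'   (`"MS"`/`"HC"`), `genotype` (`"HAB"`/`"MAB"`), `blood` ([blood_data]),
#'   `input` (the true [plasma_input]) and `regions`, each region holding
#'   `class`, `volume_cm3`, `true_params`, `vt_true`, `bpnd_true`,
#'   `tac_true` (noiseless) and `tac` (noisy).
#' @export
generate_cohort <- function(config = effect_config(), seed = 1) {
  stopifnot(inherits(config, "effect_config"))
  schedule <- default_frame_schedule()
  spec <- model_spec("2T4k", blood_volume = TRUE)
  labels <- data.frame(
    group = rep(c("MS", "MS", "HC", "HC"),
                c(config$n_ms_hab, config$n_ms_mab, config$n_hc_hab, config$n_hc_mab)),
    genotype = rep(c("HAB", "MAB", "HAB", "MAB"),
                   c(config$n_ms_hab, config$n_ms_mab, config$n_hc_hab, config$n_hc_mab)))
  bp0 <- ANCHOR$k3 / ANCHOR$k4
  # K1 multiplier giving the configured V_T ratio given the k3 change
  nd_geno <- config$genotype_vt_ratio * (1 + bp0) /
    (1 + bp0 * config$genotype_bpnd_ratio)
  subjects <- with_seed(seed, lapply(seq_len(nrow(labels)), function(i) {
    group <- labels$group[i]
    genotype <- labels$genotype[i]
    id <- sprintf("%s%02d", if (group == "MS") "P" else "C", i)
    amp <- 30 * exp(rnorm(1, 0, 0.05))
    input <- generate_feng_input(peak_amp = amp)
    blood <- sample_blood_data(input)
    vt_mult <- exp(rnorm(1, 0, config$between_subject_cv))
    bp_mult <- exp(rnorm(1, 0, config$between_subject_cv))
    vb_subj <- min(max(ANCHOR$vb * exp(rnorm(1, 0, 0.1)), 0.02), 0.1)
    is_hab <- genotype == "HAB"
    nd_subj <- (ANCHOR$K1 / ANCHOR$k2) * (if (is_hab) nd_geno else 1) * vt_mult
    bp_subj <- bp0 * (if (is_hab) config$genotype_bpnd_ratio else 1) * bp_mult
    # V_T is pinned at the genotype level: disease-related increases in
    # specific binding are absorbed by the non-displaceable volume, so the
    # large non-displaceable compartment masks them in V_T (no V_T group
    # difference), while BP_ND carries the full elevation.
    vt_subj <- nd_subj * (1 + bp_subj)
    diffuse <- if (group == "MS" && is_hab) 1 + config$ms_hab_bpnd_increase else 1
    classes <- if (group == "MS") REGION_CLASSES else setdiff(REGION_CLASSES, "t2_lesion")
    gen_input <- if (config$delay_s != 0) shift_input(input, config$delay_s) else input
    nawm_vt <- NA_real_
    regions <- list()
    for (cls in classes) {
      if (cls == "t2_lesion") {
        les_mult <- if (config$outlier_patient && i == 1) 1
                    else config$lesion_bpnd_multiplier
        bp_r <- bp_subj * diffuse * les_mult
        vt_r <- nawm_vt * runif(1, 0.96, 1.04)
        nd_r <- vt_r / (1 + bp_r)
        vol <- exp(runif(1, log(3.6), log(60.6)))
      } else {
        bp_r <- bp_subj * diffuse
        jit <- min(max(exp(rnorm(1, 0, config$region_vt_jitter)), 0.94), 1.06)
        vt_r <- vt_subj * jit
        nd_r <- vt_r / (1 + bp_r)
        if (cls == "nawm") nawm_vt <- vt_r
        vol <- ROI_VOLUMES[[cls]]
      }
      K1_r <- ANCHOR$K1 * (if (is_hab) nd_geno else 1) * vt_mult * DELIVERY[[cls]]
      pars <- kinetic_params(K1 = K1_r, k2 = K1_r / nd_r,
                             k3 = bp_r * ANCHOR$k4, k4 = ANCHOR$k4,
                             vb = vb_subj)
      tac_true <- model_tac(spec, pars, gen_input, schedule)
      tac <- add_noise(tac_true, schedule, config$noise_level)
      regions[[cls]] <- list(class = cls, volume_cm3 = vol, true_params = pars,
                             vt_true = macro_vt(spec, pars),
                             bpnd_true = macro_bpnd(pars),
                             tac_true = tac_true, tac = tac)
    }
    list(id = id, group = group, genotype = genotype, blood = blood,
         input = input, regions = regions)
  }))
  structure(list(subjects = subjects, schedule = schedule, config = config,
                 seed = seed), class = "synthetic_cohort")
}

# Sample a continuous input into measured blood data: continuous-sampler
# whole-blood grid plus the six standard manual samples.
sample_blood_data <- function(input) {
  gen <- attr(input, "generator")
  stopifnot(!is.null(gen))
  grid <- sort(unique(c(seq(0, 3, by = 1/12), seq(3.25, 10, by = 0.25),
                        seq(10.5, 60, by = 0.5))))
  manual <- c(5, 10, 20, 30, 40, 60)
  blood_data(wb_time = grid,
             wb_activity = eval_curve(input$wb, grid),
             sample_time = manual,
             plasma_to_wb_ratio = gen$ratio(manual),
             parent_fraction = gen$parent_fraction(manual))
}

#' Add count-statistics frame noise to a TAC
#'
#' Zero-mean Gaussian noise with
#' `SD_i = noise_level * sqrt(C_i * exp(lambda * t_mid,i) / duration_i) * s`,
#' where `lambda` is the isotope decay constant and the global scale `s` is
#' set so the peak-activity (reference) frame has fractional SD equal to
#' `noise_level`. Values are not clipped at zero, as in real reconstructions.
#'
#' @param tac noiseless frame TAC.
#' @param schedule its [frame_schedule].
#' @param noise_level fractional SD at the reference frame (`>= 0`).
#' @param seed optional seed; `NULL` draws from the current RNG state.
#' @param halflife_min isotope half-life in minutes.
#' @return the noisy TAC.
#' @export
add_noise <- function(tac, schedule, noise_level, seed = NULL,
                      halflife_min = F18_HALFLIFE_MIN) {
  stopifnot(inherits(schedule, "frame_schedule"), length(tac) == nrow(schedule))
  if (noise_level < 0) stop("noise level must be non-negative")
  if (noise_level == 0) return(tac)
  lambda <- log(2) / halflife_min
  raw <- sqrt(pmax(tac, 0) * exp(lambda * frame_mid(schedule, "min")) /
                (schedule$dur_s / 60))
  ref <- which.max(tac)
  if (raw[ref] <= 0) return(tac)
  s <- tac[ref] / raw[ref]
  with_seed(seed, tac + rnorm(length(tac), 0, noise_level * raw * s))
}

#' Volume-weighted ROI aggregation
#'
#' Frame-wise volume-weighted mean of several TACs sharing one schedule, used
#' to build larger composite regions.
#'
#' @param tacs list of frame TACs (equal length) or a frames x regions matrix.
#' @param volumes region volumes in cm^3 (`> 0`).
#' @return the combined frame TAC.
#' @export
aggregate_rois <- function(tacs, volumes) {
  if (is.list(tacs)) {
    len <- unique(vapply(tacs, length, 0L))
    if (length(len) != 1L)
      stop("all TACs must share the same schedule (equal frame counts)")
    tacs <- do.call(cbind, tacs)
  }
  stopifnot(is.matrix(tacs), ncol(tacs) == length(volumes))
  if (any(volumes <= 0)) stop("volumes must be positive")
  as.vector(tacs %*% (volumes / sum(volumes)))
}

#' Ground-truth table of a synthetic cohort
#'
#' @param cohort a [generate_cohort] result.
#' @return data frame with one row per subject x region: labels, volume, true
#'   rate constants and the true `V_T` and `BP_ND`.
#' @export
cohort_truth <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s) {
    do.call(rbind, lapply(s$regions, function(r) {
      data.frame(subject = s$id, group = s$group, genotype = s$genotype,
                 region = r$class, volume_cm3 = unname(r$volume_cm3),
                 K1 = r$true_params[["K1"]], k2 = r$true_params[["k2"]],
                 k3 = r$true_params[["k3"]], k4 = r$true_params[["k4"]],
                 vb = r$true_params[["vb"]], vt_true = r$vt_true,
                 bpnd_true = r$bpnd_true)
    }))
  }))
}

#' Long-format TAC table of a synthetic cohort
#'
#' @param cohort a [generate_cohort] result.
#' @param noiseless return the noiseless TACs instead of the noisy ones?
#' @return data frame with columns `subject`, `region`, `frame_start_s`,
#'   `frame_dur_s`, `activity_kBq_mL`.
#' @export
cohort_tacs <- function(cohort, noiseless = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  sch <- cohort$schedule
  do.call(rbind, lapply(cohort$subjects, function(s) {
    do.call(rbind, lapply(s$regions, function(r) {
      data.frame(subject = s$id, region = r$class,
                 frame_start_s = sch$start_s, frame_dur_s = sch$dur_s,
                 activity_kBq_mL = if (noiseless) r$tac_true else r$tac)
    }))
  }))
}

#' Fit one model across a cohort
#'
#' Fits `spec` to every (subject, region) TAC, reconstructing each subject's
#' input function from its sampled blood data by default (set
#' `input = "true"` to use the generating input directly).
#'
#' @param cohort a [generate_cohort] result.
#' @param spec a [model_spec] (default the reversible two-tissue + blood
#'   volume model).
#' @param opts a [fit_options]; when `opts$seed` is set, each fit uses a
#'   distinct seed derived from it so runs are reproducible.
#' @param subjects optional subject ids to restrict to.
#' @param regions optional region classes to restrict to.
#' @param input `"blood"` (rebuild from blood samples) or `"true"`.
#' @return data frame with one row per fit: labels, estimates, %SD of the
#'   derived macro-parameters, `vt`, `bpnd`, `rss`, `aic`, `reliable`. The
#'   full `fit_result` objects are attached as attribute `"fits"`.
#' @export
fit_cohort <- function(cohort, spec = model_spec("2T4k", blood_volume = TRUE),
                       opts = fit_options(), subjects = NULL, regions = NULL,
                       input = c("blood", "true")) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  input <- match.arg(input)
  rows <- list()
  fits <- list()
  k <- 0L
  for (s in cohort$subjects) {
    if (!is.null(subjects) && !(s$id %in% subjects)) next
    inp <- if (input == "true") s$input else build_plasma_input(s$blood)
    for (r in s$regions) {
      if (!is.null(regions) && !(r$class %in% regions)) next
      k <- k + 1L
      o <- opts
      if (!is.null(opts$seed)) o$seed <- opts$seed + k
      fit <- fit_model(r$tac, inp, spec, cohort$schedule, o)
      fits[[k]] <- fit
      est <- fit$estimates
      rows[[k]] <- data.frame(
        subject = s$id, group = s$group, genotype = s$genotype,
        region = r$class,
        K1 = if (is.null(est)) NA_real_ else est[["K1"]],
        k2 = if (is.null(est)) NA_real_ else est[["k2"]],
        k3 = if (is.null(est)) NA_real_ else est[["k3"]],
        k4 = if (is.null(est)) NA_real_ else est[["k4"]],
        vb = if (is.null(est)) NA_real_ else est[["vb"]],
        kb = if (is.null(est)) NA_real_ else est[["kb"]],
        vt = fit$derived$vt %||% NA_real_,
        bpnd = fit$derived$bpnd %||% NA_real_,
        ki = fit$derived$ki %||% NA_real_,
        vt_percent_sd = fit$derived$vt_percent_sd %||% NA_real_,
        bpnd_percent_sd = fit$derived$bpnd_percent_sd %||% NA_real_,
        rss = fit$rss, aic = fit$aic, reliable = fit$reliable)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  g <- table(vapply(x$subjects, `[[`, "", "group"),
             vapply(x$subjects, `[[`, "", "genotype"))
  cat(sprintf("synthetic cohort: %d subjects (seed %d)\n", length(x$subjects), x$seed))
  print(g)
  invisible(x)
}
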