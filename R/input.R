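#' Sampled arterial blood data
#'
#' Raw blood measurements for one scan: the continuous-sampler whole-blood
#' curve plus discrete manual samples carrying the plasma-to-whole-blood
#' ratio and the parent (unmetabolised tracer) fraction.
#'
#' @param wb_time continuous-sampler times in minutes (strictly increasing).
#' @param wb_activity whole-blood activity at those times (kBq/mL, `>= 0`).
#' @param sample_time manual sample times in minutes; the conventional scheme
#'   is 5, 10, 20, 30, 40 and 60 min.
#' @param plasma_to_wb_ratio plasma/whole-blood activity ratio per sample
#'   (`> 0`).
#' @param parent_fraction fraction of plasma activity due to parent tracer per
#'   sample, in `[0, 1]`.
#' @return an object of class `blood_data`.
#' @export
blood_data <- function(wb_time, wb_activity,
                       sample_time = c(5, 10, 20, 30, 40, 60),
                       plasma_to_wb_ratio, parent_fraction) {
  stopifnot(length(wb_time) == length(wb_activity),
            length(sample_time) == length(plasma_to_wb_ratio),
            length(sample_time) == length(parent_fraction))
  if (any(diff(wb_time) <= 0) || any(diff(sample_time) <= 0))
    stop("times must be strictly increasing within each series")
  if (any(wb_activity < 0)) stop("whole-blood activity must be non-negative")
  if (any(plasma_to_wb_ratio <= 0)) stop("plasma/whole-blood ratios must be positive")
  if (any(parent_fraction < 0 | parent_fraction > 1))
    stop("parent fractions must lie in [0, 1]")
  structure(list(wb_time = as.numeric(wb_time),
                 wb_activity = as.numeric(wb_activity),
                 sample_time = as.numeric(sample_time),
                 plasma_to_wb_ratio = as.numeric(plasma_to_wb_ratio),
                 parent_fraction = as.numeric(parent_fraction)),
            class = "blood_data")
}

#' Plasma/whole-blood ratio model
#'
#' Fits the discrete ratio samples with a straight line in time (six manual
#' samples cannot support more structure), with predictions clamped to
#' `>= 0.5`.
#'
#' @param blood a [blood_data] with at least two ratio samples.
#' @return a list with `intercept`, `slope` and `predict(t)`.
#' @export
fit_ratio_model <- function(blood) {
  stopifnot(inherits(blood, "blood_data"))
  if (length(blood$sample_time) < 2L)
    stop("at least two plasma/whole-blood ratio samples are required")
  fit <- lm(r ~ t, data = data.frame(t = blood$sample_time,
                                     r = blood$plasma_to_wb_ratio))
  b <- coef(fit)
  list(intercept = unname(b[1]), slope = unname(b[2]),
       predict = function(t) pmax(unname(b[1]) + unname(b[2]) * t, 0.5))
}

#' Correct whole blood to total plasma
#'
#' `plasma(t) = wb(t) * rho(t)` where `rho` is the fitted
#' [plasma/whole-blood ratio model][fit_ratio_model]. Returns a continuous
#' plasma curve on the whole-blood sampling grid, with the ratio model
#' attached as attribute `"ratio_model"`.
#'
#' @param blood a [blood_data].
#' @return a [pl_curve] of total plasma activity (kBq/mL).
#' @export
correct_plasma_wholeblood <- function(blood) {
  rm_ <- fit_ratio_model(blood)
  curve <- pl_curve(blood$wb_time, blood$wb_activity * rm_$predict(blood$wb_time))
  attr(curve, "ratio_model") <- rm_
  curve
}

#' Parent-fraction (metabolite) model
#'
#' Fits the measured parent fractions with a monotone Hill-type function
#' constrained to start at one:
#' `f(t) = 1 - (1 - a) * t^b / (t^b + c^b)`,
#' where `a` in `[0, 1]` is the asymptotic parent fraction, `b > 0` the
#' steepness and `c > 0` (min) the half-conversion time. The form is monotone
#' non-increasing for any admissible parameters, which guarantees a monotone
#' metabolite correction.
#'
#' @param time sample times in minutes.
#' @param fraction measured parent fractions in `[0, 1]` (at least 3 samples).
#' @return a list with `a`, `b`, `c`, `predict(t)` and the residual sum of
#'   squares `rss`.
#' @export
fit_parent_fraction <- function(time, fraction) {
  if (length(time) < 3L) stop("at least three parent-fraction samples are required")
  if (any(fraction < 0 | fraction > 1)) stop("parent fractions must lie in [0, 1]")
  hill <- function(p, t) 1 - (1 - p[1]) * t^p[2] / (t^p[2] + p[3]^p[2])
  if (sd(fraction) < 1e-12) {
    # flat measurements: degenerate fit, constant parent fraction
    a <- fraction[1]
    return(list(a = a, b = 1, c = Inf, rss = 0,
                predict = function(t) rep(a, length(t))))
  }
  res_fn <- function(p) hill(p, time) - fraction
  start <- c(a = max(min(fraction), 0), b = 1.5, c = max(median(time), 1))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = c(0, 0.05, 0.05),
                       upper = c(1, 10, 1e4), fn = res_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("parent-fraction fit failed: ", conditionMessage(e)))
  p <- fit$par
  list(a = unname(p[1]), b = unname(p[2]), c = unname(p[3]),
       rss = sum(fit$fvec^2),
       predict = function(t) {
         f <- hill(unname(p), pmax(t, 0))
         f[t <= 0] <- 1
         f
       })
}

#' Correct plasma for metabolites
#'
#' Multiplies the total-plasma curve by the fitted
#' [parent-fraction model][fit_parent_fraction] to obtain the
#' metabolite-corrected parent-plasma input `Cp(t) = plasma(t) * f(t)`.
#'
#' @param plasma a total-plasma [pl_curve] (e.g. from
#'   [correct_plasma_wholeblood]).
#' @param blood a [blood_data] providing the parent-fraction samples.
#' @return a [pl_curve] of parent-plasma activity with the fitted model
#'   attached as attribute `"parent_model"`.
#' @export
correct_metabolites <- function(plasma, blood) {
  stopifnot(inherits(plasma, "pl_curve"), inherits(blood, "blood_data"))
  pf <- fit_parent_fraction(blood$sample_time, blood$parent_fraction)
  curve <- pl_curve(plasma$time, plasma$value * pf$predict(plasma$time))
  attr(curve, "parent_model") <- pf
  curve
}

#' Build the full plasma input from blood data
#'
#' Chains the plasma/whole-blood ratio and metabolite corrections and bundles
#' the result with the whole-blood curve.
#'
#' @param blood a [blood_data].
#' @param delay_s optional delay (seconds) applied to both curves, e.g. from
#'   [estimate_delay].
#' @return a [plasma_input].
#' @export
build_plasma_input <- function(blood, delay_s = 0) {
  plasma <- correct_plasma_wholeblood(blood)
  cp <- correct_metabolites(plasma, blood)
  wb <- pl_curve(blood$wb_time, blood$wb_activity)
  input <- plasma_input(cp, wb)
  if (delay_s != 0) input <- shift_input(input, delay_s)
  input
}

#' Estimate the blood-tissue time delay
#'
#' Finds the shift of the blood curves (bounded, on a discrete grid) that
#' minimises the weighted residual sum of squares of a single-tissue + blood
#' volume model fitted to the early part of a whole-brain time-activity
#' curve. The estimated delay is meant to be determined once per scan and
#' then held fixed for all regional fits.
#'
#' @param input an undelayed [plasma_input].
#' @param tac whole-brain frame TAC (kBq/mL).
#' @param schedule the [frame_schedule] of `tac`; frames starting before
#'   `early_min` are used.
#' @param bound_s search bound in seconds (default 30; the delay grid is
#'   `[-bound_s, bound_s]`).
#' @param step_s search grid step in seconds (default 0.5).
#' @param early_min use frames starting before this time (default 5 min).
#' @return list with `delay_s`, `at_bound` (logical: solution on the search
#'   boundary) and `rss` (the profile of weighted RSS over the grid).
#' @export
estimate_delay <- function(input, tac, schedule, bound_s = 30, step_s = 0.5,
                           early_min = 5) {
  stopifnot(inherits(input, "plasma_input"), inherits(schedule, "frame_schedule"))
  if (sd(input$wb$value) < 1e-12) stop("delay undefined for a flat blood curve")
  keep <- schedule$start_s < early_min * 60
  if (sum(keep) < 4L) stop("too few early frames for delay estimation")
  sub_sched <- frame_schedule(schedule$dur_s[keep], schedule$start_s[keep])
  y <- tac[keep]
  w <- compute_weights(sub_sched)
  spec <- model_spec("1T2k", blood_volume = TRUE)
  grid <- seq(-bound_s, bound_s, by = step_s)
  rss <- rep(NA_real_, length(grid))
  par0 <- c(K1 = 0.2, k2 = 0.1, vb = 0.05)
  lower <- c(1e-4, 1e-4, 0)
  upper <- c(2, 2, 0.3)
  last <- par0
  for (i in seq_along(grid)) {
    shifted <- shift_input(input, grid[i])
    ctx <- build_tac_context(shifted, sub_sched)
    fn <- function(p) {
      p <- as.numeric(p)
      sqrt(w) * (predict_frames(spec, kinetic_params(K1 = p[1], k2 = p[2], vb = p[3]),
                                ctx) - y)
    }
    fit <- tryCatch(minpack.lm::nls.lm(par = last, lower = lower, upper = upper,
                                       fn = fn,
                                       control = minpack.lm::nls.lm.control(maxiter = 100)),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      rss[i] <- sum(fit$fvec^2)
      last <- fit$par
    }
  }
  if (all(is.na(rss))) stop("delay estimation failed: no candidate fit converged")
  best <- which.min(rss)
  list(delay_s = grid[best],
       at_bound = best == 1L || best == length(grid),
       rss = data.frame(delay_s = grid, rss = rss))
}

#' Synthetic arterial input function
#'
#' Parametric parent-plasma input with a linear rise to the peak followed by a
#' tri-exponential washout (the standard bolus shape), plus the matching
#' whole-blood curve obtained by inverting the plasma/whole-blood ratio and
#' parent-fraction models:
#' `plasma(t) = Cp(t) / f(t)`, `C_wb(t) = plasma(t) / rho(t)`.
#'
#' @param peak_time time of the plasma peak in minutes (`> 0`).
#' @param peak_amp parent-plasma activity at the peak in kBq/mL (`> 0`).
#' @param decay_rates three washout exponents in 1/min, strictly decreasing.
#' @param decay_weights mixing weights of the three exponentials (summing to
#'   one; renormalised otherwise).
#' @param parent_params Hill parent-fraction parameters `c(a, b, c)` as in
#'   [fit_parent_fraction].
#' @param ratio_params plasma/whole-blood ratio line `c(intercept, slope_per_min)`.
#' @param t_end end of the sampling grid in minutes.
#' @return a [plasma_input]; the generating component functions are attached
#'   as attribute `"generator"`.
#' @export
generate_feng_input <- function(peak_time = 0.75, peak_amp = 30,
                                decay_rates = c(4, 0.5, 0.02),
                                decay_weights = c(0.75, 0.2, 0.05),
                                parent_params = c(a = 0.45, b = 1.5, c = 25),
                                ratio_params = c(intercept = 1.2, slope = 1/300),
                                t_end = 60) {
  if (peak_amp <= 0) stop("peak amplitude must be positive")
  if (peak_time <= 0) stop("peak time must be positive")
  if (length(decay_rates) != 3L || any(decay_rates <= 0) || any(diff(decay_rates) >= 0))
    stop("decay_rates must be three positive, strictly decreasing exponents")
  w <- decay_weights / sum(decay_weights)
  cp_fun <- function(t) {
    y <- numeric(length(t))
    rise <- t >= 0 & t <= peak_time
    y[rise] <- peak_amp * t[rise] / peak_time
    late <- t > peak_time
    if (any(late)) {
      u <- t[late] - peak_time
      y[late] <- peak_amp * (w[1] * exp(-decay_rates[1] * u) +
                             w[2] * exp(-decay_rates[2] * u) +
                             w[3] * exp(-decay_rates[3] * u))
    }
    y
  }
  pf_fun <- function(t) {
    f <- 1 - (1 - parent_params[["a"]]) * pmax(t, 0)^parent_params[["b"]] /
      (pmax(t, 0)^parent_params[["b"]] + parent_params[["c"]]^parent_params[["b"]])
    f[t <= 0] <- 1
    f
  }
  ratio_fun <- function(t) pmax(ratio_params[["intercept"]] + ratio_params[["slope"]] * t, 0.5)
  # dense near the bolus, coarser later: the curves are smooth after ~10 min
  grid <- sort(unique(c(seq(0, min(3, t_end), by = 1/12),
                        seq(min(3, t_end), min(10, t_end), by = 0.25),
                        seq(min(10, t_end), t_end, by = 0.5),
                        peak_time, t_end)))
  cp <- pl_curve(grid, cp_fun(grid))
  wb <- pl_curve(grid, cp_fun(grid) / pf_fun(grid) / ratio_fun(grid))
  input <- plasma_input(cp, wb)
  attr(input, "generator") <- list(cp_fun = cp_fun, parent_fraction = pf_fun,
                                   ratio = ratio_fun, peak_time = peak_time,
                                   peak_amp = peak_amp)
  input
}
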