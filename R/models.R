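#' Compartment model specification
#'
#' The model space spans the single-tissue model (`1T2k`), the irreversible
#' (`2T3k`) and reversible (`2T4k`) two-tissue models, each with or without a
#' fractional blood volume term, plus one combined variant: the reversible
#' two-tissue model with blood volume and an additional irreversible vascular
#' trapping compartment (`2T4k_VB_1T1k`) representing slow tracer binding to
#' the vascular endothelium.
#'
#' @param family one of `"1T2k"`, `"2T3k"`, `"2T4k"`.
#' @param blood_volume include the fractional blood volume term `V_B`?
#' @param vascular_trap include the irreversible vascular trapping rate `K_b`?
#'   Only valid for the `2T4k` family with `blood_volume = TRUE`.
#' @return an object of class `model_spec`.
#' @examples
#' model_spec("2T4k", blood_volume = TRUE)
#' length(all_model_specs())  # the 7 candidate models
#' @export
model_spec <- function(family = c("1T2k", "2T3k", "2T4k"),
                       blood_volume = FALSE, vascular_trap = FALSE) {
  family <- match.arg(family)
  stopifnot(is.logical(blood_volume), is.logical(vascular_trap))
  if (vascular_trap && !(family == "2T4k" && blood_volume))
    stop("the vascular trapping component is only defined for 2T4k with blood volume")
  structure(list(family = family, blood_volume = blood_volume,
                 vascular_trap = vascular_trap), class = "model_spec")
}

#' @rdname model_spec
#' @export
all_model_specs <- function() {
  specs <- list()
  for (fam in c("1T2k", "2T3k", "2T4k"))
    for (bv in c(FALSE, TRUE))
      specs[[length(specs) + 1L]] <- model_spec(fam, bv)
  specs[[length(specs) + 1L]] <- model_spec("2T4k", TRUE, TRUE)
  names(specs) <- vapply(specs, model_name, "")
  specs
}

#' @rdname model_spec
#' @param spec a `model_spec`.
#' @export
model_name <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  nm <- spec$family
  if (spec$blood_volume) nm <- paste0(nm, "_VB")
  if (spec$vascular_trap) nm <- paste0(nm, "_1T1k")
  nm
}

#' @rdname model_spec
#' @param name a model name such as `"2T4k_VB"` or `"2T4k_VB_1T1k"`.
#' @export
parse_model_name <- function(name) {
  specs <- all_model_specs()
  if (!name %in% names(specs))
    stop(sprintf("unknown model '%s'; valid models: %s",
                 name, paste(names(specs), collapse = ", ")))
  specs[[name]]
}

#' @export
print.model_spec <- function(x, ...) {
  cat("compartment model:", model_name(x), "\n")
  invisible(x)
}

#' Kinetic rate constants
#'
#' Container for the micro-parameters of the compartment models. `K1`
#' (mL plasma / cm^3 tissue / min) is the plasma-to-tissue delivery rate,
#' `k2` (1/min) the tissue washout rate, `k3`/`k4` (1/min) the exchange rates
#' with the specifically bound compartment, `vb` the unitless fractional blood
#' volume in `[0, 1]`, and `kb` (1/min) the irreversible vascular trapping
#' rate. Parameters absent from a given model are simply ignored by it.
#'
#' @param K1,k2,k3,k4,vb,kb see description; all rates must be non-negative.
#' @return an object of class `kinetic_params` (a named numeric vector).
#' @export
kinetic_params <- function(K1 = 0, k2 = 0, k3 = 0, k4 = 0, vb = 0, kb = 0) {
  p <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vb = vb, kb = kb)
  if (anyNA(p)) stop("kinetic parameters must not be NA")
  if (any(p < 0)) stop("kinetic parameters must be non-negative")
  if (vb > 1) stop("vb is a fraction and must lie in [0, 1]")
  structure(p, class = "kinetic_params")
}

as_kinetic_params <- function(p) {
  if (inherits(p, "kinetic_params")) return(p)
  do.call(kinetic_params, as.list(p))
}

# Exponential rates and weights of the tissue impulse response
# H(t) = phi1 * exp(-a1 t) + phi2 * exp(-a2 t), the bi-exponential form of
# C_T = C1 + C2 for the two-tissue model (collapsing to one term for 1T2k).
# For non-negative rates the discriminant (k2+k3+k4)^2 - 4 k2 k4 is always
# >= 0; a repeated root is separated by a relative nudge of 1e-9, which
# perturbs the curve by far less than any fitting tolerance.
impulse_terms <- function(family, p) {
  K1 <- p[["K1"]]
  k2 <- p[["k2"]]
  if (family == "1T2k") {
    return(list(rates = k2, coefs = K1))
  }
  k3 <- p[["k3"]]
  k4 <- if (family == "2T3k") 0 else p[["k4"]]
  s <- k2 + k3 + k4
  disc2 <- s^2 - 4 * k2 * k4
  stopifnot(disc2 > -1e-12 * max(1, s^2))
  disc <- sqrt(max(disc2, 0))
  a1 <- (s - disc) / 2
  a2 <- (s + disc) / 2
  if (a2 - a1 < 1e-9 * max(1, s)) a2 <- a1 + 1e-9 * max(1, s)
  phi1 <- K1 * (k3 + k4 - a1) / (a2 - a1)
  phi2 <- K1 * (a2 - k3 - k4) / (a2 - a1)
  list(rates = c(a1, a2), coefs = c(phi1, phi2))
}

# Tissue concentration at `times` (which must include all curve knots up to
# max(times) for the convolution to be exact for the interpolated input).
ct_at <- function(family, p, times, cp_values) {
  terms <- impulse_terms(family, p)
  y <- numeric(length(times))
  for (j in seq_along(terms$rates)) {
    if (terms$coefs[j] != 0)
      y <- y + terms$coefs[j] * conv_plexp(times, cp_values, terms$rates[j])
  }
  y
}

augment_times <- function(curve, times) {
  tmax <- max(times)
  tt <- sort(unique(c(times, curve$time[curve$time <= tmax])))
  tt
}

#' Single-tissue compartment model solution
#'
#' Solves `dC1/dt = K1 Cp(t) - k2 C1(t)` for the piecewise-linear interpolant
#' of the input by exact segment-wise analytic convolution:
#' `C_T(t) = K1 int_0^t exp(-k2 (t-s)) Cp(s) ds`.
#'
#' @param params a [kinetic_params] (uses `K1`, `k2`).
#' @param input a [plasma_input] or a parent-plasma [pl_curve].
#' @param times evaluation time grid in minutes (non-empty, non-negative).
#' @return data frame with columns `time` (min) and `conc` (kBq/mL).
#' @export
solve_1t2k <- function(params, input, times) {
  solve_tissue(params, input, times, family = "1T2k")
}

#' Two-tissue compartment model solution
#'
#' Solves the coupled system `dC1/dt = K1 Cp - (k2 + k3) C1 + k4 C2`,
#' `dC2/dt = k3 C1 - k4 C2` and returns `C_T = C1 + C2`, using the
#' bi-exponential impulse response with eigen-rates
#' `a_{1,2} = ((k2+k3+k4) -/+ sqrt((k2+k3+k4)^2 - 4 k2 k4)) / 2`
#' convolved analytically with the piecewise-linear input. With
#' `reversible = FALSE` the model is the irreversible 2T3k variant (`k4 = 0`).
#'
#' @inheritParams solve_1t2k
#' @param reversible if `FALSE`, `k4` is forced to zero.
#' @return data frame with columns `time` and `conc`.
#' @export
solve_2t <- function(params, input, times, reversible = TRUE) {
  solve_tissue(params, input, times,
               family = if (reversible) "2T4k" else "2T3k")
}

solve_tissue <- function(params, input, times, family) {
  p <- as_kinetic_params(params)
  if (length(times) < 1L) stop("time grid must be non-empty")
  if (any(times < 0)) stop("time grid must be non-negative")
  times <- sort(unique(as.numeric(times)))
  cp <- if (inherits(input, "plasma_input")) input$cp else input
  stopifnot(inherits(cp, "pl_curve"))
  tt <- augment_times(cp, times)
  y <- ct_at(family, p, tt, eval_curve(cp, tt))
  data.frame(time = times, conc = y[match(times, tt)])
}

#' Irreversible vascular trapping component
#'
#' Tracer trapped irreversibly on the vascular endothelium, fed by whole
#' blood: `C_vasc(t) = K_b int_0^t C_wb(s) ds`.
#'
#' @param kb trapping rate `K_b` in 1/min (`>= 0`).
#' @param whole_blood whole-blood [pl_curve], or a [plasma_input] (its `wb`).
#' @param times evaluation grid in minutes.
#' @return data frame with columns `time` and `conc`.
#' @export
solve_vascular_trap <- function(kb, whole_blood, times) {
  if (kb < 0) stop("kb must be non-negative")
  if (length(times) < 1L) stop("time grid must be non-empty")
  wb <- if (inherits(whole_blood, "plasma_input")) whole_blood$wb else whole_blood
  stopifnot(inherits(wb, "pl_curve"))
  times <- sort(unique(as.numeric(times)))
  tt <- augment_times(wb, times)
  y <- kb * conv_plexp(tt, eval_curve(wb, tt), 0)
  data.frame(time = times, conc = y[match(times, tt)])
}

# Continuous PET signal model on an arbitrary grid (times must contain the
# input knots; cp/wb are the input curves evaluated on that grid).
signal_at <- function(spec, p, times, cp_values, wb_values,
                      vascular_within_vb = TRUE) {
  ct <- ct_at(spec$family, p, times, cp_values)
  vb <- if (spec$blood_volume) p[["vb"]] else 0
  blood <- wb_values
  if (spec$vascular_trap) {
    cv <- p[["kb"]] * conv_plexp(times, wb_values, 0)
    if (vascular_within_vb) blood <- blood + cv
    else return((1 - vb) * ct + vb * wb_values + cv)
  }
  (1 - vb) * ct + vb * blood
}

# Precompute the evaluation grid and the frame-averaging (trapezoid) matrix
# for one (input, schedule) pair so repeated model evaluations during fitting
# only pay for the convolutions.
build_tac_context <- function(input, schedule, points_per_frame = 9L) {
  stopifnot(inherits(input, "plasma_input"), inherits(schedule, "frame_schedule"))
  end_min <- max(frame_end_s(schedule)) / 60
  if (curve_end(input$cp) < end_min - 1e-9 || curve_end(input$wb) < end_min - 1e-9)
    stop("frame schedule extends beyond the support of the input curves")
  edges <- c(schedule$start_s, max(frame_end_s(schedule))) / 60
  sub <- unlist(lapply(seq_len(nrow(schedule)), function(i) {
    a <- schedule$start_s[i] / 60
    b <- frame_end_s(schedule)[i] / 60
    seq(a, b, length.out = points_per_frame)
  }))
  knots <- c(input$cp$time, input$wb$time)
  tt <- sort(unique(c(0, edges, sub, knots[knots <= end_min])))
  n <- length(tt)
  W <- matrix(0, nrow = nrow(schedule), ncol = n)
  for (i in seq_len(nrow(schedule))) {
    a <- schedule$start_s[i] / 60
    b <- frame_end_s(schedule)[i] / 60
    idx <- which(tt >= a - 1e-12 & tt <= b + 1e-12)
    dt <- diff(tt[idx])
    coefs <- c(dt / 2, 0) + c(0, dt / 2)
    W[i, idx] <- coefs / (b - a)
  }
  list(times = tt,
       cp = eval_curve(input$cp, tt),
       wb = eval_curve(input$wb, tt),
       W = W,
       schedule = schedule)
}

predict_frames <- function(spec, p, ctx, vascular_within_vb = TRUE) {
  y <- signal_at(spec, p, ctx$times, ctx$cp, ctx$wb, vascular_within_vb)
  as.vector(ctx$W %*% y)
}

#' Frame-averaged model time-activity curve
#'
#' Continuous model signal averaged over each acquisition frame. The signal is
#' `(1 - V_B) C_T(t) + V_B C_wb(t)` for models without the vascular trap; for
#' the trapping model the blood term becomes `V_B (C_wb(t) + C_vasc(t))` by
#' default (trapped activity accumulating within the vascular fraction), with
#' `vascular_within_vb = FALSE` switching to `... + V_B C_wb + C_vasc` for
#' sensitivity analyses. Frame means are computed by trapezoidal integration
#' over a refined grid containing every input knot.
#'
#' @param spec a [model_spec].
#' @param params a [kinetic_params].
#' @param input a [plasma_input] carrying both parent-plasma and whole-blood
#'   curves covering the full schedule.
#' @param schedule a [frame_schedule].
#' @param vascular_within_vb convention for the vascular trapping signal
#'   (see description).
#' @return numeric vector of frame-averaged activities (kBq/mL), one per frame.
#' @export
model_tac <- function(spec, params, input, schedule, vascular_within_vb = TRUE) {
  p <- as_kinetic_params(params)
  ctx <- build_tac_context(input, schedule)
  predict_frames(spec, p, ctx, vascular_within_vb)
}

#' Total volume of distribution
#'
#' Closed-form `V_T`: `K1/k2` for the single-tissue model and
#' `(K1/k2)(1 + k3/k4)` for the reversible two-tissue model. Undefined (`NA`,
#' with a warning) for the irreversible 2T3k family and whenever `k2` (or
#' `k4`, for 2T4k) is zero.
#'
#' @param spec a [model_spec].
#' @param params a [kinetic_params].
#' @return `V_T` in mL/cm^3, or `NA_real_` when undefined.
#' @export
macro_vt <- function(spec, params) {
  p <- as_kinetic_params(params)
  if (spec$family == "2T3k") {
    warning("V_T is undefined for the irreversible 2T3k model")
    return(NA_real_)
  }
  if (p[["k2"]] == 0) {
    warning("V_T undefined: k2 = 0")
    return(NA_real_)
  }
  if (spec$family == "1T2k") return(p[["K1"]] / p[["k2"]])
  if (p[["k3"]] > 0 && p[["k4"]] == 0) {
    warning("V_T undefined: k4 = 0 with k3 > 0")
    return(NA_real_)
  }
  bp <- if (p[["k3"]] == 0) 0 else p[["k3"]] / p[["k4"]]
  p[["K1"]] / p[["k2"]] * (1 + bp)
}

#' Non-displaceable binding potential
#'
#' `BP_ND = k3/k4`, the specific-binding outcome measure of the reversible
#' two-tissue model.
#'
#' @param params a [kinetic_params]; requires `k4 > 0` (or `k3 = 0`, where
#'   the value is zero regardless).
#' @return unitless `BP_ND`, or `NA_real_` with a warning when undefined.
#' @export
macro_bpnd <- function(params) {
  p <- as_kinetic_params(params)
  if (p[["k3"]] == 0) return(0)
  if (p[["k4"]] == 0) {
    warning("BP_ND undefined: k4 = 0")
    return(NA_real_)
  }
  p[["k3"]] / p[["k4"]]
}

#' Net influx rate of the irreversible model
#'
#' `K_i = K1 k3 / (k2 + k3)` for the 2T3k model.
#'
#' @param params a [kinetic_params]; requires `k2 + k3 > 0`.
#' @return `K_i` in mL/cm^3/min, or `NA_real_` with a warning when undefined.
#' @export
macro_ki <- function(params) {
  p <- as_kinetic_params(params)
  if (p[["k2"]] + p[["k3"]] == 0) {
    warning("K_i undefined: k2 + k3 = 0")
    return(NA_real_)
  }
  p[["K1"]] * p[["k3"]] / (p[["k2"]] + p[["k3"]])
}
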