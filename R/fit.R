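F18_HALFLIFE_MIN <- 109.77  # fluorine-18 physical half-life

#' Frame weights for the least-squares fit
#'
#' Default duration-decay scheme: `w_i` proportional to
#' `duration_i * exp(-lambda * t_mid,i)` with `lambda = ln 2 / halflife`, a
#' proxy for the (inverse-variance) count statistics of each frame, normalised
#' to mean one so that residual sums of squares are comparable across schemes.
#'
#' @param schedule a [frame_schedule].
#' @param scheme `"duration_decay"` (default) or `"uniform"`.
#' @param halflife_min isotope half-life in minutes (default the fluorine-18
#'   value, 109.77 min).
#' @param tac unused by the built-in schemes; kept so custom variance models
#'   depending on the measured TAC can share the signature.
#' @return numeric vector of weights with mean one.
#' @export
compute_weights <- function(schedule, scheme = c("duration_decay", "uniform"),
                            halflife_min = F18_HALFLIFE_MIN, tac = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  scheme <- match.arg(scheme)
  if (scheme == "uniform") return(rep(1, nrow(schedule)))
  if (halflife_min <= 0) stop("halflife must be positive")
  lambda <- log(2) / halflife_min
  w <- (schedule$dur_s / 60) * exp(-lambda * frame_mid(schedule, "min"))
  w / mean(w)
}

#' Fitting options
#'
#' @param bounds named list of `c(lower, upper)` per parameter; defaults are
#'   generous physiological envelopes: `K1`, `k2`, `k3`, `k4` in
#'   `[1e-4, 2]` (mL/cm^3/min resp. 1/min), `vb` in `[0, 0.2]`, `kb` in
#'   `[0, 0.1]` 1/min.
#' @param multistart number of Latin-hypercube starting points (>= 1); the
#'   objective of the richer models is multimodal, so several starts are
#'   needed for a reliable global optimum.
#' @param weight_scheme weighting scheme id passed to [compute_weights].
#' @param fix_vb fix the blood volume fraction to this value (e.g. `0.05`)
#'   instead of fitting it; `NULL` (default) leaves it free.
#' @param seed seed for the multistart draw; `NULL` uses the current RNG
#'   state.
#' @param vascular_within_vb signal convention for the vascular trap, see
#'   [model_tac].
#' @param halflife_min isotope half-life for the weight model.
#' @return a list of class `fit_options`.
#' @export
fit_options <- function(bounds = default_bounds(), multistart = 10,
                        weight_scheme = "duration_decay", fix_vb = NULL,
                        seed = NULL, vascular_within_vb = TRUE,
                        halflife_min = F18_HALFLIFE_MIN) {
  stopifnot(multistart >= 1)
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      stop("bounds must be finite with lower < upper: ", nm)
  }
  structure(list(bounds = bounds, multistart = as.integer(multistart),
                 weight_scheme = weight_scheme, fix_vb = fix_vb, seed = seed,
                 vascular_within_vb = vascular_within_vb,
                 halflife_min = halflife_min),
            class = "fit_options")
}

#' @rdname fit_options
#' @export
default_bounds <- function() {
  list(K1 = c(1e-4, 2), k2 = c(1e-4, 2), k3 = c(1e-4, 2), k4 = c(1e-4, 2),
       vb = c(0, 0.2), kb = c(0, 0.1))
}

free_param_names <- function(spec, fix_vb = FALSE) {
  nm <- c("K1", "k2")
  if (spec$family %in% c("2T3k", "2T4k")) nm <- c(nm, "k3")
  if (spec$family == "2T4k") nm <- c(nm, "k4")
  if (spec$blood_volume && !fix_vb) nm <- c(nm, "vb")
  if (spec$vascular_trap) nm <- c(nm, "kb")
  nm
}

full_params <- function(free, spec, opts) {
  p <- c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, vb = 0, kb = 0)
  p[names(free)] <- free
  if (spec$blood_volume && !is.null(opts$fix_vb)) p[["vb"]] <- opts$fix_vb
  structure(p, class = "kinetic_params")
}

# Latin-hypercube starts; rate parameters are drawn log-uniformly (their
# plausible values span orders of magnitude), fractions uniformly.
lhs_starts <- function(free, bounds, n, seed = NULL) {
  k <- length(free)
  u <- with_seed(seed, lhs::randomLHS(n, k))
  starts <- matrix(NA_real_, n, k, dimnames = list(NULL, free))
  for (j in seq_len(k)) {
    b <- bounds[[free[j]]]
    if (free[j] %in% c("K1", "k2", "k3", "k4")) {
      lo <- max(b[1], 1e-3)
      starts[, j] <- exp(log(lo) + u[, j] * (log(b[2]) - log(lo)))
    } else {
      starts[, j] <- b[1] + u[, j] * (b[2] - b[1])
    }
  }
  starts
}

#' Akaike information criterion for least squares
#'
#' `AIC = n ln(RSS/n) + 2p` (least-squares form, additive constants dropped);
#' no small-sample correction is applied by default, with `correct = TRUE`
#' adding the AICc term `2p(p+1)/(n-p-1)`.
#'
#' @param rss weighted residual sum of squares (`> 0`).
#' @param n number of frames.
#' @param p number of free parameters (`< n`).
#' @param correct apply the small-sample (AICc) correction?
#' @return the AIC value; `-Inf` with a warning if `rss == 0`.
#' @export
compute_aic <- function(rss, n, p, correct = FALSE) {
  stopifnot(n > p)
  if (rss < 0) stop("rss must be non-negative")
  if (rss == 0) {
    warning("rss is exactly zero; AIC is -Inf")
    return(-Inf)
  }
  aic <- n * log(rss / n) + 2 * p
  if (correct) aic <- aic + 2 * p * (p + 1) / (n - p - 1)
  aic
}

#' Fit a compartment model to a frame TAC
#'
#' Minimises the weighted residual sum of squares over the model's free
#' parameters with bounded Levenberg-Marquardt iterations from multiple
#' Latin-hypercube starting points. Parameter uncertainty (%SD) is obtained
#' from the residual-variance-scaled inverse of `J' W J` at the optimum, with
#' the %SD of derived macro-parameters (`V_T`, `BP_ND`, `K_i`) propagated by
#' the delta method. Estimates within `1e-6` of the bound range of a bound
#' are flagged as boundary solutions. Reliability combines the %SD cut-offs
#' (25% for `K1`, 50% for all other parameters) with the boundary flags, see
#' [assess_reliability].
#'
#' @param tac measured frame TAC (kBq/mL), one value per frame.
#' @param input a [plasma_input] covering the schedule.
#' @param spec a [model_spec].
#' @param schedule a [frame_schedule].
#' @param opts a [fit_options].
#' @param weights optional frame weights overriding the scheme in `opts`.
#' @return an object of class `fit_result`: a list with `spec`, `estimates`
#'   (full [kinetic_params]), `free` (names of fitted parameters),
#'   `percent_sd`, `boundary`, `rss`, `aic`, `n_frames`, `converged`,
#'   `reliable`, `reasons`, `derived` (list with `vt`, `bpnd` or `ki` and
#'   their %SD where defined), and `cov` (covariance of the free parameters).
#' @export
fit_model <- function(tac, input, spec, schedule, opts = fit_options(),
                      weights = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(opts, "fit_options"))
  n <- nrow(schedule)
  if (length(tac) != n) stop("tac length must match the schedule")
  w <- weights %||% compute_weights(schedule, opts$weight_scheme, opts$halflife_min)
  sw <- sqrt(w)
  ctx <- build_tac_context(input, schedule)
  free <- free_param_names(spec, fix_vb = !is.null(opts$fix_vb))
  lower <- vapply(free, function(nm) opts$bounds[[nm]][1], 0)
  upper <- vapply(free, function(nm) opts$bounds[[nm]][2], 0)
  resid_fn <- function(p) {
    names(p) <- free
    sw * (predict_frames(spec, full_params(p, spec, opts), ctx,
                         opts$vascular_within_vb) - tac)
  }
  mid <- c(K1 = 0.1, k2 = 0.1, k3 = 0.05, k4 = 0.05, vb = 0.05, kb = 0.005)
  starts <- rbind(pmin(pmax(mid[free], lower), upper),
                  if (opts$multistart > 1)
                    lhs_starts(free, opts$bounds, opts$multistart - 1L, opts$seed))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(spec = spec, estimates = NULL, free = free,
                          percent_sd = setNames(rep(NA_real_, length(free)), free),
                          boundary = setNames(rep(NA, length(free)), free),
                          rss = NA_real_, aic = NA_real_, n_frames = n,
                          converged = FALSE, reliable = FALSE,
                          reasons = "no start converged", derived = list(),
                          cov = NULL, weights = w),
                     class = "fit_result"))
  }
  est <- setNames(as.numeric(best$par), free)
  pfull <- full_params(est, spec, opts)
  rss <- best$deviance
  p_n <- length(free)
  aic <- suppressWarnings(compute_aic(max(rss, .Machine$double.xmin), n, p_n))
  boundary <- setNames((est - lower) < 1e-6 * (upper - lower) |
                         (upper - est) < 1e-6 * (upper - lower), free)
  # covariance from a fresh finite-difference Jacobian of the weighted
  # residuals at the optimum (independent of optimiser internals)
  J <- num_jacobian(resid_fn, est, lower, upper)
  sigma2 <- if (n > p_n) rss / (n - p_n) else NA_real_
  cov <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  percent_sd <- setNames(rep(NA_real_, p_n), free)
  if (!is.null(cov) && all(is.finite(diag(cov))) && all(diag(cov) >= 0)) {
    se <- sqrt(diag(cov))
    percent_sd <- ifelse(abs(est) > 0, 100 * se / abs(est), NA_real_)
    names(percent_sd) <- free
  } else {
    cov <- NULL
  }
  derived <- derived_macros(spec, pfull, est, cov)
  fit <- structure(list(spec = spec, estimates = pfull, free = free,
                        percent_sd = percent_sd, boundary = boundary,
                        rss = rss, aic = aic, n_frames = n, converged = TRUE,
                        reliable = NA, reasons = character(), derived = derived,
                        cov = cov, weights = w),
                   class = "fit_result")
  rel <- assess_reliability(fit)
  fit$reliable <- rel$reliable
  fit$reasons <- rel$reasons
  fit
}

num_jacobian <- function(fn, par, lower, upper, h_rel = 1e-6) {
  f0 <- fn(par)
  J <- matrix(NA_real_, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- h_rel * (upper[j] - lower[j])
    up <- par; up[j] <- min(par[j] + h, upper[j])
    dn <- par; dn[j] <- max(par[j] - h, lower[j])
    J[, j] <- (fn(up) - fn(dn)) / (up[j] - dn[j])
  }
  J
}

# Derived macro-parameters and their delta-method %SD in free-parameter space.
derived_macros <- function(spec, pfull, est, cov) {
  out <- list()
  grad_sd <- function(value, grad) {
    if (is.null(cov) || is.na(value) || value == 0) return(NA_real_)
    g <- setNames(rep(0, length(est)), names(est))
    g[names(grad)[names(grad) %in% names(est)]] <-
      grad[names(grad) %in% names(est)]
    v <- as.numeric(t(g) %*% cov %*% g)
    if (!is.finite(v) || v < 0) return(NA_real_)
    100 * sqrt(v) / abs(value)
  }
  K1 <- pfull[["K1"]]; k2 <- pfull[["k2"]]
  k3 <- pfull[["k3"]]; k4 <- pfull[["k4"]]
  if (spec$family == "2T3k") {
    ki <- suppressWarnings(macro_ki(pfull))
    out$ki <- ki
    if (!is.na(ki) && (k2 + k3) > 0) {
      out$ki_percent_sd <- grad_sd(ki, c(
        K1 = k3 / (k2 + k3),
        k2 = -K1 * k3 / (k2 + k3)^2,
        k3 = K1 * k2 / (k2 + k3)^2))
    }
  } else {
    vt <- suppressWarnings(macro_vt(spec, pfull))
    out$vt <- vt
    if (!is.na(vt) && k2 > 0) {
      if (spec$family == "1T2k") {
        out$vt_percent_sd <- grad_sd(vt, c(K1 = 1 / k2, k2 = -K1 / k2^2))
      } else if (k4 > 0) {
        bp <- k3 / k4
        out$vt_percent_sd <- grad_sd(vt, c(
          K1 = (1 + bp) / k2, k2 = -K1 * (1 + bp) / k2^2,
          k3 = K1 / (k2 * k4), k4 = -K1 * k3 / (k2 * k4^2)))
      }
    }
    if (spec$family == "2T4k") {
      bp <- suppressWarnings(macro_bpnd(pfull))
      out$bpnd <- bp
      if (!is.na(bp) && k4 > 0)
        out$bpnd_percent_sd <- grad_sd(bp, c(k3 = 1 / k4, k4 = -k3 / k4^2))
    }
  }
  if (spec$vascular_trap) out$kb <- pfull[["kb"]]
  out
}

#' Reliability gate for a fit
#'
#' A fit is reliable when every %SD is defined, `%SD(K1) <= 25`, the %SD of
#' every other fitted parameter is `<= 50`, and no estimate touches a bound.
#'
#' @param fit a [fit_model] result.
#' @param k1_cut %SD cut-off for `K1` (default 25).
#' @param other_cut %SD cut-off for the remaining parameters (default 50).
#' @return list with `reliable` (logical) and `reasons` (character vector
#'   naming the offending parameters).
#' @export
assess_reliability <- function(fit, k1_cut = 25, other_cut = 50) {
  stopifnot(inherits(fit, "fit_result"))
  reasons <- character()
  if (!isTRUE(fit$converged)) {
    return(list(reliable = FALSE, reasons = "fit did not converge"))
  }
  for (nm in fit$free) {
    psd <- fit$percent_sd[[nm]]
    cut <- if (nm == "K1") k1_cut else other_cut
    if (is.na(psd)) reasons <- c(reasons, paste0(nm, ": %SD undefined"))
    else if (psd > cut) reasons <- c(reasons, sprintf("%s: %%SD %.1f > %g", nm, psd, cut))
    if (isTRUE(fit$boundary[[nm]]))
      reasons <- c(reasons, paste0(nm, ": estimate at bound"))
  }
  list(reliable = length(reasons) == 0L, reasons = reasons)
}

#' AIC model selection
#'
#' Picks the minimum-AIC model from a set of fits of the same TAC, breaking
#' exact ties towards the model with fewer free parameters, and tabulates the
#' per-model AIC differences for model-preference tallies.
#'
#' @param fits a list of [fit_model] results for the same data.
#' @return list with `preferred` (the winning [model_spec]), `name` (its
#'   name) and `table` (data frame with model, n_par, rss, aic, delta_aic,
#'   reliable).
#' @export
select_model <- function(fits) {
  if (length(fits) < 1L) stop("at least one fit is required")
  stopifnot(all(vapply(fits, inherits, TRUE, "fit_result")))
  tab <- data.frame(
    model = vapply(fits, function(f) model_name(f$spec), ""),
    n_par = vapply(fits, function(f) length(f$free), 0L),
    rss = vapply(fits, function(f) f$rss, 0),
    aic = vapply(fits, function(f) f$aic, 0),
    reliable = vapply(fits, function(f) isTRUE(f$reliable), TRUE))
  ok <- is.finite(tab$aic) | tab$aic == -Inf
  if (!any(ok)) stop("no fit produced a usable AIC")
  amin <- min(tab$aic[ok])
  tied <- which(ok & abs(tab$aic - amin) <= 1e-9)
  best <- tied[which.min(tab$n_par[tied])]
  tab$delta_aic <- tab$aic - amin
  list(preferred = fits[[best]]$spec, name = tab$model[best], table = tab)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit:", model_name(x$spec),
      if (isTRUE(x$converged)) sprintf("(RSS %.4g, AIC %.2f)", x$rss, x$aic)
      else "(did not converge)", "\n")
  if (!is.null(x$estimates)) {
    for (nm in x$free)
      cat(sprintf("  %-3s = %.4g  (%%SD %.1f%s)\n", nm, x$estimates[[nm]],
                  x$percent_sd[[nm]],
                  if (isTRUE(x$boundary[[nm]])) ", at bound" else ""))
    if (!is.null(x$derived$vt)) cat(sprintf("  V_T  = %.4g\n", x$derived$vt))
    if (!is.null(x$derived$bpnd)) cat(sprintf("  BPnd = %.4g\n", x$derived$bpnd))
    if (!is.null(x$derived$ki)) cat(sprintf("  K_i  = %.4g\n", x$derived$ki))
  }
  cat("  reliable:", x$reliable,
      if (length(x$reasons)) paste0("(", paste(x$reasons, collapse = "; "), ")") else "", "\n")
  invisible(x)
}
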