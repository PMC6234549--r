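#' Piecewise-linear sampled curve
#'
#' Continuous curves (blood activity, plasma input) are represented by their
#' sample knots and interpolated linearly in between. A curve is zero before
#' time zero; if the first knot is after zero a `(0, 0)` knot is inserted so
#' the curve rises linearly from zero.
#'
#' @param time numeric vector of knot times (minutes), strictly increasing,
#'   all `>= 0`.
#' @param value numeric vector of curve values at the knots (kBq/mL).
#' @return an object of class `pl_curve` with elements `time` and `value`.
#' @export
pl_curve <- function(time, value) {
  stopifnot(is.numeric(time), is.numeric(value), length(time) == length(value))
  if (length(time) < 1L) stop("curve needs at least one knot")
  if (anyNA(time) || anyNA(value)) stop("curve knots must not contain NA")
  if (any(diff(time) <= 0)) stop("curve times must be strictly increasing")
  if (time[1] < 0) stop("curve times must be non-negative")
  if (time[1] > 0) {
    time <- c(0, time)
    value <- c(0, value)
  }
  structure(list(time = as.numeric(time), value = as.numeric(value)),
            class = "pl_curve")
}

#' Evaluate a piecewise-linear curve
#'
#' @param curve a [pl_curve].
#' @param t times (minutes) at which to evaluate; values before time zero are
#'   zero, values beyond the last knot hold the last value.
#' @return numeric vector of curve values.
#' @export
eval_curve <- function(curve, t) {
  stopifnot(inherits(curve, "pl_curve"))
  if (length(curve$time) == 1L) {
    y <- rep(curve$value, length(t))
  } else {
    y <- approx(curve$time, curve$value, xout = t, rule = 2)$y
  }
  y[t < 0] <- 0
  y
}

#' Shift a curve in time
#'
#' A positive shift delays the curve (it starts later); a negative shift
#' advances it, dropping whatever lay before time zero and holding the last
#' value so the support does not shrink (delay corrections are a few tens of
#' seconds against a slowly varying 60-min tail). Used for input-function
#' delay correction.
#'
#' @param curve a [pl_curve].
#' @param shift_s shift in seconds.
#' @return the shifted [pl_curve].
#' @export
shift_curve <- function(curve, shift_s) {
  stopifnot(inherits(curve, "pl_curve"))
  d <- shift_s / 60
  tt <- curve$time + d
  vv <- curve$value
  if (d >= 0) return(pl_curve(c(0, tt[tt > 0]), c(0, vv[tt > 0])))
  keep <- tt >= 0
  if (!any(keep)) stop("shift moves the whole curve before time zero")
  v0 <- approx(tt, vv, xout = 0, rule = 2)$y
  end0 <- curve_end(curve)
  tt <- c(tt[keep], end0)
  vv <- c(vv[keep], vv[length(vv)])
  if (tt[1] == 0) pl_curve(tt, vv)
  else pl_curve(c(0, tt), c(v0, vv))
}

curve_end <- function(curve) curve$time[length(curve$time)]

#' Arterial plasma input function
#'
#' Bundles the metabolite-corrected parent-plasma curve `cp` that drives the
#' tissue compartments with the whole-blood curve `wb` needed for the blood
#' volume and vascular trapping terms, plus the fitted delay.
#'
#' @param cp parent-plasma [pl_curve] (kBq/mL).
#' @param wb whole-blood [pl_curve] (kBq/mL).
#' @param delay_s delay applied to the blood curves relative to scanner time,
#'   in seconds (default 0).
#' @return an object of class `plasma_input`.
#' @export
plasma_input <- function(cp, wb, delay_s = 0) {
  stopifnot(inherits(cp, "pl_curve"), inherits(wb, "pl_curve"))
  structure(list(cp = cp, wb = wb, delay_s = delay_s), class = "plasma_input")
}

#' Apply a time shift to a plasma input
#'
#' Shifts both the parent-plasma and whole-blood curves by the same amount,
#' the operation performed by delay correction.
#'
#' @param input a [plasma_input].
#' @param shift_s shift in seconds (positive delays the input).
#' @return the shifted [plasma_input]; `delay_s` is accumulated.
#' @export
shift_input <- function(input, shift_s) {
  stopifnot(inherits(input, "plasma_input"))
  plasma_input(shift_curve(input$cp, shift_s),
               shift_curve(input$wb, shift_s),
               delay_s = input$delay_s + shift_s)
}

#' @export
print.plasma_input <- function(x, ...) {
  cat(sprintf("plasma input: %d plasma knots, %d whole-blood knots, 0-%.1f min, delay %.1f s\n",
              length(x$cp$time), length(x$wb$time),
              min(curve_end(x$cp), curve_end(x$wb)), x$delay_s))
  invisible(x)
}
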