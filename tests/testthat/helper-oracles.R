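# Independent oracles used by the tests. These deliberately do NOT share code
# with the package: the compartment oracle integrates the ODE system with
# deSolve, the rank-test oracles enumerate the null distributions by brute
# force.

# Stiff ODE integration of the full signal model for any model variant.
# cp/wb are pl_curve objects; interpolation matches the package's
# piecewise-linear convention so the two routes solve the same problem.
ode_signal <- function(spec, params, input, times) {
  cp_fun <- approxfun(input$cp$time, input$cp$value, rule = 2, yleft = 0)
  wb_fun <- approxfun(input$wb$time, input$wb$value, rule = 2, yleft = 0)
  p <- as.list(unclass(params))
  k4 <- if (spec$family == "2T3k") 0 else p$k4
  k3 <- if (spec$family == "1T2k") 0 else p$k3
  deriv <- function(t, y, parms) {
    dC1 <- p$K1 * cp_fun(t) - (p$k2 + k3) * y[1] + k4 * y[2]
    dC2 <- k3 * y[1] - k4 * y[2]
    dTr <- if (spec$vascular_trap) p$kb * wb_fun(t) else 0
    list(c(dC1, dC2, dTr))
  }
  sol <- deSolve::lsoda(c(0, 0, 0), c(0, times), deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  ct <- sol[-1, 2] + sol[-1, 3]
  vb <- if (spec$blood_volume) p$vb else 0
  blood <- wb_fun(times)
  if (spec$vascular_trap) blood <- blood + sol[-1, 4]
  (1 - vb) * ct + vb * blood
}

rel_rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to group x (tie-free inputs only).
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_obs <- sum(outer(x, y, ">"))
  idx <- utils::combn(length(pooled), m)
  us <- apply(idx, 2, function(ii) {
    xx <- pooled[ii]; yy <- pooled[-ii]
    sum(outer(xx, yy, ">"))
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign patterns
# (tie-free nonzero differences only).
wsr_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Shared fixtures ------------------------------------------------------------

feng_fixture <- function(peak_amp = 30) generate_feng_input(peak_amp = peak_amp)

constant_input <- function(value = 1, t_end = 600) {
  cv <- pl_curve(c(0, t_end), c(value, value))
  plasma_input(cv, cv)
}

# near-impulse of unit area at the origin (triangle of width 2e-4 min)
impulse_input <- function() {
  cv <- pl_curve(c(0, 1e-4, 2e-4), c(0, 1e4, 0))
  plasma_input(cv, cv)
}

random_physiological_params <- function() {
  kinetic_params(K1 = runif(1, 0.05, 0.5), k2 = runif(1, 0.05, 0.5),
                 k3 = runif(1, 0.01, 0.2), k4 = runif(1, 0.01, 0.2),
                 vb = runif(1, 0.01, 0.15), kb = runif(1, 0.001, 0.05))
}
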