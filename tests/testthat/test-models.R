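test_that("the model space has exactly seven valid specifications", {
  specs <- all_model_specs()
  expect_length(specs, 7L)
  expect_setequal(names(specs),
                  c("1T2k", "1T2k_VB", "2T3k", "2T3k_VB", "2T4k", "2T4k_VB",
                    "2T4k_VB_1T1k"))
  expect_error(model_spec("1T2k", vascular_trap = TRUE), "vascular")
  expect_error(model_spec("2T4k", blood_volume = FALSE, vascular_trap = TRUE),
               "vascular")
  expect_identical(parse_model_name("2T4k_VB_1T1k")$vascular_trap, TRUE)
})

test_that("kinetic parameters reject negative rates and invalid fractions", {
  expect_error(kinetic_params(K1 = -0.1), "non-negative")
  expect_error(kinetic_params(vb = 1.5), "fraction")
  expect_error(solve_1t2k(kinetic_params(K1 = 0.1, k2 = 0.2), feng_fixture(),
                          numeric(0)), "non-empty")
})

test_that("single-tissue solution matches closed forms", {
  # impulse response: C_T(t) = K1 exp(-k2 t) for t past the impulse width
  imp <- impulse_input()
  ct <- solve_1t2k(kinetic_params(K1 = 0.1, k2 = 0.2), imp, c(1, 5, 10))
  expect_equal(ct$conc, 0.1 * exp(-0.2 * c(1, 5, 10)), tolerance = 1e-4)
  # step input: C_T(t) = (K1/k2)(1 - exp(-k2 t)) Cp
  stp <- constant_input(2)
  ct2 <- solve_1t2k(kinetic_params(K1 = 0.1, k2 = 0.2), stp, c(2, 20, 200))
  expect_equal(ct2$conc, 2 * 0.5 * (1 - exp(-0.2 * c(2, 20, 200))),
               tolerance = 1e-12)
  # zero input gives zero output
  zero <- plasma_input(pl_curve(c(0, 60), c(0, 0)), pl_curve(c(0, 60), c(0, 0)))
  expect_equal(solve_1t2k(kinetic_params(K1 = 0.3, k2 = 0.1), zero,
                          seq(1, 60))$conc, rep(0, 60))
})

test_that("two-tissue solution nests the single-tissue model at k3 = 0", {
  inp <- feng_fixture()
  tt <- seq(0, 60, by = 0.25)
  one <- solve_1t2k(kinetic_params(K1 = 0.12, k2 = 0.15), inp, tt)$conc
  two <- solve_2t(kinetic_params(K1 = 0.12, k2 = 0.15, k3 = 0, k4 = 0.07),
                  inp, tt)$conc
  expect_lt(max(abs(one - two)), 1e-10)
})

test_that("irreversible model traps the closed-form fraction of an impulse", {
  # K1 k3/(k2+k3) of the unit bolus ends up trapped
  imp <- impulse_input()
  ct <- solve_2t(kinetic_params(K1 = 0.1, k2 = 0.1, k3 = 0.1), imp, 60,
                 reversible = FALSE)
  expect_equal(ct$conc, 0.05, tolerance = 1e-4)
})

test_that("two-tissue solution matches the ODE oracle on a realistic input", {
  inp <- feng_fixture()
  tt <- seq(0.5, 60, by = 0.5)
  p <- kinetic_params(K1 = 0.15, k2 = 0.3, k3 = 0.05, k4 = 0.02)
  mine <- solve_2t(p, inp, tt)$conc
  oracle <- ode_signal(model_spec("2T4k"), p, inp, tt)
  expect_lt(rel_rms(mine, oracle), 1e-3)
})

test_that("vascular trapping integrates whole blood", {
  # constant whole blood 1: C_vasc(T) = Kb T; ramp t on [0,10]: Kb * 50
  const <- pl_curve(c(0, 60), c(1, 1))
  expect_equal(solve_vascular_trap(0.01, const, c(10, 60))$conc, c(0.1, 0.6))
  ramp <- pl_curve(c(0, 10), c(0, 10))
  expect_equal(solve_vascular_trap(0.02, ramp, 10)$conc, 1.0)
  expect_equal(solve_vascular_trap(0, feng_fixture(), c(1, 30))$conc, c(0, 0))
  expect_error(solve_vascular_trap(-0.1, const, 10), "non-negative")
})

test_that("model TACs respect the blood-volume limits and preserve constants", {
  sch <- default_frame_schedule()
  inp <- feng_fixture()
  p <- kinetic_params(K1 = 0.1, k2 = 0.15, k3 = 0.04, k4 = 0.04, vb = 1)
  full_blood <- model_tac(model_spec("2T4k", TRUE), p, inp, sch)
  ctx_wb <- model_tac(model_spec("1T2k", TRUE),
                      kinetic_params(K1 = 0, k2 = 0.1, vb = 1), inp, sch)
  expect_equal(full_blood, ctx_wb, tolerance = 1e-12)  # both = frame-avg blood
  p0 <- kinetic_params(K1 = 0.1, k2 = 0.15, k3 = 0.04, k4 = 0.04, vb = 0)
  no_blood <- model_tac(model_spec("2T4k", TRUE), p0, inp, sch)
  bare <- model_tac(model_spec("2T4k", FALSE), p0, inp, sch)
  expect_equal(no_blood, bare, tolerance = 1e-12)
  cst <- constant_input(5, t_end = 60)
  flat <- model_tac(model_spec("1T2k", TRUE),
                    kinetic_params(K1 = 0, k2 = 0.1, vb = 1), cst, sch)
  expect_equal(flat, rep(5, 19))
})

test_that("a schedule extending beyond the input support is rejected", {
  short <- plasma_input(pl_curve(c(0, 30), c(0, 1)), pl_curve(c(0, 30), c(0, 1)))
  expect_error(model_tac(model_spec("1T2k"), kinetic_params(K1 = 0.1, k2 = 0.1),
                         short, default_frame_schedule()), "support")
})

test_that("model TACs are linear in the input and non-negative", {
  sch <- default_frame_schedule()
  set.seed(11)
  for (i in 1:5) {
    p <- random_physiological_params()
    inp <- feng_fixture()
    dbl <- plasma_input(pl_curve(inp$cp$time, 2 * inp$cp$value),
                        pl_curve(inp$wb$time, 2 * inp$wb$value))
    for (spec in all_model_specs()[c("1T2k_VB", "2T3k_VB", "2T4k_VB_1T1k")]) {
      a <- model_tac(spec, p, inp, sch)
      b <- model_tac(spec, p, dbl, sch)
      expect_equal(b, 2 * a, tolerance = 1e-12)
      expect_true(all(a >= 0))
    }
  }
})

test_that("reversible models approach V_T at quasi-equilibrium", {
  stp <- constant_input(1, t_end = 1500)
  for (p in list(kinetic_params(K1 = 0.1, k2 = 0.15, k3 = 0.04, k4 = 0.04),
                 kinetic_params(K1 = 0.3, k2 = 0.2, k3 = 0.1, k4 = 0.05))) {
    vt <- macro_vt(model_spec("2T4k"), p)
    eq <- solve_2t(p, stp, 1500)$conc
    expect_equal(eq, vt, tolerance = 0.01)
  }
})

test_that("macro-parameters follow their closed forms and degenerate cases", {
  expect_equal(macro_vt(model_spec("2T4k"),
                        kinetic_params(K1 = 0.1, k2 = 0.1, k3 = 0.05, k4 = 0.05)), 2)
  expect_equal(macro_vt(model_spec("1T2k"), kinetic_params(K1 = 0.2, k2 = 0.1)), 2)
  expect_equal(macro_vt(model_spec("2T4k"),
                        kinetic_params(K1 = 0.2, k2 = 0.1, k3 = 0, k4 = 0.05)), 2)
  expect_warning(v <- macro_vt(model_spec("2T3k"),
                               kinetic_params(K1 = 0.1, k2 = 0.1, k3 = 0.1)),
                 "undefined")
  expect_true(is.na(v))
  expect_warning(macro_vt(model_spec("1T2k"), kinetic_params(K1 = 0.1, k2 = 0)),
                 "k2")
  expect_equal(macro_bpnd(kinetic_params(k3 = 0.05, k4 = 0.05)), 1)
  expect_equal(macro_bpnd(kinetic_params(k3 = 0, k4 = 0)), 0)
  expect_equal(macro_bpnd(kinetic_params(k3 = 0.06, k4 = 0.04)), 1.5)
  expect_warning(b <- macro_bpnd(kinetic_params(k3 = 0.1, k4 = 0)), "k4")
  expect_true(is.na(b))
  expect_equal(macro_ki(kinetic_params(K1 = 0.1, k2 = 0.1, k3 = 0.1)), 0.05)
  expect_equal(macro_ki(kinetic_params(K1 = 0.2, k2 = 0.3, k3 = 0.1)), 0.05)
  expect_equal(macro_ki(kinetic_params(K1 = 0.1, k2 = 0.2, k3 = 0)), 0)
})
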