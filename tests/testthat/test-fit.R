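test_that("frame weights follow the duration-decay scheme", {
  sch <- frame_schedule(c(60, 240))
  # negligible decay: weights proportional to duration, mean one
  expect_equal(compute_weights(sch, halflife_min = 1e12), c(0.4, 1.6))
  expect_equal(compute_weights(sch, scheme = "uniform"), c(1, 1))
  w <- compute_weights(default_frame_schedule())
  expect_equal(mean(w), 1)
  expect_gt(w[19], w[1])  # 600 s frame outweighs 15 s despite decay
  expect_error(compute_weights(sch, halflife_min = 0), "positive")
})

test_that("least-squares AIC follows its closed form", {
  expect_equal(compute_aic(19, 19, 4), 8)
  expect_equal(compute_aic(10, 19, 6) - compute_aic(10, 19, 4), 4)
  expect_equal(compute_aic(5, 19, 4) - compute_aic(10, 19, 4), -19 * log(2))
  expect_warning(a <- compute_aic(0, 19, 4), "zero")
  expect_identical(a, -Inf)
  expect_gt(compute_aic(10, 19, 5, correct = TRUE), compute_aic(10, 19, 5))
})

test_that("noiseless parameters are recovered with near-zero %SD", {
  sch <- default_frame_schedule()
  inp <- feng_fixture()
  spec <- model_spec("2T4k", TRUE)
  truth <- kinetic_params(K1 = 0.15, k2 = 0.18, k3 = 0.064, k4 = 0.04, vb = 0.05)
  tac <- model_tac(spec, truth, inp, sch)
  fit <- fit_model(tac, inp, spec, sch, fit_options(seed = 7))
  expect_true(fit$converged)
  for (nm in fit$free)
    expect_equal(fit$estimates[[nm]], truth[[nm]], tolerance = 0.01)
  expect_true(all(fit$percent_sd < 1e-3))
  expect_true(fit$reliable)
  expect_equal(fit$derived$vt, macro_vt(spec, truth), tolerance = 1e-6)
  expect_equal(fit$derived$bpnd, macro_bpnd(truth), tolerance = 1e-6)
})

test_that("an all-zero TAC drives K1 to its lower bound and fails the gate", {
  sch <- default_frame_schedule()
  inp <- feng_fixture()
  fit <- fit_model(rep(0, 19), inp, model_spec("1T2k"), sch, fit_options(seed = 3))
  expect_equal(fit$estimates[["K1"]], default_bounds()$K1[1], tolerance = 1e-9)
  expect_true(fit$boundary[["K1"]])
  expect_false(fit$reliable)
})

test_that("the fitted optimum matches a dense grid search on a toy problem", {
  # one effective free parameter: k2 pinned by a degenerate bound interval
  sch <- frame_schedule(c(60, 120, 180))
  inp <- constant_input(1, t_end = 10)
  truth <- kinetic_params(K1 = 0.11, k2 = 0.23)
  tac <- model_tac(model_spec("1T2k"), truth, inp, sch) * c(1.02, 0.99, 1.01)
  b <- default_bounds()
  b$k2 <- c(0.23, 0.23 + 1e-9)
  fit <- fit_model(tac, inp, model_spec("1T2k"), sch,
                   fit_options(seed = 5, bounds = b))
  grid_k1 <- seq(0.05, 0.2, by = 1e-4)
  w <- compute_weights(sch)
  rss <- vapply(grid_k1, function(K1) {
    sum(w * (model_tac(model_spec("1T2k"), kinetic_params(K1 = K1, k2 = 0.23),
                       inp, sch) - tac)^2)
  }, 0)
  expect_lt(abs(fit$estimates[["K1"]] - grid_k1[which.min(rss)]), 1e-4)
  expect_lte(fit$rss, min(rss) + 1e-12)
})

test_that("richer nested models never fit worse", {
  sch <- default_frame_schedule()
  inp <- feng_fixture()
  truth <- kinetic_params(K1 = 0.12, k2 = 0.16, k3 = 0.05, k4 = 0.04, vb = 0.04)
  tac <- add_noise(model_tac(model_spec("2T4k", TRUE), truth, inp, sch), sch,
                   0.03, seed = 21)
  f1 <- fit_model(tac, inp, model_spec("1T2k", TRUE), sch, fit_options(seed = 9))
  f2 <- fit_model(tac, inp, model_spec("2T4k", TRUE), sch, fit_options(seed = 9))
  expect_lte(f2$rss, f1$rss + 1e-6)
})

test_that("fixing the blood volume removes it from the free parameters", {
  sch <- default_frame_schedule()
  inp <- feng_fixture()
  spec <- model_spec("2T4k", TRUE)
  truth <- kinetic_params(K1 = 0.12, k2 = 0.16, k3 = 0.05, k4 = 0.04, vb = 0.05)
  tac <- model_tac(spec, truth, inp, sch)
  free_fit <- fit_model(tac, inp, spec, sch, fit_options(seed = 2))
  fixed_fit <- fit_model(tac, inp, spec, sch, fit_options(seed = 2, fix_vb = 0.05))
  expect_false("vb" %in% fixed_fit$free)
  expect_equal(length(fixed_fit$free), length(free_fit$free) - 1L)
  expect_equal(fixed_fit$estimates[["vb"]], 0.05)
  # the 2p term drops by 2; here V_B is fixed at truth so RSS stays ~ 0
  expect_lt(fixed_fit$aic - 19 * log(fixed_fit$rss / 19),
            free_fit$aic - 19 * log(free_fit$rss / 19))
})

fake_fit <- function(name, aic, percent_sd = c(K1 = 5), boundary = NULL) {
  spec <- parse_model_name(name)
  free <- names(percent_sd)
  structure(list(spec = spec, estimates = NULL, free = free,
                 percent_sd = percent_sd,
                 boundary = setNames(free %in% boundary, free),
                 rss = exp((aic - 2 * length(free)) / 19) * 19, aic = aic,
                 n_frames = 19L, converged = TRUE, reliable = TRUE,
                 reasons = character(), derived = list(), cov = NULL),
            class = "fit_result")
}

test_that("AIC selection picks the minimum and breaks ties to fewer parameters", {
  fits <- list(fake_fit("1T2k", 10), fake_fit("2T3k", 8), fake_fit("2T4k", 12))
  sel <- select_model(fits)
  expect_equal(sel$name, "2T3k")
  expect_equal(sel$table$delta_aic, c(2, 0, 4))
  tie <- list(fake_fit("2T4k_VB_1T1k", 5, c(K1 = 5, k2 = 5, k3 = 5, k4 = 5,
                                            vb = 5, kb = 5)),
              fake_fit("2T4k_VB", 5, c(K1 = 5, k2 = 5, k3 = 5, k4 = 5, vb = 5)))
  expect_equal(select_model(tie)$name, "2T4k_VB")
  expect_error(select_model(list()), "at least one")
})

test_that("reliability gating applies the 25/50% cut-offs and boundary flags", {
  ok <- fake_fit("2T4k_VB", 0, c(K1 = 10, k2 = 40, k3 = 40, k4 = 40, vb = 30))
  expect_true(assess_reliability(ok)$reliable)
  k1_bad <- fake_fit("2T4k_VB", 0, c(K1 = 30, k2 = 40, k3 = 40, k4 = 40, vb = 30))
  r1 <- assess_reliability(k1_bad)
  expect_false(r1$reliable)
  expect_match(r1$reasons, "K1", all = FALSE)
  kb_bad <- fake_fit("2T4k_VB_1T1k", 0, c(K1 = 10, k2 = 40, k3 = 40, k4 = 40,
                                          vb = 30, kb = 80))
  r2 <- assess_reliability(kb_bad)
  expect_false(r2$reliable)
  expect_match(r2$reasons, "kb", all = FALSE)
  bnd <- fake_fit("1T2k", 0, c(K1 = 5, k2 = 5), boundary = "k2")
  r3 <- assess_reliability(bnd)
  expect_false(r3$reliable)
  expect_match(r3$reasons, "bound", all = FALSE)
})

test_that("K1 and V_T recover more tightly than k3 and k4; BP_ND beats both", {
  sch <- default_frame_schedule()
  inp <- feng_fixture()
  spec <- model_spec("2T4k", TRUE)
  truth <- kinetic_params(K1 = 0.12, k2 = 0.16, k3 = 0.05, k4 = 0.04, vb = 0.05)
  clean <- model_tac(spec, truth, inp, sch)
  res <- t(vapply(1:30, function(i) {
    tac <- add_noise(clean, sch, 0.05, seed = 400 + i)
    fit <- fit_model(tac, inp, spec, sch, fit_options(seed = 500 + i, multistart = 6))
    c(K1 = fit$estimates[["K1"]] / truth[["K1"]] - 1,
      k3 = fit$estimates[["k3"]] / truth[["k3"]] - 1,
      k4 = fit$estimates[["k4"]] / truth[["k4"]] - 1,
      vt = fit$derived$vt / macro_vt(spec, truth) - 1,
      bp = fit$derived$bpnd / macro_bpnd(truth) - 1)
  }, c(K1 = 0, k3 = 0, k4 = 0, vt = 0, bp = 0)))
  disp <- apply(res, 2, function(x) median(abs(x)))
  expect_lt(disp[["K1"]], disp[["k3"]])
  expect_lt(disp[["K1"]], disp[["k4"]])
  expect_lt(disp[["vt"]], disp[["k3"]])
  expect_lt(disp[["bp"]], disp[["k3"]])
  expect_lt(disp[["bp"]], disp[["k4"]])
})
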