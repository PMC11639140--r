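test_that("noiseless linear-truth data identify the linear model exactly", {
  tr <- make_truth("linear", overrides = list(
    alpha_sigma = 0, beta_sigma = 0,
    beta_dim = c(WE = 0.15, LO = 0.1, DA = 0.12, LE = 0.08,
                 PA = 0.3, TI = 0.1, AN = 0.18, DE = 0.32)))
  tto <- simulate_tto(tr, tto_design_fx, 6, seed = 1)
  fit <- fit_value_model(model_spec("linear", "tto", heteroscedastic = FALSE),
                         tto = tto, tto_design = tto_design_fx,
                         control = fit_control(restarts = 2))
  expect_equal(fit$convergence, 0)
  expect_equal(unname(coef(fit)[dims_fx]), unname(tr$beta_dim),
               tolerance = 5e-3)
})

test_that("null-truth data drive all disutility coefficients to the zero bound", {
  # zero-noise null: values are exactly 1, so the boundary solution is exact
  nl0 <- make_truth("null", overrides = list(alpha_sigma = 0))
  tto0 <- simulate_tto(nl0, tto_design_fx, 6, seed = 2)
  fit0 <- fit_value_model(model_spec("cale", "tto"), tto = tto0,
                          tto_design = tto_design_fx,
                          control = fit_control(restarts = 2))
  expect_equal(fit0$convergence, 0)
  expect_true(all(coef(fit0)[dims_fx] < 1e-6))
  # noisy null at moderate n: estimates stay within sampling noise of 0
  nl <- make_truth("null", overrides = list(alpha_sigma = 0.15))
  tto <- simulate_tto(nl, tto_design_fx, 200, seed = 2)
  dce <- simulate_dce(nl, dce_pairs_fx, 300, seed = 3)
  fit <- fit_value_model(model_spec("cale", "hybrid"), tto, dce,
                         tto_design_fx, dce_pairs_fx,
                         control = fit_control(restarts = 2))
  expect_equal(fit$convergence, 0)
  expect_true(all(coef(fit)[dims_fx] < 0.06))
})

test_that("hybrid CALE fitting recovers a paper-like truth at study scale", {
  tto <- simulate_tto(truth_fx, tto_design_fx, 200, seed = 11)
  dce <- simulate_dce(truth_fx, dce_pairs_fx, 508, seed = 12)
  fit <- fit_value_model(model_spec("cale", "hybrid"), tto, dce,
                         tto_design_fx, dce_pairs_fx,
                         control = fit_control(restarts = 3, seed = 4))
  expect_equal(fit$convergence, 0)
  expect_lt(max(abs(coef(fit)[dims_fx] - truth_fx$beta_dim)), 0.08)
  expect_lt(abs(coef(fit)[["theta"]] - truth_fx$theta), 0.15)
  lv <- coef(fit)[paste0("lvl.", c(1:5, 7))]
  expect_lt(max(abs(lv - truth_fx$beta_level[c(2:6, 8)])), 0.1)
  # the combined log-likelihood is the sum of the two components
  expect_equal(fit$loglik$combined, fit$loglik$tto + fit$loglik$dce)
})

test_that("the hybrid optimum dominates patched-together separate fits", {
  tto <- simulate_tto(truth_fx, tto_design_fx, 60, seed = 21)
  dce <- simulate_dce(truth_fx, dce_pairs_fx, 90, seed = 22)
  hspec <- model_spec("cale", "hybrid")
  hyb <- fit_value_model(hspec, tto, dce, tto_design_fx, dce_pairs_fx,
                         control = fit_control(restarts = 2))
  ft <- fit_value_model(model_spec("cale", "tto"), tto = tto,
                        tto_design = tto_design_fx,
                        control = fit_control(restarts = 2))
  fd <- fit_value_model(model_spec("cale", "dce"), dce = dce,
                        dce_pairs = dce_pairs_fx,
                        control = fit_control(restarts = 2))
  patched <- coef(hyb)
  shared <- intersect(names(patched), names(coef(ft)))
  patched[shared] <- coef(ft)[shared]
  ll_patched <- hybrid_loglik(hspec, patched, tto, dce,
                              tto_design_fx, dce_pairs_fx)
  expect_gte(hyb$loglik$combined, ll_patched - 1e-6)
})

test_that("fitting is reproducible given data and seed", {
  f1 <- fit_value_model(model_spec("cale", "hybrid"), tto_small_fx,
                        dce_small_fx, tto_design_fx, dce_pairs_fx,
                        control = fit_control(restarts = 3, seed = 9))
  f2 <- fit_value_model(model_spec("cale", "hybrid"), tto_small_fx,
                        dce_small_fx, tto_design_fx, dce_pairs_fx,
                        control = fit_control(restarts = 3, seed = 9))
  expect_identical(coef(f1), coef(f2))
})

test_that("cluster bootstrap is reproducible and collapses with zero noise", {
  fit <- fit_value_model(model_spec("cale", "tto"), tto = tto_small_fx,
                         tto_design = tto_design_fx,
                         control = fit_control(restarts = 2))
  b1 <- bootstrap_se(fit, tto = tto_small_fx, tto_design = tto_design_fx,
                     B = 4, seed = 5)
  b2 <- bootstrap_se(fit, tto = tto_small_fx, tto_design = tto_design_fx,
                     B = 4, seed = 5)
  expect_identical(b1$bootstrap$replicates, b2$bootstrap$replicates)
  expect_equal(b1$bootstrap$n_dropped, 0)

  # zero-noise data: every resample carries identical information, SEs ~ 0
  tr <- make_truth("linear", overrides = list(alpha_sigma = 0, beta_sigma = 0,
                                              beta_dim = make_truth()$beta_dim / 3))
  tto0 <- simulate_tto(tr, tto_design_fx, 6, seed = 31)
  f0 <- fit_value_model(model_spec("linear", "tto", heteroscedastic = FALSE),
                        tto = tto0, tto_design = tto_design_fx,
                        control = fit_control(restarts = 1))
  b0 <- bootstrap_se(f0, tto = tto0, tto_design = tto_design_fx, B = 3, seed = 6)
  expect_lt(max(b0$bootstrap$se[dims_fx]), 1e-3)
})

test_that("bootstrap standard errors shrink roughly as 1/sqrt(n)", {
  set.seed(77)
  tto_n <- simulate_tto(truth_fx, tto_design_fx, 50, seed = 41)
  tto_4n <- simulate_tto(truth_fx, tto_design_fx, 200, seed = 42)
  spec <- model_spec("cale", "tto")
  f_n <- fit_value_model(spec, tto = tto_n, tto_design = tto_design_fx,
                         control = fit_control(restarts = 2))
  f_4n <- fit_value_model(spec, tto = tto_4n, tto_design = tto_design_fx,
                          control = fit_control(restarts = 2))
  b_n <- bootstrap_se(f_n, tto = tto_n, tto_design = tto_design_fx,
                      B = 30, seed = 43)
  b_4n <- bootstrap_se(f_4n, tto = tto_4n, tto_design = tto_design_fx,
                       B = 30, seed = 44)
  ratio <- median(b_n$bootstrap$se[dims_fx] / b_4n$bootstrap$se[dims_fx])
  expect_gt(ratio, 1.3)  # ideal 2, generous band for B = 30 noise
  expect_lt(ratio, 3.2)
})

test_that("scope-data mismatches are rejected up front", {
  expect_error(fit_value_model(model_spec("cale", "hybrid"),
                               tto = tto_small_fx, tto_design = tto_design_fx),
               "requires")
  expect_error(fit_value_model(model_spec("cale", "tto")), "requires")
})
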