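# a converged fit to small synthetic data, reused across tariff tests
tariff_fit_fx <- fit_value_model(
  model_spec("cale", "hybrid"), tto_small_fx, dce_small_fx,
  tto_design_fx, dce_pairs_fx, control = fit_control(restarts = 2))

test_that("level 6 is interpolated as the midpoint of levels 5 and 7", {
  tar <- build_tariff(tariff_fit_fx, repair = FALSE)
  e <- tar$entries
  expect_equal(e[, "6"], (e[, "5"] + e[, "7"]) / 2)
  expect_true(all(tar$provenance[, "6"] == "interpolated"))
  expect_true(all(e[, "1"] >= 0))
  expect_equal(unname(e[, "0"]), rep(0, 8))
  # interpolation preserves monotone flanks: if e5 <= e7 then e5 <= e6 <= e7
  ok <- e[, "5"] <= e[, "7"]
  expect_true(all(e[ok, "6"] >= e[ok, "5"] & e[ok, "6"] <= e[ok, "7"]))
})

test_that("a shared-CALE tariff is the dimension coefficient times the level curve", {
  tar <- build_tariff(tariff_fit_fx, repair = FALSE)
  cf <- coef(tariff_fit_fx)
  curve <- c(0, cf[paste0("lvl.", 1:5)], NA, cf["lvl.7"])
  for (d in dims_fx)
    expect_equal(unname(tar$entries[d, c(1:6, 8)]),
                 unname(cf[d] * curve[c(1:6, 8)]))
})

test_that("single-arm scopes interpolate their extra level gaps", {
  fit_t <- fit_value_model(model_spec("cale", "tto"), tto = tto_small_fx,
                           tto_design = tto_design_fx,
                           control = fit_control(restarts = 2))
  tar <- build_tariff(fit_t, repair = FALSE)
  # the TTO arm observes levels 1,3,5,7 (symptom) / 0,3,5,7 (impact), so the
  # shared level curve has multipliers at 1,3,5,7: level 2 is the midpoint of
  # its fitted neighbours, and impact level 1 is *fitted* via the shared curve
  expect_equal(tar$entries["WE", "2"],
               (tar$entries["WE", "1"] + tar$entries["WE", "3"]) / 2)
  expect_equal(tar$provenance["DA", "1"], "fitted")
  expect_equal(unname(tar$entries["DA", "1"]),
               unname(coef(fit_t)["DA"] * coef(fit_t)["lvl.1"]))
  expect_equal(tar$entries["DA", "2"],
               (tar$entries["DA", "1"] + tar$entries["DA", "3"]) / 2)
  expect_true(all(tar$provenance[, "4"] %in% "interpolated"))
  expect_equal(tar$entries["PA", "4"],
               (tar$entries["PA", "3"] + tar$entries["PA", "5"]) / 2)
})

test_that("monotonicity repair pools adjacent violators and flags them", {
  # an adversarial main-effects fit with a logical inconsistency on DA:
  # the level-5 entry sits below level 3
  spec <- model_spec("main", "tto", heteroscedastic = FALSE)
  pb <- model_bounds(spec)
  cf <- setNames(rep(0, nrow(pb)), pb$name)
  for (d in sym_fx) cf[paste0(d, ".l", c(1, 3, 5, 7))] <- c(0.1, 0.2, 0.3, 0.5)
  for (d in setdiff(dims_fx, sym_fx))
    cf[paste0(d, ".l", c(3, 5, 7))] <- c(0.2, 0.3, 0.5)
  cf["DA.l5"] <- 0.15  # violates DA.l3 = 0.2
  cf["sigma"] <- 0.3
  fit <- structure(list(spec = spec, coefficients = cf,
                        free_names = pb$name[!pb$fixed], convergence = 0L,
                        loglik = list(combined = NA_real_)),
                   class = "value_fit")
  raw <- build_tariff(fit, repair = FALSE)
  # DA entries before repair: l3 = 0.2, l4 = 0.175, l5 = 0.15 (a descent)
  expect_equal(unname(raw$entries["DA", c("3", "4", "5")]), c(0.2, 0.175, 0.15))
  rep_t <- build_tariff(fit, repair = TRUE)
  # pool-adjacent-violators: the descending run is replaced by its average
  expect_equal(unname(rep_t$entries["DA", c("3", "4", "5")]),
               rep(mean(c(0.2, 0.175, 0.15)), 3))
  # the cells whose values changed are flagged (l4 already equalled the pool)
  expect_true(all(rep_t$provenance["DA", c("3", "5")] == "monotonized"))
  expect_true(all(diff(rep_t$entries["DA", ]) >= -1e-12))
  # an already-monotone dimension is untouched
  expect_equal(rep_t$entries["PA", ], raw$entries["PA", ])
  expect_false(any(rep_t$provenance["PA", ] == "monotonized"))
  # repair never decreases the level-7 entry
  expect_true(all(rep_t$entries[, "7"] >= raw$entries[, "7"] - 1e-12))
})

test_that("scoring is additive, anchored at 1, and monotone with severity", {
  tar <- build_tariff(tariff_fit_fx)
  best <- score_responses(tar, data.frame(t(setNames(rep(0, 8), dims_fx))))
  expect_equal(best$utility, 1)
  # single-dimension state: utility = 1 - tariff entry
  one <- data.frame(WE = 0, LO = 0, DA = 0, LE = 0, PA = 7, TI = 0, AN = 0, DE = 0)
  expect_equal(score_responses(tar, one)$utility, 1 - tar$entries["PA", "7"])
  # additivity across dimensions (no intercept in this fit)
  two <- data.frame(WE = 3, LO = 0, DA = 0, LE = 0, PA = 7, TI = 0, AN = 0, DE = 0)
  expect_equal(score_responses(tar, two)$utility,
               1 - tar$entries["WE", "3"] - tar$entries["PA", "7"])
  # with a monotone repaired tariff, worsening any dimension never raises utility
  set.seed(99)
  for (k in 1:20) {
    lv <- sample(0:7, 8, replace = TRUE)
    j <- sample(1:8, 1)
    if (lv[j] == 7) next
    lv2 <- lv
    lv2[j] <- lv[j] + 1
    u1 <- score_responses(tar, data.frame(t(setNames(lv, dims_fx))))$utility
    u2 <- score_responses(tar, data.frame(t(setNames(lv2, dims_fx))))$utility
    expect_lte(u2, u1 + 1e-12)
  }
})

test_that("tariffs round-trip through CSV and imports are validated", {
  tar <- build_tariff(tariff_fit_fx)
  path <- tempfile(fileext = ".csv")
  export_tariff(tar, path)
  back <- import_tariff(path)
  expect_identical(back$entries, tar$entries)
  expect_identical(back$provenance, tar$provenance)
  expect_equal(back$intercept, tar$intercept)
  expect_equal(back$apply_intercept, tar$apply_intercept)
  # scoring agrees after the round trip
  resp <- data.frame(WE = 1, LO = 2, DA = 3, LE = 0, PA = 6, TI = 7, AN = 5, DE = 4)
  expect_equal(score_responses(back, resp)$utility,
               score_responses(tar, resp)$utility)

  # a nonzero level-0 entry is rejected
  x <- read.csv(path, colClasses = "character")
  x$level_0[3] <- "0.1"
  bad1 <- tempfile(fileext = ".csv")
  write.csv(x, bad1, row.names = FALSE, quote = FALSE)
  expect_error(import_tariff(bad1), "level-0")
  # a missing level column is named in the error
  x2 <- read.csv(path, colClasses = "character")
  x2$level_4 <- NULL
  bad2 <- tempfile(fileext = ".csv")
  write.csv(x2, bad2, row.names = FALSE, quote = FALSE)
  expect_error(import_tariff(bad2), "level_4")
})

test_that("the TTO intercept is applied to non-best states only when requested", {
  fit_i <- fit_value_model(model_spec("cale", "hybrid", tto_intercept = TRUE),
                           tto_small_fx, dce_small_fx, tto_design_fx,
                           dce_pairs_fx, control = fit_control(restarts = 2))
  tar_on <- build_tariff(fit_i, apply_intercept = TRUE)
  tar_off <- build_tariff(fit_i, apply_intercept = FALSE)
  best <- data.frame(t(setNames(rep(0, 8), dims_fx)))
  mild <- data.frame(WE = 1, LO = 0, DA = 0, LE = 0, PA = 0, TI = 0, AN = 0, DE = 0)
  expect_equal(score_responses(tar_on, best)$utility, 1)
  expect_equal(score_responses(tar_on, mild)$utility,
               1 - tar_on$intercept - tar_on$entries["WE", "1"])
  expect_equal(score_responses(tar_off, mild)$utility,
               1 - tar_off$entries["WE", "1"])
})
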