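small_hp_grid <- expand.grid(cost = c(1, 10), gamma = c(0.02, 0.1))

test_that("precision-recall matches brute-force confusion enumeration", {
  # perfect classifier: both measures 1 at the default cutoff
  pr <- precision_recall(c(1, 1, 1, 0, 0), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  p05 <- attr(pr, "point_05")
  expect_equal(p05$precision, 1)
  expect_equal(p05$recall, 1)

  # fixed 10-sample probability vector vs exhaustive enumeration
  prob <- c(0.05, 0.15, 0.35, 0.42, 0.5, 0.55, 0.61, 0.78, 0.82, 0.99)
  truth <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  cuts <- seq(0, 1, by = 0.01)
  pr <- precision_recall(prob, truth, cuts)
  for (i in seq_along(cuts)) {
    pred <- prob >= cuts[i]
    tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    expect_equal(pr$recall[i], tp / (tp + fn))
    if (tp + fp == 0) expect_true(is.na(pr$precision[i]))
    else expect_equal(pr$precision[i], tp / (tp + fp))
  }

  # degenerate scores: recall steps from 1 to 0 at the shared value
  pr2 <- precision_recall(rep(0.4, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
                          cutoffs = c(0, 0.2, 0.4, 0.6, 1))
  expect_equal(pr2$recall, c(1, 1, 1, 0, 0))

  expect_error(precision_recall(c(0.2, 0.8), c(TRUE, TRUE)), "both classes")
})

test_that("accuracy from the PR confusion equals the direct accuracy", {
  set.seed(71)
  prob <- runif(40)
  truth <- runif(40) < prob
  if (!any(truth)) truth[1] <- TRUE
  if (all(truth)) truth[2] <- FALSE
  pr <- precision_recall(prob, truth, cutoffs = 0.5)
  tn <- sum(prob < 0.5 & !truth)
  expect_equal((pr$tp + tn) / 40, mean((prob >= 0.5) == truth))
})

test_that("scenario windows clamp to the ranking and reject tiny pools", {
  rk <- study_ranking()
  scn <- hp_scenarios()
  expect_equal(nrow(scn), 13L)
  set.seed(72)
  top100 <- draw_cols <- hybripred:::draw_scenario_cols(
    scn[scn$id == "5ofTop100", ], rk)
  expect_length(top100, 5L)
  # a 4-column ranking cannot feed a 5-feature scenario
  rk4 <- rk[1:4, ]
  expect_error(hybripred:::draw_scenario_cols(scn[scn$id == "Top5", ], rk4),
               "fewer ranked columns")
  expect_error(hp_scenarios("NoSuch"), "unknown scenario")
})

test_that("planted-signal scenarios order as the generator dictates", {
  s <- study_panel()
  rk <- study_ranking()
  scn <- hp_scenarios(c("Top5", "Random5", "Bottom5", "All-perm"))
  reg <- predict_hp_regression(s$xdf, s$panel$phenotypes, rk,
                               scenarios = scn, repetitions = 6,
                               cv_reps = 1, seed = 31, grid = small_hp_grid)
  med <- vapply(split(reg$r2, reg$scenario), median, numeric(1))
  expect_gt(med[["Top5"]], med[["Random5"]])
  expect_gt(med[["Random5"]], med[["Bottom5"]])
  expect_lt(med[["All-perm"]], 0.05)
  expect_true(all(reg$r2 >= 0 & reg$r2 <= 1))
})

test_that("reported R-squared is invariant to affine biomass rescaling", {
  s <- study_panel()
  rk <- study_ranking()
  ph <- s$panel$phenotypes
  ph2 <- phenotype_table(setNames(3.7 * ph$biomass + 200, ph$cross_id),
                         setNames(ph$trial, ph$cross_id))
  scn <- hp_scenarios("Top5")
  r1 <- predict_hp_regression(s$xdf, ph, rk, scenarios = scn,
                              repetitions = 2, cv_reps = 1, seed = 32,
                              grid = small_hp_grid)
  r2 <- predict_hp_regression(s$xdf, ph2, rk, scenarios = scn,
                              repetitions = 2, cv_reps = 1, seed = 32,
                              grid = small_hp_grid)
  # the SVR scales x and y internally, so the solutions coincide up to the
  # optimizer's termination tolerance
  expect_equal(r1$r2, r2$r2, tolerance = 1e-3)
})

test_that("good/bad classification recovers the planted separation", {
  s <- study_panel()
  rk <- study_ranking()
  cls <- predict_hp_classification(s$xdf, s$panel$phenotypes, rk,
                                   scenarios = hp_scenarios("Top5"),
                                   repetitions = 4, cv_reps = 1, seed = 33,
                                   grid = small_hp_grid)
  expect_true(all(cls$accuracy > 0.5))
  expect_gt(median(cls$auc), 0.6)
  expect_true(all(cls$accuracy >= 0 & cls$accuracy <= 1))
  expect_true(all(cls$auc >= 0 & cls$auc <= 1, na.rm = TRUE))
  # probabilities feed a valid PR curve
  pp <- do.call(rbind, attr(cls, "probs"))
  pr <- precision_recall(pp$prob_good, pp$good)
  expect_true(all(diff(pr$recall) <= 1e-12))   # recall non-increasing in cutoff

  # thresholds outside the biomass range are rejected
  expect_error(predict_hp_classification(s$xdf, s$panel$phenotypes, rk,
                                         scenarios = hp_scenarios("Top5"),
                                         threshold = 1e6),
               "outside")
})

test_that("the threshold sweep flags degenerate cutoffs and includes the mean", {
  s <- study_panel()
  rk <- study_ranking()
  sw <- threshold_sweep(s$xdf, s$panel$phenotypes, rk, n_thresholds = 5,
                        repetitions = 2, cv_reps = 1, seed = 34,
                        grid = small_hp_grid)
  expect_equal(nrow(sw), 5L)
  y <- s$panel$phenotypes$biomass
  expect_true(any(abs(sw$threshold - mean(y)) < 1e-9))
  expect_true(all(sw$threshold > min(y) & sw$threshold < max(y)))
  ok <- !sw$degenerate
  expect_true(any(ok))
  # chance-corrected agreement peaks at the centre of the distribution
  mid <- which.min(abs(sw$threshold - mean(y)))
  expect_gte(sw$kappa[mid], max(sw$kappa[ok][c(1, sum(ok))], na.rm = TRUE) - 0.15)
})

test_that("without causal analytes the full model has no predictive power", {
  cfg <- sim_config(n_dents = 10, n_flints = 10, cross_fraction = 0.8,
                    n_analytes = 20, n_replicates = 4, n_causal = 0,
                    causal_weights = numeric(0), n_encoded = 0)
  p <- simulate_panel(cfg, seed = 13)
  rf <- redundancy_filter(p$profiles)
  xdf <- build_predictor_matrix(p$design, p$profiles, rf$retained)
  # ranking is irrelevant here; use an arbitrary deterministic order
  rk <- structure(data.frame(column = colnames(xdf),
                             analyte = attr(xdf, "analyte"),
                             origin = attr(xdf, "origin"),
                             median_importance = seq(100, 1,
                                                     length.out = ncol(xdf)),
                             importance_sd = 0,
                             rank = seq_len(ncol(xdf))),
                  class = c("analyte_ranking", "data.frame"))
  reg <- predict_hp_regression(xdf, p$phenotypes, rk,
                               scenarios = hp_scenarios("All"),
                               repetitions = 5, cv_reps = 1, seed = 35,
                               grid = small_hp_grid)
  expect_lt(median(reg$r2), 0.05)
})
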