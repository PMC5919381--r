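# Support-vector prediction of field hybrid performance from ranked
# parental-analyte subsets, with permutation nulls.

#' The thirteen feature-subset scenarios for hybrid-performance models
#'
#' Subsets of the ranked parental columns used to train each model: the
#' fixed top/bottom five, five drawn at random from sliding top/bottom
#' windows, five drawn from the whole ranking, all columns, and all columns
#' with permuted biomass (the permutation null).
#'
#' @param ids optional subset of scenario ids to keep, in the canonical
#'   order.
#' @return data.frame `id`, `type`, `window`.
#' @export
hp_scenarios <- function(ids = NULL) {
  sc <- data.frame(
    id = c("Top5", "5ofTop10", "5ofTop20", "5ofTop50", "5ofTop100",
           "5ofBottom100", "5ofBottom50", "5ofBottom20", "5ofBottom10",
           "Bottom5", "Random5", "All", "All-perm"),
    type = c("top", "top", "top", "top", "top",
             "bottom", "bottom", "bottom", "bottom",
             "bottom", "random", "all", "all_perm"),
    window = c(5L, 10L, 20L, 50L, 100L, 100L, 50L, 20L, 10L, 5L, NA, NA, NA),
    stringsAsFactors = FALSE)
  if (!is.null(ids)) {
    bad <- setdiff(ids, sc$id)
    if (length(bad)) stop("unknown scenario id(s): ", paste(bad, collapse = ", "))
    sc <- sc[sc$id %in% ids, ]
  }
  sc
}

# Draw the predictor columns for one scenario repetition. Windows larger
# than the ranking are clamped to it; a window below the subset size is an
# error.
draw_scenario_cols <- function(scn, ranking, n_sub = 5L) {
  N <- nrow(ranking)
  if (N < n_sub) stop("fewer ranked columns than the subset size")
  cols <- ranking$column[order(ranking$rank)]
  if (scn$type %in% c("all", "all_perm")) return(cols)
  w <- min(scn$window, N)
  if (is.na(w) && scn$type == "random") w <- N
  if (w < n_sub) stop("subset window smaller than ", n_sub)
  pool <- switch(scn$type,
                 top = cols[seq_len(w)],
                 bottom = cols[seq.int(N - w + 1L, N)],
                 random = cols)
  if (length(pool) == n_sub) pool else sample(pool, n_sub)
}

# Tune + fit an RBF-kernel SVM (regression or classification) maximizing
# the given objective over a (cost, gamma) grid by repeated k-fold CV.
tune_svm_hp <- function(x, y, type, objective, cv_folds, cv_reps, grid,
                        weights = NULL) {
  grid <- grid %||% {
    g0 <- rbf_gamma0(x)
    expand.grid(cost = 2^seq(-2, 6, by = 2), gamma = g0 * c(0.5, 1, 2))
  }
  score_fun <- switch(objective,
    r2 = function(pred, obs) {
      if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(0)
      stats::cor(pred, obs)^2
    },
    accuracy = function(pred, obs) mean(pred == obs),
    auc = function(pred, obs) {
      a <- rank_auc(pred, obs == levels(obs)[2])
      if (is.na(a)) 0 else max(a, 1 - a)
    })
  classif <- type == "C-classification"
  scores <- matrix(NA_real_, 0L, nrow(grid))
  for (r in seq_len(cv_reps)) {
    fold <- if (classif) stratified_folds(y, cv_folds)
            else sample(rep_len(seq_len(cv_folds), length(y)))
    for (k in seq_len(cv_folds)) {
      tr <- fold != k
      if (classif && length(unique(y[tr])) < 2L) next
      sc <- vapply(seq_len(nrow(grid)), function(i) {
        f <- tryCatch(
          e1071::svm(x[tr, , drop = FALSE], y[tr], type = type,
                     kernel = "radial", cost = grid$cost[i],
                     gamma = grid$gamma[i], class.weights = weights,
                     probability = FALSE),
          error = function(e) NULL)
        if (is.null(f)) return(NA_real_)
        pr <- predict(f, x[!tr, , drop = FALSE])
        if (objective == "auc") {
          # refit with probabilities only for the winning model; rank the
          # grid by decision-value AUC via the class prediction proxy
          score_fun(as.numeric(pr == levels(y)[2]), y[!tr])
        } else score_fun(if (classif) pr else as.numeric(pr),
                         if (classif) y[!tr] else y[!tr])
      }, numeric(1))
      scores <- rbind(scores, sc)
    }
  }
  msc <- colMeans(scores, na.rm = TRUE); msc[is.nan(msc)] <- -Inf
  best <- grid[which.max(msc), , drop = FALSE]
  fit <- e1071::svm(x, y, type = type, kernel = "radial", cost = best$cost,
                    gamma = best$gamma, class.weights = weights,
                    probability = FALSE)
  list(fit = fit, par = best, cv_score = max(msc))
}

# Signed decision value toward the 'good' class.
svm_dv_good <- function(fit, x) {
  pr <- predict(fit, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  d <- as.numeric(dv[, 1])
  if (!startsWith(colnames(dv)[1], "good")) d <- -d
  d
}

# Platt calibration: logistic fit of the class on the decision values.
# Deterministic (unlike libsvm's internal cross-validated estimate).
platt_probs <- function(fit, xtr, ytr, xte) {
  dtr <- svm_dv_good(fit, xtr)
  dte <- svm_dv_good(fit, xte)
  g <- suppressWarnings(stats::glm((ytr == "good") ~ dtr,
                                   family = stats::binomial()))
  p <- suppressWarnings(stats::predict(g, newdata = data.frame(dtr = dte),
                                       type = "response"))
  pmin(pmax(as.numeric(p), 1e-8), 1 - 1e-8)
}

align_hp_inputs <- function(xdf, pheno) {
  common <- intersect(rownames(xdf), pheno$cross_id)
  if (length(common) < 10L) stop("too few phenotyped hybrids with predictors")
  list(x = unclass(xdf)[common, , drop = FALSE],
       y = setNames(pheno$biomass, pheno$cross_id)[common])
}

#' Quantitative hybrid-performance prediction (support-vector regression)
#'
#' Per scenario and repetition: random 80/20 train/test partition of the
#' phenotyped hybrids, RBF-kernel support-vector regression on the
#' scenario's predictor columns tuned by repeated 3-fold cross-validation
#' maximizing R-squared (squared Pearson correlation of predicted vs
#' observed), then test-set R-squared. Random subsets are redrawn every
#' repetition; the `All-perm` scenario permutes biomass once per repetition
#' before splitting.
#'
#' @param xdf [build_predictor_matrix()] output.
#' @param pheno [phenotype_table()].
#' @param ranking [rank_parental_analytes()] output.
#' @param scenarios [hp_scenarios()] rows to run.
#' @param repetitions default 25.
#' @param train_fraction default 0.8.
#' @param cv_folds,cv_reps inner tuning (default 3-fold, 10 reps).
#' @param seed master seed.
#' @param grid optional (cost, gamma) grid override.
#' @return data.frame of class `hp_eval`: `scenario`, `rep`, `r2` (squared
#'   correlation), `r2_sse` (1 - SSE/SST alternative), `n_test`, `params`.
#' @export
predict_hp_regression <- function(xdf, pheno, ranking,
                                  scenarios = hp_scenarios(),
                                  repetitions = 25L, train_fraction = 0.8,
                                  cv_folds = 3L, cv_reps = 10L, seed = 1L,
                                  grid = NULL) {
  inp <- align_hp_inputs(xdf, pheno)
  seeds <- derive_seeds(seed, nrow(scenarios) * repetitions)
  res <- list(); t <- 0L
  for (si in seq_len(nrow(scenarios))) {
    scn <- scenarios[si, ]
    for (r in seq_len(repetitions)) {
      t <- t + 1L
      set.seed(seeds[t])
      cols <- draw_scenario_cols(scn, ranking)
      y <- inp$y
      if (scn$type == "all_perm") y <- setNames(sample(y), names(y))
      n <- length(y)
      tr <- sample.int(n, round(train_fraction * n))
      x <- inp$x[, cols, drop = FALSE]
      tuned <- tune_svm_hp(x[tr, , drop = FALSE], y[tr], "eps-regression",
                           "r2", cv_folds, cv_reps, grid)
      pred <- as.numeric(predict(tuned$fit, x[-tr, , drop = FALSE]))
      obs <- y[-tr]
      r2 <- if (stats::sd(pred) == 0) 0 else stats::cor(pred, obs)^2
      res[[t]] <- data.frame(
        scenario = scn$id, rep = r, r2 = r2,
        r2_sse = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
        n_test = length(obs),
        params = paste(names(tuned$par), unlist(tuned$par), sep = "=",
                       collapse = ";"))
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("hp_eval", "data.frame")
  out
}

#' Qualitative hybrid-performance prediction (good vs bad performers)
#'
#' Hybrids are labelled 'good' when biomass is greater than or equal to the
#' threshold (default: the mean biomass) and 'bad' otherwise; an RBF-kernel
#' SVM is then trained/tested with the same partitioning scheme as
#' [predict_hp_regression()], tuned to maximize accuracy (or AUC). Records
#' test accuracy, Cohen's kappa, AUC and the per-hybrid good-class
#' probabilities (Platt calibration: a logistic fit on the SVM decision
#' values, which is deterministic) for precision-recall analysis.
#'
#' @inheritParams predict_hp_regression
#' @param threshold numeric biomass cutoff, or `"mean"`.
#' @param objective tuning objective: `"accuracy"` (default) or `"auc"`.
#' @return data.frame of class `hp_class_eval`: `scenario`, `rep`,
#'   `accuracy`, `kappa`, `auc`, `n_test`, `params`; attribute `probs` is a
#'   list (per row) of data.frames `cross_id`, `prob_good`, `good`.
#'   Attribute `threshold` is the numeric cutoff used.
#' @export
predict_hp_classification <- function(xdf, pheno, ranking,
                                      scenarios = hp_scenarios(),
                                      threshold = "mean",
                                      repetitions = 25L,
                                      train_fraction = 0.8,
                                      cv_folds = 3L, cv_reps = 10L,
                                      objective = c("accuracy", "auc"),
                                      seed = 1L, grid = NULL) {
  objective <- match.arg(objective)
  inp <- align_hp_inputs(xdf, pheno)
  thr <- if (identical(threshold, "mean")) mean(inp$y) else as.numeric(threshold)
  if (thr <= min(inp$y) || thr >= max(inp$y))
    stop("threshold outside the observed biomass range")
  cls <- factor(ifelse(inp$y >= thr, "good", "bad"), levels = c("bad", "good"))
  if (any(table(cls) == 0L)) stop("a performance class is empty at this threshold")
  seeds <- derive_seeds(seed, nrow(scenarios) * repetitions)
  res <- list(); probs <- list(); t <- 0L
  for (si in seq_len(nrow(scenarios))) {
    scn <- scenarios[si, ]
    for (r in seq_len(repetitions)) {
      t <- t + 1L
      set.seed(seeds[t])
      cols <- draw_scenario_cols(scn, ranking)
      y <- cls
      if (scn$type == "all_perm") y <- sample(y)
      tr <- stratified_train_idx(y, train_fraction)
      x <- inp$x[, cols, drop = FALSE]
      tuned <- tune_svm_hp(x[tr, , drop = FALSE], droplevels(y[tr]),
                           "C-classification", objective, cv_folds, cv_reps,
                           grid)
      te <- setdiff(seq_along(y), tr)
      pr <- predict(tuned$fit, x[te, , drop = FALSE])
      pg <- platt_probs(tuned$fit, x[tr, , drop = FALSE], y[tr],
                        x[te, , drop = FALSE])
      obs <- y[te]
      auc <- tryCatch(
        as.numeric(pROC::auc(pROC::roc(response = obs, predictor = pg,
                                       levels = c("bad", "good"),
                                       direction = "<", quiet = TRUE))),
        error = function(e) NA_real_)
      res[[t]] <- data.frame(
        scenario = scn$id, rep = r,
        accuracy = mean(pr == obs),
        kappa = kappa_of(pr, obs, levels(y)),
        auc = auc, n_test = length(te),
        params = paste(names(tuned$par), unlist(tuned$par), sep = "=",
                       collapse = ";"))
      probs[[t]] <- data.frame(cross_id = rownames(x)[te], prob_good = pg,
                               good = obs == "good",
                               stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  attr(out, "probs") <- probs
  attr(out, "threshold") <- thr
  class(out) <- c("hp_class_eval", "data.frame")
  out
}

#' Precision-recall curve over probability cutoffs
#'
#' A hybrid is predicted 'good' when its good-class probability is at least
#' the cutoff. Precision = TP/(TP+FP) is reported as `NA` (absent, not 0)
#' at cutoffs with no predicted positives; recall = TP/(TP+FN).
#'
#' @param prob numeric good-class probabilities in \[0, 1\].
#' @param truth logical (or factor coercible to logical) true 'good' labels;
#'   both classes must be present.
#' @param cutoffs probability grid (default 0 to 1 by 0.01).
#' @return data.frame of class `pr_curve`: `cutoff`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`; attribute `point_05` holds the precision/recall
#'   pair at cutoff 0.5.
#' @export
precision_recall <- function(prob, truth, cutoffs = seq(0, 1, by = 0.01)) {
  if (is.factor(truth)) truth <- truth == "good" | truth == TRUE
  truth <- as.logical(truth)
  stopifnot(all(prob >= 0 & prob <= 1), !anyNA(truth))
  if (!any(truth) || all(truth)) stop("both classes must be present in truth")
  rows <- lapply(cutoffs, function(ct) {
    pred <- prob >= ct
    tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    data.frame(cutoff = ct, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
               recall = tp / (tp + fn))
  })
  out <- do.call(rbind, rows)
  i05 <- which.min(abs(out$cutoff - 0.5))
  attr(out, "point_05") <- out[i05, c("precision", "recall")]
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Sweep the good/bad decision threshold
#'
#' Repeats [predict_hp_classification()] for `n_thresholds` evenly spaced
#' biomass cutoffs centered on (and including) the mean, spanning the bulk
#' of the biomass distribution while staying strictly inside its range.
#' Thresholds that empty a class are reported as degenerate.
#'
#' @inheritParams predict_hp_classification
#' @param scenario scenario id used for every threshold (default `"Top5"`).
#' @param n_thresholds default 9.
#' @param repetitions default 5 (the sweep repeats the full classification
#'   procedure per threshold).
#' @return data.frame: `threshold`, `degenerate`, `n_good`, `n_bad`, and
#'   median `accuracy` / `kappa` / `auc` over repetitions.
#' @export
threshold_sweep <- function(xdf, pheno, ranking, scenario = "Top5",
                            n_thresholds = 9L, repetitions = 5L,
                            cv_folds = 3L, cv_reps = 5L, seed = 1L,
                            grid = NULL) {
  inp <- align_hp_inputs(xdf, pheno)
  y <- inp$y
  m <- mean(y)
  span <- 0.9 * min(m - min(y), max(y) - m)
  thrs <- m + seq(-1, 1, length.out = n_thresholds) * span
  scn <- hp_scenarios(scenario)
  seeds <- derive_seeds(seed, n_thresholds)
  rows <- lapply(seq_along(thrs), function(i) {
    th <- thrs[i]
    ng <- sum(y >= th); nb <- sum(y < th)
    if (ng < 4L || nb < 4L)
      return(data.frame(threshold = th, degenerate = TRUE, n_good = ng,
                        n_bad = nb, accuracy = NA, kappa = NA, auc = NA))
    ev <- predict_hp_classification(xdf, pheno, ranking, scenarios = scn,
                                    threshold = th,
                                    repetitions = repetitions,
                                    cv_folds = cv_folds, cv_reps = cv_reps,
                                    seed = seeds[i], grid = grid)
    data.frame(threshold = th, degenerate = FALSE, n_good = ng, n_bad = nb,
               accuracy = stats::median(ev$accuracy),
               kappa = stats::median(ev$kappa),
               auc = stats::median(ev$auc, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
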