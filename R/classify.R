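# Seven multi-class classifiers of the metabolic inheritance pattern,
# behind a single fit/predict/tune interface. Each method exposes:
#   grid(x, y)      -> data.frame of tuning-parameter combinations
#   fit(x, y, par, w)  -> fitted model
#   predict(model, x)  -> factor of class labels
# and optionally tune_eval(xtr, ytr, xva, yva, grid, w) -> kappa per grid
# row (used by glmnet to evaluate a whole lambda path from one fit).

# Median-heuristic RBF width: gamma0 = 1 / median squared distance.
rbf_gamma0 <- function(x, max_n = 200L) {
  n <- nrow(x)
  if (n > max_n) x <- x[sample.int(n, max_n), , drop = FALSE]
  d2 <- as.vector(stats::dist(x))^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) 1 / ncol(x) else 1 / m
}

svm_method <- function(weighted) {
  list(
    grid = function(x, y) {
      g0 <- rbf_gamma0(x)
      expand.grid(cost = 2^seq(-2, 6, by = 1),
                  gamma = g0 * c(0.5, 1, 2))
    },
    fit = function(x, y, par, w) {
      e1071::svm(x, y, kernel = "radial", cost = par$cost, gamma = par$gamma,
                 class.weights = if (weighted) class_weights(levels(y)) else NULL,
                 probability = FALSE)
    },
    predict = function(model, x) predict(model, x)
  )
}

rf_method <- function(weighted) {
  list(
    grid = function(x, y) {
      p <- ncol(x)
      mtry <- unique(pmax(1L, round(sqrt(p) * c(0.5, 1, 2))))
      expand.grid(mtry = mtry, min.node.size = c(1L, 5L))
    },
    fit = function(x, y, par, w) {
      cw <- if (weighted) unname(class_weights(levels(y))) else NULL
      ranger::ranger(x = x, y = y, num.trees = 500,
                     mtry = min(par$mtry, ncol(x)),
                     min.node.size = par$min.node.size,
                     class.weights = cw, num.threads = 1L,
                     verbose = FALSE)
    },
    predict = function(model, x) predict(model, data = x)$predictions
  )
}

plsda_method <- function() {
  list(
    grid = function(x, y) {
      data.frame(ncomp = seq_len(min(10L, ncol(x) - 1L, nrow(x) - 2L)))
    },
    fit = function(x, y, par, w) {
      f <- mixOmics::plsda(x, y, ncomp = par$ncomp)
      f$.levels <- levels(y)
      f
    },
    predict = function(model, x) {
      cl <- predict(model, x)$class$max.dist
      factor(cl[, ncol(cl)], levels = model$.levels)
    }
  )
}

plsrf_method <- function() {
  list(
    grid = function(x, y) {
      nc <- min(6L, ncol(x) - 1L, nrow(x) - 2L)
      expand.grid(ncomp = unique(pmin(nc, c(2L, 4L, 6L))),
                  min.node.size = c(1L, 5L))
    },
    fit = function(x, y, par, w) {
      pf <- mixOmics::pls(x, mixOmics::unmap(y), ncomp = par$ncomp,
                          mode = "regression")
      sc <- pf$variates$X
      rf <- ranger::ranger(x = sc, y = y, num.trees = 500,
                           min.node.size = par$min.node.size,
                           num.threads = 1L, verbose = FALSE)
      list(pls = pf, rf = rf, levels = levels(y))
    },
    predict = function(model, x) {
      sc <- predict(model$pls, x)$variates
      colnames(sc) <- colnames(model$pls$variates$X)
      predict(model$rf, data = sc)$predictions
    }
  )
}

glmnet_method <- function() {
  lambdas <- 10^seq(0, -3, length.out = 8)
  list(
    grid = function(x, y) expand.grid(alpha = seq(0.1, 1, by = 0.1),
                                      lambda = lambdas),
    fit = function(x, y, par, w) {
      # small strata routinely trip glmnet's small-class advisory; expected here
      f <- suppressWarnings(
        glmnet::glmnet(x, y, family = "multinomial", alpha = par$alpha,
                       lambda = lambdas))
      f$.s <- par$lambda; f$.levels <- levels(y)
      f
    },
    predict = function(model, x) {
      cl <- predict(model, x, s = model$.s, type = "class")
      factor(as.vector(cl), levels = model$.levels)
    },
    # one glmnet fit per alpha evaluates the entire lambda path
    tune_eval = function(xtr, ytr, xva, yva, grid, w) {
      out <- rep(NA_real_, nrow(grid))
      for (a in unique(grid$alpha)) {
        rows <- which(grid$alpha == a)
        f <- tryCatch(suppressWarnings(
          glmnet::glmnet(xtr, ytr, family = "multinomial",
                         alpha = a, lambda = lambdas)),
          error = function(e) NULL)
        if (is.null(f)) next
        cl <- predict(f, xva, s = grid$lambda[rows], type = "class")
        for (k in seq_along(rows))
          out[rows[k]] <- kappa_of(factor(cl[, k], levels = levels(ytr)),
                                   yva, levels(ytr))
      }
      out
    }
  )
}

mip_method_registry <- function() {
  list(plsda = plsda_method(), glmnet = glmnet_method(),
       plsrf = plsrf_method(), svm = svm_method(FALSE),
       svmw = svm_method(TRUE), rf = rf_method(FALSE),
       rfw = rf_method(TRUE))
}

#' Names of the seven mIP classifiers
#' @return character vector: `plsda`, `glmnet`, `plsrf`, `svm`, `svmw`,
#'   `rf`, `rfw`.
#' @export
mip_methods <- function() names(mip_method_registry())

# Grid-search tuning: stratified cv_folds-fold CV repeated cv_reps times,
# maximizing the mean held-out kappa. Returns best parameter row.
tune_model <- function(method, x, y, cv_folds = 3L, cv_reps = 5L,
                       grid = NULL) {
  grid <- grid %||% method$grid(x, y)
  scores <- matrix(NA_real_, 0L, nrow(grid))
  for (r in seq_len(cv_reps)) {
    fold <- stratified_folds(y, cv_folds)
    for (k in seq_len(cv_folds)) {
      tr <- fold != k
      if (length(unique(y[tr])) < 2L || !any(!tr)) next
      ytr <- droplevels(y[tr])
      if (!is.null(method$tune_eval)) {
        sc <- method$tune_eval(x[tr, , drop = FALSE], ytr,
                               x[!tr, , drop = FALSE], y[!tr], grid, NULL)
      } else {
        sc <- vapply(seq_len(nrow(grid)), function(i) {
          f <- tryCatch(method$fit(x[tr, , drop = FALSE], ytr,
                                   grid[i, , drop = FALSE], NULL),
                        error = function(e) NULL)
          if (is.null(f)) return(NA_real_)
          pr <- method$predict(f, x[!tr, , drop = FALSE])
          kappa_of(pr, y[!tr], levels(y))
        }, numeric(1))
      }
      scores <- rbind(scores, sc)
    }
  }
  mean_sc <- colMeans(scores, na.rm = TRUE)
  mean_sc[is.nan(mean_sc)] <- -Inf
  best <- which.max(mean_sc)
  list(par = grid[best, , drop = FALSE], cv_kappa = mean_sc[best],
       grid = grid, scores = mean_sc)
}

#' Evaluate the seven mIP classifiers over the encoded analytes
#'
#' For every (method, encoded analyte, repetition): a stratified random
#' 75/25 train/test partition, grid-search tuning by stratified 3-fold
#' cross-validation (repeated) maximizing Cohen's kappa on the training
#' set, then kappa of the tuned model on the held-out 25%. With
#' `permute = TRUE` the analyte's labels are randomly permuted once before
#' the whole procedure (the permutation null).
#'
#' @param xdf [build_predictor_matrix()] output.
#' @param labels filtered `inheritance_matrix` ([class_balance_filter()]).
#' @param methods subset of [mip_methods()].
#' @param repetitions outer repetitions per (method, analyte); default 5.
#' @param train_fraction default 0.75.
#' @param cv_folds,cv_reps inner cross-validation (default 3-fold, 5 reps).
#' @param permute permutation-null flag.
#' @param seed master seed; expands deterministically into
#'   per-(method, analyte, repetition) streams.
#' @param grids optional named list method -> tuning grid data.frame
#'   overriding the defaults (e.g. to scale the search down).
#' @return data.frame of class `model_eval`: `method`, `analyte`, `rep`,
#'   `kappa`, `params`, `permuted`. Skipped repetitions (a training class
#'   smaller than the fold count) carry `NA` kappa; attribute `skipped`
#'   logs them.
#' @export
evaluate_classifiers <- function(xdf, labels, methods = mip_methods(),
                                 repetitions = 5L, train_fraction = 0.75,
                                 cv_folds = 3L, cv_reps = 5L,
                                 permute = FALSE, seed = 1L, grids = NULL) {
  registry <- mip_method_registry()
  bad <- setdiff(methods, names(registry))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  analytes <- colnames(labels)
  x_all <- unclass(xdf)
  n_tasks <- length(methods) * length(analytes) * repetitions
  seeds <- derive_seeds(seed, n_tasks + length(analytes))
  perm_seeds <- tail(seeds, length(analytes))
  res <- vector("list", n_tasks)
  skipped <- list()
  t <- 0L
  for (ai in seq_along(analytes)) {
    a <- analytes[ai]
    keep <- !is.na(labels[, a])
    y <- factor(labels[keep, a])
    x <- x_all[rownames(labels)[keep], , drop = FALSE]
    if (permute) {
      set.seed(perm_seeds[ai])
      y <- sample(y)
    }
    for (m in methods) {
      method <- registry[[m]]
      for (r in seq_len(repetitions)) {
        t <- t + 1L
        set.seed(seeds[t])
        tr <- stratified_train_idx(y, train_fraction)
        ytr <- y[tr]
        if (min(table(ytr)) < cv_folds) {
          skipped[[length(skipped) + 1L]] <-
            data.frame(method = m, analyte = a, rep = r,
                       reason = "training stratum smaller than fold count")
          res[[t]] <- data.frame(method = m, analyte = a, rep = r,
                                 kappa = NA_real_, params = NA_character_,
                                 permuted = permute)
          next
        }
        tn <- tune_model(method, x[tr, , drop = FALSE], ytr,
                         cv_folds = cv_folds, cv_reps = cv_reps,
                         grid = grids[[m]])
        fit <- method$fit(x[tr, , drop = FALSE], ytr, tn$par, NULL)
        pr <- method$predict(fit, x[-tr, , drop = FALSE])
        k <- kappa_of(pr, y[-tr], levels(y))
        res[[t]] <- data.frame(
          method = m, analyte = a, rep = r, kappa = k,
          params = paste(names(tn$par), unlist(tn$par), sep = "=",
                         collapse = ";"),
          permuted = permute)
      }
    }
  }
  out <- do.call(rbind, res)
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  class(out) <- c("model_eval", "data.frame")
  out
}

#' Select the ranking classifier by coefficient of variation of kappa
#'
#' Pools every (analyte x repetition) test kappa per method and returns the
#' method minimizing CV = sd/mean. Methods with non-positive mean kappa
#' have undefined CV and are excluded.
#'
#' @param evals `model_eval` from [evaluate_classifiers()] (observed, not
#'   permuted).
#' @return list with `method` (selected name) and `table` (per-method n,
#'   mean, sd, cv).
#' @export
select_ranking_model <- function(evals) {
  ev <- evals[!is.na(evals$kappa) & !evals$permuted, ]
  if (!nrow(ev)) stop("no kappa values to select from")
  tab <- do.call(rbind, lapply(split(ev$kappa, ev$method), function(k) {
    data.frame(n = length(k), mean = mean(k),
               sd = if (length(k) > 1L) stats::sd(k) else NA_real_)
  }))
  tab$method <- rownames(tab); rownames(tab) <- NULL
  tab$cv <- ifelse(tab$mean > 0 & !is.na(tab$sd), tab$sd / tab$mean, NA_real_)
  ok <- tab[!is.na(tab$cv), ]
  if (!nrow(ok)) stop("no method with positive mean kappa and >= 2 values")
  list(method = ok$method[which.min(ok$cv)],
       table = tab[, c("method", "n", "mean", "sd", "cv")])
}
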