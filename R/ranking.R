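#' Filter (model-agnostic) variable importance by one-vs-rest AUC
#'
#' For every predictor column and every realized class, the AUC of the
#' column separating that class from the rest is computed (folded about 0.5
#' so that direction does not matter); the per-column importance is the
#' mean over classes, scaled so the best column is 100. This is the
#' standard model-agnostic importance for kernel classifiers without a
#' native importance measure.
#'
#' @param x numeric matrix (samples x predictors).
#' @param y factor response.
#' @return named numeric vector of importances in (0, 100\].
#' @export
filter_importance <- function(x, y) {
  y <- droplevels(as.factor(y))
  imp <- vapply(seq_len(ncol(x)), function(j) {
    aucs <- vapply(levels(y), function(lev) {
      a <- rank_auc(x[, j], y == lev)
      max(a, 1 - a)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  names(imp) <- colnames(x)
  imp * 100 / max(imp)
}

# Per-analyte importance for one method. Model-based measures (random
# forest impurity, elastic-net coefficients) are used where the method has
# one; kernel and PLS-based methods use the filter AUC importance, with a
# permutation importance available on request.
analyte_importance <- function(x, y, method_name, importance = "auto",
                               cv_folds = 3L, cv_reps = 10L, grid = NULL,
                               n_perm = 1L) {
  if (importance == "auto")
    importance <- switch(method_name,
                         rf = , rfw = "impurity",
                         glmnet = "coef",
                         "auc")
  registry <- mip_method_registry()
  method <- registry[[method_name]]
  scale100 <- function(v) {
    v <- pmax(v, 0)
    if (max(v) <= 0) return(setNames(rep(0, length(v)), names(v)))
    v * 100 / max(v)
  }
  if (importance == "auc") return(filter_importance(x, y))
  tn <- tune_model(method, x, y, cv_folds = cv_folds, cv_reps = cv_reps,
                   grid = grid)
  if (importance == "impurity") {
    cw <- if (method_name == "rfw") unname(class_weights(levels(y))) else NULL
    f <- ranger::ranger(x = x, y = y, num.trees = 500,
                        mtry = min(tn$par$mtry %||% floor(sqrt(ncol(x))), ncol(x)),
                        min.node.size = tn$par$min.node.size %||% 1L,
                        class.weights = cw, importance = "impurity",
                        num.threads = 1L, verbose = FALSE)
    return(scale100(f$variable.importance[colnames(x)]))
  }
  if (importance == "coef") {
    f <- suppressWarnings(
      glmnet::glmnet(x, y, family = "multinomial", alpha = tn$par$alpha,
                     lambda = sort(unique(tn$grid$lambda), decreasing = TRUE)))
    co <- stats::coef(f, s = tn$par$lambda)
    v <- Reduce(`+`, lapply(co, function(m) abs(as.numeric(m)[-1]))) / length(co)
    return(scale100(setNames(v, colnames(x))))
  }
  if (importance == "permutation") {
    fit <- method$fit(x, y, tn$par, NULL)
    base <- kappa_of(method$predict(fit, x), y, levels(y))
    drop <- vapply(seq_len(ncol(x)), function(j) {
      d <- 0
      for (b in seq_len(n_perm)) {
        xp <- x; xp[, j] <- sample(xp[, j])
        d <- d + (base - kappa_of(method$predict(fit, xp), y, levels(y)))
      }
      d / n_perm
    }, numeric(1))
    return(scale100(setNames(drop, colnames(x))))
  }
  stop("unknown importance measure: ", importance)
}

#' Rank the parental analytes by median variable importance
#'
#' Trains the selected classifier once per encoded analyte on the full
#' sample (tuned by repeated stratified cross-validation where the
#' importance measure is model-based) and extracts the per-column variable
#' importance scaled to \[0, 100\] within each model. The final score per
#' parental column is the median over the encoded-analyte models; the
#' ranking is a strict total order (ties broken lexicographically by
#' column id).
#'
#' @param xdf [build_predictor_matrix()] output.
#' @param labels filtered `inheritance_matrix`.
#' @param method one of [mip_methods()]; typically the
#'   [select_ranking_model()] winner.
#' @param importance `"auto"` (default; AUC filter importance for
#'   kernel/PLS methods, impurity for random forests, coefficients for the
#'   elastic net), or one of `"auc"`, `"impurity"`, `"coef"`,
#'   `"permutation"`.
#' @param cv_folds,cv_reps inner tuning (default 3-fold, 10 reps) for
#'   model-based importance.
#' @param seed master seed.
#' @param grids optional named list method -> grid override.
#' @return data.frame of class `analyte_ranking`: `column`, `analyte`,
#'   `origin`, `median_importance`, `importance_sd`, `rank` (1 = most
#'   important), ordered by rank. Attribute `per_analyte`: the column x
#'   encoded-analyte importance matrix.
#' @export
rank_parental_analytes <- function(xdf, labels, method = "svmw",
                                   importance = "auto", cv_folds = 3L,
                                   cv_reps = 10L, seed = 1L, grids = NULL) {
  analytes <- colnames(labels)
  x_all <- unclass(xdf)
  seeds <- derive_seeds(seed, length(analytes))
  impmat <- matrix(NA_real_, ncol(x_all), length(analytes),
                   dimnames = list(colnames(x_all), analytes))
  for (ai in seq_along(analytes)) {
    a <- analytes[ai]
    keep <- !is.na(labels[, a])
    y <- factor(labels[keep, a])
    x <- x_all[rownames(labels)[keep], , drop = FALSE]
    set.seed(seeds[ai])
    imp <- tryCatch(
      analyte_importance(x, y, method, importance, cv_folds, cv_reps,
                         grid = grids[[method]]),
      error = function(e) {
        warning("importance model failed for analyte ", a, ": ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(imp)) impmat[names(imp), ai] <- imp
  }
  med <- apply(impmat, 1, stats::median, na.rm = TRUE)
  sds <- apply(impmat, 1, stats::sd, na.rm = TRUE)
  ord <- order(-med, rownames(impmat))
  out <- data.frame(column = rownames(impmat)[ord],
                    analyte = attr(xdf, "analyte")[ord],
                    origin = attr(xdf, "origin")[ord],
                    median_importance = med[ord],
                    importance_sd = sds[ord],
                    rank = seq_along(ord),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "per_analyte") <- impmat
  attr(out, "method") <- method
  class(out) <- c("analyte_ranking", "data.frame")
  out
}

#' Concordance diagnostics between the maternal and paternal rankings
#'
#' Each analyte appears once in the Dent (maternal) block and once in the
#' Flint (paternal) block of the predictor matrix. This computes Kendall's
#' tau between the within-block rank positions of the shared analyte
#' identities (association of the two parental orders) and the cumulative
#' relative frequency of each parental origin scanning the overall ranking
#' from the top.
#'
#' @param ranking [rank_parental_analytes()] output.
#' @return list with `tau`, `p` (Kendall test) and `curves`
#'   (data.frame: rank, cumulative relative frequency of Dent and Flint
#'   columns).
#' @export
rank_diagnostics <- function(ranking) {
  d <- ranking[ranking$origin == "dent", ]
  f <- ranking[ranking$origin == "flint", ]
  if (!nrow(d) || !nrow(f)) stop("both parental blocks must be non-empty")
  pos_d <- setNames(rank(d$rank), d$analyte)   # within-block positions
  pos_f <- setNames(rank(f$rank), f$analyte)
  shared <- intersect(names(pos_d), names(pos_f))
  kt <- stats::cor.test(pos_d[shared], pos_f[shared], method = "kendall")
  cum_d <- cumsum(ranking$origin == "dent") / sum(ranking$origin == "dent")
  cum_f <- cumsum(ranking$origin == "flint") / sum(ranking$origin == "flint")
  list(tau = unname(kt$estimate), p = kt$p.value,
       curves = data.frame(rank = ranking$rank, cum_dent = cum_d,
                           cum_flint = cum_f))
}
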