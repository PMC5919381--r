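#' Remove redundant (highly correlated) analytes
#'
#' Identifies all analyte pairs whose Pearson correlation exceeds
#' `r_threshold` and, in each pair, removes the member with the greater
#' average (signed) correlation with all other analytes. Correlations are
#' computed over genotype-mean profiles (parents and hybrids pooled) so that
#' replicate pseudo-replication does not inflate them. Pairs are resolved
#' greedily in one pass, in decreasing order of r; ties on the mean
#' correlation are broken by dropping the lexicographically later analyte
#' id. Zero-variance analytes have undefined correlations and are dropped
#' first.
#'
#' @param profiles [profile_matrix()].
#' @param r_threshold correlation threshold in (0, 1]; default 0.85.
#' @param iterative recompute mean correlations among the still-retained
#'   analytes after every removal instead of the default one-pass greedy
#'   resolution.
#' @return list with `retained` (character, analyte ids in input order) and
#'   `log` (data.frame: one row per resolved pair or degenerate analyte,
#'   with the pair, its r, the dropped member and both mean correlations).
#' @export
redundancy_filter <- function(profiles, r_threshold = 0.85, iterative = FALSE) {
  stopifnot(r_threshold > 0, r_threshold <= 1)
  gm <- genotype_means(profiles)
  ids <- colnames(gm)
  if (length(ids) < 2L) stop("need at least 2 analytes")
  log <- data.frame(analyte_a = character(), analyte_b = character(),
                    r = numeric(), dropped = character(),
                    mean_r_a = numeric(), mean_r_b = numeric(),
                    stringsAsFactors = FALSE)
  sds <- apply(gm, 2, stats::sd)
  constant <- ids[sds == 0 | !is.finite(sds)]
  if (length(constant)) {
    log <- rbind(log, data.frame(analyte_a = constant, analyte_b = NA,
                                 r = NA, dropped = constant,
                                 mean_r_a = NA, mean_r_b = NA))
    gm <- gm[, setdiff(ids, constant), drop = FALSE]
    ids <- colnames(gm)
  }

  drop_one <- function(a, b, ra, rb) {
    # drop the member with the larger mean signed r; lexicographic tie-break
    if (ra > rb) a
    else if (rb > ra) b
    else max(a, b)
  }

  if (!iterative) {
    cm <- stats::cor(gm)
    mean_r <- (rowSums(cm) - 1) / (ncol(cm) - 1)
    ut <- which(upper.tri(cm) & cm > r_threshold, arr.ind = TRUE)
    if (nrow(ut)) {
      ord <- order(cm[ut], decreasing = TRUE)
      ut <- ut[ord, , drop = FALSE]
      dropped <- character(0)
      for (k in seq_len(nrow(ut))) {
        a <- ids[ut[k, 1]]; b <- ids[ut[k, 2]]
        if (a %in% dropped || b %in% dropped) next
        d <- drop_one(a, b, mean_r[a], mean_r[b])
        dropped <- c(dropped, d)
        log <- rbind(log, data.frame(analyte_a = a, analyte_b = b,
                                     r = cm[ut[k, 1], ut[k, 2]], dropped = d,
                                     mean_r_a = mean_r[a], mean_r_b = mean_r[b]))
      }
      ids <- setdiff(ids, dropped)
    }
  } else {
    repeat {
      if (length(ids) < 2L) break
      cm <- stats::cor(gm[, ids, drop = FALSE])
      mean_r <- (rowSums(cm) - 1) / (ncol(cm) - 1)
      ut <- which(upper.tri(cm) & cm > r_threshold, arr.ind = TRUE)
      if (!nrow(ut)) break
      k <- which.max(cm[ut])
      a <- ids[ut[k, 1]]; b <- ids[ut[k, 2]]
      d <- drop_one(a, b, mean_r[a], mean_r[b])
      log <- rbind(log, data.frame(analyte_a = a, analyte_b = b,
                                   r = cm[ut[k, 1], ut[k, 2]], dropped = d,
                                   mean_r_a = mean_r[a], mean_r_b = mean_r[b]))
      ids <- setdiff(ids, d)
    }
  }
  list(retained = ids, log = log)
}

#' Build the standardized concatenated parental predictor matrix
#'
#' For every cross, the Dent parent's replicate-mean profile and the Flint
#' parent's replicate-mean profile (over the retained analytes) are
#' concatenated, Dent block first; the resulting |H| x (2 m) matrix is then
#' z-scored column-wise over the crosses.
#'
#' @param design [mating_design()].
#' @param profiles [profile_matrix()].
#' @param retained character vector of retained analyte ids.
#' @param standardize z-score the columns (default `TRUE`; `FALSE` exposes
#'   the raw concatenated means, mainly for testing).
#' @return numeric matrix of class `predictor_matrix` with rownames the
#'   cross ids (design order) and attributes `analyte` and `origin`
#'   (`"dent"`/`"flint"` per column).
#' @export
build_predictor_matrix <- function(design, profiles, retained,
                                   standardize = TRUE) {
  gm <- genotype_means(profiles)
  miss <- setdiff(retained, colnames(gm))
  if (length(miss)) stop("unknown analyte id(s): ", paste(miss, collapse = ", "))
  cr <- design$crosses
  bad <- cr$cross_id[!(cr$dent %in% rownames(gm)) | !(cr$flint %in% rownames(gm))]
  if (length(bad))
    stop("cross(es) with missing parental profiles: ", paste(bad, collapse = ", "))
  xd <- gm[cr$dent, retained, drop = FALSE]
  xf <- gm[cr$flint, retained, drop = FALSE]
  x <- cbind(xd, xf)
  colnames(x) <- c(paste0(retained, "_D"), paste0(retained, "_F"))
  rownames(x) <- cr$cross_id
  if (standardize) {
    mu <- colMeans(x)
    s <- apply(x, 2, stats::sd)
    zero <- colnames(x)[s == 0]
    if (length(zero))
      stop("zero-variance predictor column(s): ", paste(zero, collapse = ", "))
    x <- scale(x, center = mu, scale = s)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
  }
  structure(x,
            analyte = rep(retained, 2L),
            origin = rep(c("dent", "flint"), each = length(retained)),
            class = c("predictor_matrix", class(x)))
}
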