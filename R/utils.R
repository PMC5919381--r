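#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic vector of sub-seeds from one master seed
#'
#' Expands a single master seed into `n` independent stream seeds so that
#' per-(method, analyte, repetition) computations are reproducible and
#' order-independent. Seeds stay below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

# Stratified train indices: per class, round(frac * n_k) samples (at least 1
# when the class has >= 2 members; a singleton class goes to the training set).
stratified_train_idx <- function(y, frac) {
  y <- as.factor(y)
  idx <- integer(0)
  for (lev in levels(y)) {
    rows <- which(y == lev)
    nk <- length(rows)
    if (nk == 0L) next
    ntr <- if (nk == 1L) 1L else max(1L, min(nk - 1L, round(frac * nk)))
    idx <- c(idx, if (nk == 1L) rows else sample(rows, ntr))
  }
  sort(idx)
}

# Stratified k-fold assignment (vector of fold ids, length(y)).
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    rows <- which(y == lev)
    if (!length(rows)) next
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  fold
}

# Rank-based two-group AUC of a score separating `pos` from the rest
# (Mann-Whitney identity); cross-checked against pROC in the test suite.
rank_auc <- function(score, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

mip_levels <- function() c("-2", "-1", "0", "1", "2")

#' Map the five symmetric class weights onto realized mIP classes
#'
#' The weight vector is indexed by class magnitude: additivity gets the
#' smallest weight, dominance an intermediate one and overdominance the
#' largest, symmetrically for the negative classes.
#'
#' @param levels character vector of class labels (subset of `"-2"..."2"`).
#' @param weights length-5 numeric `c(w-OD, w-D, wA, w+D, w+OD)`;
#'   default `c(10, 5, 1, 5, 10)`.
#' @return named numeric vector over `levels`.
#' @export
class_weights <- function(levels, weights = c(10, 5, 1, 5, 10)) {
  stopifnot(length(weights) == 5L)
  if (weights[1] != weights[5] || weights[2] != weights[4])
    stop("class weights must be symmetric (w-OD = w+OD, w-D = w+D)")
  if (weights[3] > min(weights))
    stop("additivity weight must be minimal")
  full <- setNames(weights, mip_levels())
  setNames(full[match(as.character(levels), names(full))], levels)
}
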