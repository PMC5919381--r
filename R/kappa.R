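#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with `p_o`
#' the observed accuracy and `p_e` the expected accuracy of a random
#' classifier with the same marginals. In the degenerate single-class case
#' (`p_e = 1`) kappa is defined as 0.
#'
#' @param confusion square k x k matrix of non-negative counts (rows =
#'   predicted, columns = reference, or vice versa — kappa is symmetric in
#'   the orientation).
#' @return kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(confusion) {
  m <- as.matrix(confusion)
  if (!length(m) || nrow(m) != ncol(m)) stop("confusion matrix must be square and non-empty")
  if (any(m < 0)) stop("negative counts")
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

# Confusion matrix over a fixed level set.
confusion_matrix <- function(pred, truth, levels) {
  table(factor(pred, levels = levels), factor(truth, levels = levels))
}

kappa_of <- function(pred, truth, levels) {
  cohen_kappa(confusion_matrix(pred, truth, levels))
}
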