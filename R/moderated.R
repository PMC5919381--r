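#' Inverse of the trigamma function
#'
#' Solves `trigamma(y) = x` for `y > 0` by Newton iteration on `1/trigamma`
#' (which is nearly linear), the standard approach for empirical-Bayes
#' variance-prior estimation.
#'
#' @param x positive numeric vector.
#' @return numeric vector `y` with `trigamma(y) = x`; `Inf` for `x <= 0`.
#' @export
trigamma_inverse <- function(x) {
  out <- x
  out[x <= 0] <- Inf
  big <- is.finite(x) & x > 1e7
  out[big] <- 1 / sqrt(x[big])
  small <- is.finite(x) & x < 1e-6 & x > 0
  out[small] <- 1 / x[small]
  mid <- is.finite(x) & x > 0 & !big & !small
  if (any(mid)) {
    y <- 0.5 + 1 / x[mid]
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[mid]) / psigamma(y, 2)
      y <- y + dif
      if (max(-dif / y) < 1e-8) break
    }
    out[mid] <- y
  }
  out
}

#' Estimate the empirical-Bayes variance prior (d0, s0^2)
#'
#' Method-of-moments fit on the log sample variances: with residual
#' variances `s2` on `df` degrees of freedom drawn from a scaled chi-square
#' around a common prior variance, `log(s2)` has known mean and variance
#' expressed through digamma/trigamma functions, which are inverted to give
#' the prior degrees of freedom `d0` and prior variance `s02`. When the
#' spread of the log variances is at or below its pure-sampling floor, the
#' prior is degenerate: `d0 = Inf` and `s02` the common variance.
#'
#' @param s2 numeric vector of positive sample variances (one per analyte).
#' @param df residual degrees of freedom (scalar or vector).
#' @return list with `d0` (prior df, possibly `Inf`) and `s02` (prior
#'   variance).
#' @export
estimate_variance_prior <- function(s2, df) {
  stopifnot(length(s2) >= 2L)
  df <- rep_len(df, length(s2))
  if (all(s2 <= 0)) stop("degenerate variances: all sample variances are zero")
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2L) stop("need at least 2 finite positive variances")
  if (any(!ok)) warning(sum(!ok), " non-positive variance(s) ignored")
  s2 <- s2[ok]; df <- df[ok]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # spread of log variances at/below its sampling floor: degenerate prior,
    # all true variances equal; pool the observed ones
    d0 <- Inf
    s02 <- mean(s2)
  }
  list(d0 = d0, s02 = s02)
}

# Moderated variance: weighted combination of prior and observed.
squeeze_var <- function(s2, df, d0, s02) {
  if (is.infinite(d0)) rep_len(s02, length(s2))
  else if (d0 == 0) s2
  else (d0 * s02 + df * s2) / (d0 + df)
}

#' Moderated t-contrasts for one cross (Dent, Flint, hybrid)
#'
#' Fits, per analyte, a one-way three-group model to the replicate profiles
#' of one cross, pools the residual variance across the three groups,
#' shrinks it toward the empirical-Bayes prior, and reports moderated
#' t-statistics and two-sided p-values for the two contrasts hybrid - b and
#' hybrid - w, where b (w) is the parent with the higher (lower) group mean
#' for that analyte. No multiplicity adjustment is applied.
#'
#' @param values replicate x analyte numeric matrix for the three genotypes
#'   of a single cross.
#' @param genotype character vector of genotype ids, one per row.
#' @param role named character vector mapping the three genotypes to
#'   `"dent"`, `"flint"`, `"hybrid"`.
#' @param prior optional list `(d0, s02)`; by default the prior is
#'   estimated from this subset's per-analyte residual variances.
#'   `prior = list(d0 = 0)` gives ordinary (unmoderated) t-statistics.
#' @return object of class `contrast_result`: data.frame with per-analyte
#'   group means, residual variance `s2` (df in attribute), moderated
#'   variance `s2_tilde`, the identity of `b`, and estimate/t/p/sign for
#'   both contrasts. Attributes: `d0`, `s02`, `df_resid`, `n` per group.
#' @export
moderated_contrasts <- function(values, genotype, role, prior = NULL) {
  values <- as.matrix(values)
  genotype <- as.character(genotype)
  stopifnot(nrow(values) == length(genotype))
  genos <- unique(genotype)
  rl <- role[genos]
  if (!setequal(rl, c("dent", "flint", "hybrid")) || length(genos) != 3L)
    stop("subset must contain exactly one dent, one flint and one hybrid")
  gd <- genos[rl == "dent"]; gf <- genos[rl == "flint"]; gh <- genos[rl == "hybrid"]
  n <- table(factor(genotype, levels = genos))
  few <- genos[n < 2L]
  if (length(few)) stop("genotype with fewer than 2 replicates: ",
                        paste(few, collapse = ", "))
  idx <- split(seq_along(genotype), genotype)
  mean_of <- function(g) colMeans(values[idx[[g]], , drop = FALSE])
  m_d <- mean_of(gd); m_f <- mean_of(gf); m_h <- mean_of(gh)
  css <- function(g) {
    v <- values[idx[[g]], , drop = FALSE]
    colSums(sweep(v, 2, colMeans(v))^2)
  }
  df_resid <- sum(n) - 3L
  s2 <- (css(gd) + css(gf) + css(gh)) / df_resid

  if (is.null(prior)) prior <- estimate_variance_prior(s2, df_resid)
  d0 <- prior$d0
  s02 <- prior$s02 %||% NA_real_
  if (d0 > 0 && !is.finite(s02) && !is.infinite(d0))
    stop("prior with d0 > 0 requires s02")
  s2t <- squeeze_var(s2, df_resid, d0, s02)
  # total df capped at the pooled residual df of the subset: the prior can
  # never carry more information than all analytes' residuals combined
  df_total <- min(d0 + df_resid, df_resid * ncol(values))

  b_is_dent <- m_d >= m_f
  m_b <- ifelse(b_is_dent, m_d, m_f)
  m_w <- ifelse(b_is_dent, m_f, m_d)
  n_b <- ifelse(b_is_dent, n[[gd]], n[[gf]])
  n_w <- ifelse(b_is_dent, n[[gf]], n[[gd]])
  n_h <- n[[gh]]

  tstat <- function(est, n_par) {
    se <- sqrt(s2t * (1 / n_h + 1 / n_par))
    t <- ifelse(est == 0, 0, est / se)
    t[se == 0 & est != 0] <- sign(est[se == 0 & est != 0]) * Inf
    t
  }
  est_hb <- m_h - m_b; est_hw <- m_h - m_w
  t_hb <- tstat(est_hb, n_b); t_hw <- tstat(est_hw, n_w)
  pval <- function(t) 2 * stats::pt(-abs(t), df = df_total)

  structure(data.frame(analyte = colnames(values) %||%
                         paste0("a", seq_along(m_d)),
                       mean_d = m_d, mean_f = m_f, mean_h = m_h,
                       s2 = s2, s2_tilde = s2t,
                       b = ifelse(b_is_dent, "dent", "flint"),
                       est_hb = est_hb, t_hb = t_hb, p_hb = pval(t_hb),
                       sign_hb = sign(est_hb),
                       est_hw = est_hw, t_hw = t_hw, p_hw = pval(t_hw),
                       sign_hw = sign(est_hw),
                       row.names = NULL, stringsAsFactors = FALSE),
            d0 = d0, s02 = s02, df_resid = df_resid,
            n = c(dent = n[[gd]], flint = n[[gf]], hybrid = n[[gh]]),
            class = c("contrast_result", "data.frame"))
}
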