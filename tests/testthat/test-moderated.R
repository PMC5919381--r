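test_that("trigamma inversion solves trigamma(y) = x to high precision", {
  x <- c(1e-5, 0.01, 0.1, 0.5, 1, 2, 5, 50, 1e4)
  y <- trigamma_inverse(x)
  expect_equal(trigamma(y), x, tolerance = 1e-6)
  expect_identical(trigamma_inverse(0), Inf)
  skip_if_not_installed("limma")
  expect_equal(y, limma::trigammaInverse(x), tolerance = 1e-6)
})

test_that("identical sample variances give a degenerate prior at the common value", {
  pr <- estimate_variance_prior(rep(2.5, 10), df = 4)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s02, 2.5)
})

test_that("the two-variance prior matches an independent root-finding oracle", {
  s2 <- c(1, exp(2)); df <- 4
  # oracle: invert the log-variance moment equations numerically
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  d0_oracle <- 2 * uniroot(function(y) trigamma(y) - evar,
                           c(1e-6, 50), tol = 1e-12)$root
  s02_oracle <- exp(mean(e) + digamma(d0_oracle / 2) - log(d0_oracle / 2))
  pr <- estimate_variance_prior(s2, df)
  expect_equal(pr$d0, d0_oracle, tolerance = 1e-8)
  expect_equal(pr$s02, s02_oracle, tolerance = 1e-8)
})

test_that("the prior recovers planted hyperparameters and agrees with limma", {
  set.seed(12)
  d0 <- 4; s02 <- 1; df <- 4; n <- 5000
  sigma2 <- s02 * d0 / rchisq(n, d0)          # scaled inverse chi-square
  s2 <- sigma2 * rchisq(n, df) / df
  pr <- estimate_variance_prior(s2, df)
  expect_lt(abs(pr$d0 - d0) / d0, 0.15)
  expect_lt(abs(pr$s02 - s02) / s02, 0.05)
  skip_if_not_installed("limma")
  ff <- limma::fitFDist(s2, df1 = df)
  expect_equal(pr$d0, ff$df2, tolerance = 1e-8)
  expect_equal(pr$s02, ff$scale, tolerance = 1e-8)
})

test_that("all-zero variances are rejected", {
  expect_error(estimate_variance_prior(c(0, 0, 0), 4), "degenerate")
})

test_that("identical group profiles give t = 0 and p = 1", {
  base <- c(1.0, 1.4, 0.6)   # same replicate values in all three genotypes
  vals <- matrix(rep(base, 3), 9, 2)
  colnames(vals) <- c("A1", "A2"); vals[, 2] <- vals[, 2] + 1
  geno <- rep(c("D1", "F1", "D1xF1"), each = 3)
  ct <- moderated_contrasts(vals, geno,
                            c(D1 = "dent", F1 = "flint", D1xF1 = "hybrid"))
  expect_equal(ct$t_hb, c(0, 0))
  expect_equal(ct$p_hb, c(1, 1))
  expect_equal(ct$t_hw, c(0, 0))
  expect_equal(ct$sign_hb, c(0, 0))
})

test_that("with d0 = 0 the moderated t reduces to the ordinary pooled t", {
  set.seed(21)
  n_rep <- 4
  vals <- matrix(rnorm(3 * n_rep * 5), 3 * n_rep, 5)
  colnames(vals) <- paste0("A", 1:5)
  vals[9:12, ] <- vals[9:12, ] + 1   # shift the hybrid
  geno <- rep(c("D1", "F1", "D1xF1"), each = n_rep)
  role <- c(D1 = "dent", F1 = "flint", D1xF1 = "hybrid")
  ct <- moderated_contrasts(vals, geno, role, prior = list(d0 = 0))
  # hand-computed ordinary pooled-variance contrast t
  for (j in 1:5) {
    g <- split(vals[, j], geno)
    s2 <- (sum((g$D1 - mean(g$D1))^2) + sum((g$F1 - mean(g$F1))^2) +
           sum((g$D1xF1 - mean(g$D1xF1))^2)) / (3 * n_rep - 3)
    mb <- max(mean(g$D1), mean(g$F1))
    t_hand <- (mean(g$D1xF1) - mb) / sqrt(s2 * (2 / n_rep))
    expect_equal(ct$t_hb[j], t_hand, tolerance = 1e-10)
    expect_equal(ct$p_hb[j], 2 * pt(-abs(t_hand), 3 * n_rep - 3),
                 tolerance = 1e-10)
  }
})

test_that("with d0 = Inf the variance is pinned at the prior", {
  set.seed(22)
  vals <- matrix(rnorm(9 * 6), 9, 6, dimnames = list(NULL, paste0("A", 1:6)))
  geno <- rep(c("D1", "F1", "D1xF1"), each = 3)
  role <- c(D1 = "dent", F1 = "flint", D1xF1 = "hybrid")
  ct <- moderated_contrasts(vals, geno, role, prior = list(d0 = Inf, s02 = 0.7))
  expect_equal(ct$s2_tilde, rep(0.7, 6))
})

test_that("moderated t and p agree with limma on a three-group toy", {
  skip_if_not_installed("limma")
  set.seed(23)
  n_rep <- 4; m <- 40
  # dent always the better parent so that hybrid-b is the hybrid-dent contrast
  vals <- rbind(matrix(rnorm(n_rep * m, 5), n_rep),
                matrix(rnorm(n_rep * m, -5), n_rep),
                matrix(rnorm(n_rep * m, 0), n_rep))
  colnames(vals) <- paste0("A", seq_len(m))
  geno <- rep(c("D1", "F1", "D1xF1"), each = n_rep)
  role <- c(D1 = "dent", F1 = "flint", D1xF1 = "hybrid")
  ct <- moderated_contrasts(vals, geno, role)

  grp <- factor(rep(c("d", "f", "h"), each = n_rep))
  design <- model.matrix(~ 0 + grp)
  fit <- limma::lmFit(t(vals), design)
  cm <- limma::makeContrasts(hb = grph - grpd, hw = grph - grpf,
                             levels = design)
  eb <- limma::eBayes(limma::contrasts.fit(fit, cm))
  expect_equal(attr(ct, "d0"), eb$df.prior, tolerance = 1e-6)
  expect_equal(attr(ct, "s02"), eb$s2.prior, tolerance = 1e-6)
  expect_equal(ct$t_hb, unname(eb$t[, "hb"]), tolerance = 1e-6)
  expect_equal(ct$p_hb, unname(eb$p.value[, "hb"]), tolerance = 1e-6)
  expect_equal(ct$t_hw, unname(eb$t[, "hw"]), tolerance = 1e-6)
  expect_equal(ct$p_hw, unname(eb$p.value[, "hw"]), tolerance = 1e-6)
})

test_that("shrinkage moves observed variances toward the prior", {
  set.seed(24)
  vals <- matrix(rnorm(9 * 200), 9, 200,
                 dimnames = list(NULL, paste0("A", 1:200)))
  geno <- rep(c("D1", "F1", "D1xF1"), each = 3)
  role <- c(D1 = "dent", F1 = "flint", D1xF1 = "hybrid")
  ct <- moderated_contrasts(vals, geno, role)
  s02 <- attr(ct, "s02")
  below <- ct$s2 < s02
  expect_true(all(ct$s2_tilde[below] > ct$s2[below]))
  expect_true(all(ct$s2_tilde[!below] <= ct$s2[!below]))
  expect_true(all(ct$s2_tilde >= pmin(ct$s2, s02) - 1e-12))
  expect_true(all(ct$s2_tilde <= pmax(ct$s2, s02) + 1e-12))
})

test_that("|t| is monotone in the contrast magnitude for fixed variance", {
  vals <- matrix(c(0.9, 1.1, 1.0, 0.1, -0.1, 0.0, 1.9, 2.1, 2.0), 9, 1,
                 dimnames = list(NULL, "A1"))
  geno <- rep(c("D1", "F1", "D1xF1"), each = 3)
  role <- c(D1 = "dent", F1 = "flint", D1xF1 = "hybrid")
  shift <- c(0, 0.5, 1, 2, 4)
  tt <- vapply(shift, function(s) {
    v <- vals; v[7:9, 1] <- v[7:9, 1] + s
    abs(moderated_contrasts(v, geno, role,
                            prior = list(d0 = 0))$t_hb)
  }, numeric(1))
  expect_true(all(diff(tt) > 0))
})
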