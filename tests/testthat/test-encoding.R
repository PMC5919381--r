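test_that("the label mapping matches the hand-built truth table", {
  # all significance-state combinations reachable under the b/w ordering
  truth <- rbind(
    c( 1,  1,  2),   # above both: positive overdominance
    c( 0,  1,  1),   # at b, above w: positive dominance
    c( 1,  0,  1),   # above b only (unequal SEs): positive dominance
    c( 0,  0,  0),   # indistinguishable from both: additivity
    c(-1,  1,  0),   # between the parents, both significant: additivity
    c(-1,  0, -1),   # below b, at w: negative dominance
    c( 0, -1, -1),   # below w only (unequal SEs): negative dominance
    c(-1, -1, -2))   # below both: negative overdominance
  expect_identical(mip_label(truth[, 1], truth[, 2]), as.integer(truth[, 3]))
  # the geometrically unreachable state maps to additivity for totality
  expect_identical(mip_label(1L, -1L), 0L)
})

test_that("encode_mip applies alpha to both contrasts", {
  ct <- data.frame(analyte = c("up", "dom", "mid", "null"),
                   p_hb = c(0.01, 0.50, 0.01, 0.90),
                   sign_hb = c(1, 1, -1, 1),
                   p_hw = c(0.02, 0.01, 0.03, 0.70),
                   sign_hw = c(1, 1, 1, -1))
  expect_identical(encode_mip(ct, alpha = 0.05),
                   c(up = 2L, dom = 1L, mid = 0L, null = 0L))
  # tightening alpha turns everything additive
  expect_identical(unname(encode_mip(ct, alpha = 0.001)), rep(0L, 4))
})

test_that("negating all intensities negates every label", {
  s <- small_panel()
  p <- s$panel
  neg <- profile_matrix(-p$profiles$values, p$profiles$genotype,
                        p$profiles$role)
  a <- s$filter$retained[1:8]
  enc1 <- encode_inheritance(p$design, p$profiles, analytes = a)
  enc2 <- encode_inheritance(p$design, neg, analytes = a)
  expect_identical(unclass(enc1), -unclass(enc2))
})

test_that("labels depend on parental levels, not on Dent/Flint storage roles", {
  set.seed(31)
  pr <- toy_cross_profiles(mean_d = c(3, 1, 2), mean_f = c(1, 3, 2),
                           mean_h = c(4.5, 4.5, 2), n_rep = 4, noise = 0.2)
  role_swap <- c(D1 = "flint", F1 = "dent", D1xF1 = "hybrid")
  ct1 <- moderated_contrasts(pr$values, pr$genotype, pr$role)
  ct2 <- moderated_contrasts(pr$values, pr$genotype, role_swap)
  expect_identical(encode_mip(ct1), encode_mip(ct2))
})

test_that("the class-balance filter follows the stated rules case by case", {
  mk <- function(counts) {
    v <- rep(as.integer(names(counts)), counts)
    matrix(v, ncol = 1, dimnames = list(paste0("h", seq_along(v)), "A1"))
  }
  as_inh <- function(m) structure(m, alpha = 0.05, excluded = list(),
                                  class = c("inheritance_matrix", "matrix",
                                            "array"))
  # {0:14, +1:5, +2:1}: kept; the singleton's hybrid is excluded
  f1 <- class_balance_filter(as_inh(mk(c(`0` = 14, `1` = 5, `2` = 1))))
  expect_identical(colnames(f1), "A1")
  expect_length(attr(f1, "excluded")$A1, 1L)
  expect_identical(attr(f1, "excluded")$A1, "h20")
  expect_true(is.na(f1["h20", "A1"]))
  # {0:14, +1:4, +2:2}: a 2-count class drops the analyte
  f2 <- class_balance_filter(as_inh(mk(c(`0` = 14, `1` = 4, `2` = 2))))
  expect_equal(ncol(f2), 0L)
  # all-additive: fraction 1 > 0.75 drops it
  f3 <- class_balance_filter(as_inh(mk(c(`0` = 20))))
  expect_equal(ncol(f3), 0L)
  # dominant class just over the fraction threshold
  f4 <- class_balance_filter(as_inh(mk(c(`0` = 16, `1` = 4))))
  expect_equal(ncol(f4), 0L)        # 16/20 = 0.8 > 0.75
  f5 <- class_balance_filter(as_inh(mk(c(`0` = 15, `1` = 5))))
  expect_identical(colnames(f5), "A1")  # 15/20 = 0.75, not above
  # two singleton classes are ambiguous: dropped
  f6 <- class_balance_filter(as_inh(mk(c(`0` = 13, `1` = 5, `2` = 1,
                                         `-1` = 1))))
  expect_equal(ncol(f6), 0L)
  # absent classes only offend under strict_absent
  f7 <- class_balance_filter(as_inh(mk(c(`0` = 12, `1` = 8))))
  expect_identical(colnames(f7), "A1")
  f8 <- class_balance_filter(as_inh(mk(c(`0` = 12, `1` = 8))),
                             strict_absent = TRUE)
  expect_equal(ncol(f8), 0L)
})

test_that("relaxing the balance threshold never drops a previously kept analyte", {
  enc <- study_panel()$encoded
  k075 <- colnames(class_balance_filter(enc, 0.75))
  k090 <- colnames(class_balance_filter(enc, 0.90))
  expect_true(all(k075 %in% k090))
  expect_gt(length(k090), length(k075))
})

test_that("the balance filter is independent of analyte order", {
  enc <- study_panel()$encoded
  set.seed(33)
  perm <- sample(ncol(enc))
  encp <- structure(unclass(enc)[, perm], alpha = 0.05, excluded = list(),
                    class = c("inheritance_matrix", "matrix", "array"))
  expect_setequal(colnames(class_balance_filter(enc)),
                  colnames(class_balance_filter(encp)))
})

test_that("non-additive fraction vs performance behaves as constructed", {
  set.seed(34)
  n <- 300
  ids <- paste0("D1xF", seq_len(n))
  labs <- matrix(sample(c(0L, 1L, -1L), n * 20, TRUE, c(0.6, 0.2, 0.2)),
                 n, 20, dimnames = list(ids, paste0("A", 1:20)))
  inh <- structure(labs, alpha = 0.05, excluded = list(),
                   class = c("inheritance_matrix", "matrix", "array"))
  # biomass independent of the labels: no correlation
  ph0 <- phenotype_table(setNames(rnorm(n, 600, 30), ids))
  r0 <- nonadditivity_vs_hp(inh, ph0)
  expect_lt(abs(r0$r[r0$scope == "pooled"]), 0.12)
  expect_gt(r0$p[r0$scope == "pooled"], 0.05)
  # biomass a positive function of the non-additive fraction: sign recovered
  frac <- rowMeans(labs != 0)
  ph1 <- phenotype_table(setNames(600 + 200 * frac + rnorm(n, 0, 5), ids))
  r1 <- nonadditivity_vs_hp(inh, ph1)
  expect_gt(r1$r[r1$scope == "pooled"], 0.5)
  expect_lt(r1$p[r1$scope == "pooled"], 1e-6)
  # constant fraction: undefined, reported as such
  labs2 <- matrix(0L, n, 5, dimnames = list(ids, paste0("B", 1:5)))
  inh2 <- structure(labs2, alpha = 0.05, excluded = list(),
                    class = c("inheritance_matrix", "matrix", "array"))
  r2 <- nonadditivity_vs_hp(inh2, ph0)
  expect_true(is.na(r2$r[r2$scope == "pooled"]))
  expect_match(r2$note[r2$scope == "pooled"], "undefined")
})
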