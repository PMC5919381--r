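# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# The study-condition panel: default generator settings, seed 1, with the
# standard preprocessing/encoding stages attached.
study_panel <- function() {
  cached("study_panel", {
    p <- simulate_panel(sim_config(), seed = 1)
    rf <- redundancy_filter(p$profiles)
    xdf <- build_predictor_matrix(p$design, p$profiles, rf$retained)
    enc <- encode_inheritance(p$design, p$profiles, analytes = rf$retained)
    filt <- class_balance_filter(enc)
    list(panel = p, filter = rf, xdf = xdf, encoded = enc, filtered = filt)
  })
}

study_ranking <- function() {
  cached("study_ranking", {
    s <- study_panel()
    rank_parental_analytes(s$xdf, s$filtered, method = "svmw", seed = 1)
  })
}

# A small panel for cheap end-to-end checks.
small_panel <- function() {
  cached("small_panel", {
    cfg <- sim_config(n_dents = 8, n_flints = 8, cross_fraction = 0.7,
                      n_analytes = 30, n_replicates = 4, n_causal = 3,
                      causal_weights = c(25, 20, 15), n_encoded = 10,
                      n_unphenotyped = 2)
    p <- simulate_panel(cfg, seed = 11)
    rf <- redundancy_filter(p$profiles)
    xdf <- build_predictor_matrix(p$design, p$profiles, rf$retained)
    enc <- encode_inheritance(p$design, p$profiles, analytes = rf$retained)
    filt <- class_balance_filter(enc)
    list(panel = p, filter = rf, xdf = xdf, encoded = enc, filtered = filt)
  })
}

# One-cross toy profiles: replicate values around the supplied genotype
# means (dent, flint, hybrid), n_rep replicates each.
toy_cross_profiles <- function(mean_d, mean_f, mean_h, n_rep = 3,
                               noise = 0, analytes = NULL, seed = 42) {
  set.seed(seed)
  m <- length(mean_d)
  analytes <- analytes %||% sprintf("A%02d", seq_len(m))
  mk <- function(mu) matrix(rep(mu, each = n_rep), n_rep, m) +
    matrix(rnorm(n_rep * m, 0, noise), n_rep, m)
  vals <- rbind(mk(mean_d), mk(mean_f), mk(mean_h))
  colnames(vals) <- analytes
  rownames(vals) <- paste0(rep(c("D1", "F1", "D1xF1"), each = n_rep),
                           "_r", seq_len(n_rep))
  profile_matrix(vals,
                 rep(c("D1", "F1", "D1xF1"), each = n_rep),
                 c(D1 = "dent", F1 = "flint", D1xF1 = "hybrid"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A profile_matrix of parental genotypes whose genotype-mean profiles have
# an exact target correlation matrix (for redundancy-filter oracles).
profiles_with_cor <- function(R, n_geno = 6, seed = 7) {
  set.seed(seed)
  m <- ncol(R)
  x <- matrix(rnorm(n_geno * m), n_geno, m)
  x <- scale(x, scale = FALSE)
  z <- x %*% solve(chol(stats::cov(x)))   # identity sample covariance
  y <- z %*% chol(R)
  colnames(y) <- LETTERS[seq_len(m)]
  genos <- paste0("G", seq_len(n_geno))
  vals <- y[rep(seq_len(n_geno), each = 2), , drop = FALSE]
  rownames(vals) <- paste0(rep(genos, each = 2), "_r", 1:2)
  roles <- setNames(rep(c("dent", "flint"), length.out = n_geno), genos)
  profile_matrix(vals, rep(genos, each = 2), roles)
}
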