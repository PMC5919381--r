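#' Configuration for the synthetic partial-factorial panel generator
#'
#' Defaults emulate the real Dent x Flint study design: 24 Dent and 25
#' Flint lines crossed into a partial factorial (~55% of the full
#' factorial, ~330 hybrids), log10-scale analyte intensities with
#' between-line variation and a low-rank latent-factor correlation
#' structure (so the redundancy filter has work to do), a small set of
#' encodable analytes whose inheritance classes are driven by causal
#' maternal analytes, biomass around 592 dt/ha driven linearly by those
#' same causal maternal analytes, and two field trials with a mean offset.
#'
#' @param n_dents,n_flints numbers of parental lines (default 24, 25).
#' @param cross_fraction fraction of the full factorial realized (0, 1\];
#'   default 0.553 (~332 crosses at the default line numbers).
#' @param n_analytes number of measured analytes (default 60).
#' @param n_replicates biological replicates per genotype (default 6).
#' @param n_causal number of causal maternal (Dent) analytes (default 5);
#'   causal analytes are the first `n_causal` analyte indices.
#' @param causal_weights biomass weights (dt/ha per standardized causal
#'   Dent level) for the causal analytes.
#' @param n_encoded number of analytes whose hybrid inheritance classes are
#'   driven by the causal maternal levels (default 20; they follow the
#'   causal block in the analyte order).
#' @param encoded_propensities length-5 planted class propensities of
#'   encoded analytes over \{-2,...,+2\} (default c(.10,.175,.45,.175,.10)).
#' @param background_propensities propensities for all other analytes
#'   (default c(.01,.04,.90,.04,.01): strongly additive, as in real data).
#' @param delta overdominance shift beyond the parental range, in
#'   log-intensity units (default 1.0).
#' @param noise_sd replicate (technical + biological) noise sd (default 0.5).
#' @param line_sd between-line sd of analyte levels beyond the factor
#'   structure (default 1.0).
#' @param n_factors,factor_sd latent factors shared across analytes within
#'   a line and their loading sd (defaults 3 and 2.5). Loadings apply to
#'   the background analytes only: the causal and encoded blocks stay out
#'   of the factor structure so the planted ground truth remains
#'   identifiable.
#' @param min_parent_gap minimum parental gap required to plant a dominance
#'   class (default 1.0; draws falling on closer parents become additive —
#'   dominance at coinciding parental levels is not a detectable pattern).
#'   Set 0 to disable.
#' @param label_noise probability that an encoded analyte's planted class
#'   is replaced by a random class (default 0.05).
#' @param biomass_base,biomass_sd mean biomass (dt/ha) and residual sd
#'   (defaults 592 and 25).
#' @param trial_offset mean biomass advantage of the second trial (default
#'   50 dt/ha).
#' @param trial_fractions named fractions of crosses per trial
#'   (default c("2010" = 0.45, "2012" = 0.55)).
#' @param n_unphenotyped crosses profiled but never phenotyped (default 4).
#' @param seed master seed stored with the config.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_dents = 24L, n_flints = 25L, cross_fraction = 0.553,
                       n_analytes = 60L, n_replicates = 6L,
                       n_causal = 5L, causal_weights = c(25, 22, 20, 17, 15),
                       n_encoded = 20L,
                       encoded_propensities = c(0.10, 0.175, 0.45, 0.175, 0.10),
                       background_propensities = c(0.01, 0.04, 0.90, 0.04, 0.01),
                       delta = 1.0, noise_sd = 0.5, line_sd = 1.0,
                       n_factors = 3L, factor_sd = 2.5,
                       min_parent_gap = 1.0, label_noise = 0.05,
                       biomass_base = 592, biomass_sd = 25,
                       trial_offset = 50,
                       trial_fractions = c("2010" = 0.45, "2012" = 0.55),
                       n_unphenotyped = 4L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cross_fraction > 0, cross_fraction <= 1,
            noise_sd > 0, line_sd > 0, biomass_sd > 0,
            length(encoded_propensities) == 5L,
            length(background_propensities) == 5L,
            abs(sum(encoded_propensities) - 1) < 1e-8,
            abs(sum(background_propensities) - 1) < 1e-8,
            n_causal >= 0, n_causal + n_encoded <= n_analytes,
            length(causal_weights) == n_causal,
            label_noise >= 0, label_noise <= 1,
            abs(sum(trial_fractions) - 1) < 1e-8)
  n_background <- n_analytes - n_encoded   # causal analytes use background propensities
  od_wanted <- (n_encoded > 0 &&
                  (encoded_propensities[1] > 0 || encoded_propensities[5] > 0)) ||
    (n_background > 0 &&
       (background_propensities[1] > 0 || background_propensities[5] > 0))
  if (delta <= 0 && od_wanted)
    stop("infeasible class: overdominance requested with delta <= 0")
  class(cfg) <- "sim_config"
  cfg
}

draw_classes <- function(n, prop) sample(-2:2, n, replace = TRUE, prob = prop)

#' Simulate a partial-factorial panel with planted ground truth
#'
#' Draws parental line means per analyte (baseline + latent factors +
#' line noise), plants a five-class inheritance label for every
#' hybrid x analyte, places the hybrid mean accordingly (additive =
#' mid-parent; dominance = the level of the dominant parent, planted only
#' where the parental gap is at least `min_parent_gap`; overdominance =
#' `delta` beyond the parental range), adds replicate noise, and generates
#' biomass as a linear function of the standardized causal maternal levels
#' plus a trial offset and noise. Encoded analytes' labels are a
#' quantile-mapped (then noise-flipped) function of the causal maternal
#' levels, so both the classifiers and the ranking have a learnable planted
#' signal.
#'
#' @param config [sim_config()].
#' @param seed overrides `config$seed`.
#' @return list with `design`, `profiles`, `phenotypes` and `truth`
#'   (planted labels matrix, causal column ids and weights, encoded analyte
#'   ids, the config).
#' @export
simulate_panel <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed %||% config$seed))
  m <- config$n_analytes
  analytes <- sprintf("A%03d", seq_len(m))
  causal <- analytes[seq_len(config$n_causal)]
  encoded <- analytes[config$n_causal + seq_len(config$n_encoded)]
  dents <- sprintf("D%02d", seq_len(config$n_dents))
  flints <- sprintf("F%02d", seq_len(config$n_flints))

  full <- expand.grid(dent = dents, flint = flints, stringsAsFactors = FALSE)
  n_cross <- max(1L, round(config$cross_fraction * nrow(full)))
  crosses <- full[sort(sample.int(nrow(full), n_cross)), ]
  cross_id <- paste(crosses$dent, crosses$flint, sep = "x")

  # line means: baseline + latent factors + independent line effect
  lines <- c(dents, flints)
  mu <- stats::rnorm(m, 5, 1)
  lam <- matrix(stats::rnorm(m * config$n_factors, 0, config$factor_sd),
                m, config$n_factors)
  lam[seq_len(config$n_causal + config$n_encoded), ] <- 0
  u <- matrix(stats::rnorm(length(lines) * config$n_factors), length(lines))
  line_mean <- matrix(mu, length(lines), m, byrow = TRUE) +
    u %*% t(lam) +
    matrix(stats::rnorm(length(lines) * m, 0, config$line_sd), length(lines))
  dimnames(line_mean) <- list(lines, analytes)

  # standardized causal Dent levels per cross drive labels and biomass
  z_causal <- NULL
  if (config$n_causal > 0) {
    zc <- line_mean[crosses$dent, causal, drop = FALSE]
    z_causal <- scale(zc)
  }

  # plant labels
  labels <- matrix(0L, n_cross, m, dimnames = list(cross_id, analytes))
  for (j in seq_len(m)) {
    a <- analytes[j]
    if (a %in% encoded && config$n_causal > 0) {
      # unit-magnitude random-sign weights: every causal analyte carries the
      # same planted signal strength, so the ground-truth ranking is well
      # defined for each of them
      beta <- sample(c(-1, 1), config$n_causal, replace = TRUE)
      score <- as.vector(z_causal %*% beta)
      qs <- stats::quantile(score, cumsum(config$encoded_propensities)[1:4])
      lab <- (-2:2)[findInterval(score, qs, left.open = TRUE) + 1L]
      flip <- stats::runif(n_cross) < config$label_noise
      lab[flip] <- draw_classes(sum(flip), config$encoded_propensities)
    } else {
      lab <- draw_classes(n_cross, config$background_propensities)
    }
    if (config$min_parent_gap > 0) {
      gap <- abs(line_mean[crosses$dent, a] - line_mean[crosses$flint, a])
      lab[abs(lab) == 1L & gap < config$min_parent_gap] <- 0L
    }
    labels[, j] <- lab
  }

  # hybrid means per planted label
  pd <- line_mean[crosses$dent, , drop = FALSE]
  pf <- line_mean[crosses$flint, , drop = FALSE]
  hi <- pmax(pd, pf); lo <- pmin(pd, pf)
  hyb_mean <- (pd + pf) / 2
  hyb_mean[labels ==  1L] <- hi[labels ==  1L]
  hyb_mean[labels == -1L] <- lo[labels == -1L]
  hyb_mean[labels ==  2L] <- hi[labels ==  2L] + config$delta
  hyb_mean[labels == -2L] <- lo[labels == -2L] - config$delta

  # replicate rows
  nr <- config$n_replicates
  rep_block <- function(means, ids) {
    v <- means[rep(seq_len(nrow(means)), each = nr), , drop = FALSE] +
      matrix(stats::rnorm(nrow(means) * nr * m, 0, config$noise_sd),
             nrow(means) * nr, m)
    rownames(v) <- paste(rep(ids, each = nr), seq_len(nr), sep = "_r")
    v
  }
  vals <- rbind(rep_block(line_mean, lines), rep_block(hyb_mean, cross_id))
  genotype <- c(rep(lines, each = nr), rep(cross_id, each = nr))
  role <- setNames(c(rep("dent", length(dents)), rep("flint", length(flints)),
                     rep("hybrid", n_cross)), c(dents, flints, cross_id))
  profiles <- profile_matrix(vals, genotype, role)

  # trials and biomass
  k1 <- round(config$trial_fractions[1] * n_cross)
  trial <- setNames(sample(rep(names(config$trial_fractions),
                               times = c(k1, n_cross - k1))),
                    cross_id)
  signal <- if (config$n_causal > 0)
    as.vector(z_causal %*% config$causal_weights) else 0
  second <- names(config$trial_fractions)[2]
  biomass <- config$biomass_base + signal +
    config$trial_offset * (trial == second) +
    stats::rnorm(n_cross, 0, config$biomass_sd)
  biomass <- pmax(biomass, 1)
  phen_ids <- cross_id
  if (config$n_unphenotyped > 0 && config$n_unphenotyped < n_cross)
    phen_ids <- setdiff(cross_id, sample(cross_id, config$n_unphenotyped))
  pheno <- phenotype_table(setNames(biomass, cross_id)[phen_ids],
                           trial[phen_ids])

  design <- mating_design(dents, flints, crosses, trial, sep = "x")
  design$crosses$phenotyped <- design$crosses$cross_id %in% phen_ids
  list(design = design, profiles = profiles, phenotypes = pheno,
       truth = list(labels = labels,
                    causal_columns = if (config$n_causal) paste0(causal, "_D")
                                     else character(0),
                    causal_weights = config$causal_weights,
                    encoded_analytes = encoded,
                    config = config))
}

#' Score pipeline outputs against the generator's ground truth
#'
#' Computes (where the corresponding pipeline output is supplied) the
#' per-class recovery of the planted inheritance labels by the encoder,
#' the fraction of planted causal maternal columns among the top-k ranked
#' parental columns, and the planted-signal ordering of the scenario
#' R-squared medians (Top5 > Random5 > Bottom5, permuted near zero).
#'
#' @param truth `truth` element from [simulate_panel()].
#' @param encoded optional `inheritance_matrix` from [encode_inheritance()].
#' @param ranking optional [rank_parental_analytes()] output.
#' @param hp_eval optional [predict_hp_regression()] output.
#' @param top_k ranking window for causal recovery (default 10).
#' @param thresholds named list of pass thresholds:
#'   `label_accuracy` (default 0.8, per non-additive class),
#'   `causal_fraction` (default 0.8), `perm_r2` (default 0.05).
#' @return list with elements `label_recovery` (per-class data.frame),
#'   `causal_top_k`, `r2_medians`, and logical `pass` flags.
#' @export
recovery_report <- function(truth, encoded = NULL, ranking = NULL,
                            hp_eval = NULL, top_k = 10L,
                            thresholds = list()) {
  th <- modifyList(list(label_accuracy = 0.8, causal_fraction = 0.8,
                        perm_r2 = 0.05), thresholds)
  out <- list(pass = list())
  if (!is.null(encoded)) {
    common_a <- intersect(colnames(encoded), colnames(truth$labels))
    common_h <- intersect(rownames(encoded), rownames(truth$labels))
    tl <- truth$labels[common_h, common_a, drop = FALSE]
    el <- encoded[common_h, common_a, drop = FALSE]
    per_class <- do.call(rbind, lapply(-2:2, function(cl) {
      idx <- which(tl == cl & !is.na(el))
      data.frame(class = cl, n = length(idx),
                 accuracy = if (length(idx)) mean(el[idx] == cl) else NA_real_)
    }))
    out$label_recovery <- per_class
    na_cls <- per_class[abs(per_class$class) > 0 & per_class$n > 0, ]
    out$pass$labels <- all(na_cls$accuracy >= th$label_accuracy)
  }
  if (!is.null(ranking) && length(truth$causal_columns)) {
    topk <- ranking$column[ranking$rank <= top_k]
    frac <- mean(truth$causal_columns %in% topk)
    out$causal_top_k <- frac
    out$pass$causal <- frac >= th$causal_fraction
  }
  if (!is.null(hp_eval)) {
    med <- vapply(split(hp_eval$r2, hp_eval$scenario), stats::median,
                  numeric(1))
    out$r2_medians <- med
    ord_ok <- all(c("Top5", "Random5", "Bottom5") %in% names(med)) &&
      med["Top5"] > med["Random5"] && med["Random5"] > med["Bottom5"]
    out$pass$r2_ordering <- ord_ok
    if ("All-perm" %in% names(med))
      out$pass$perm_null <- med[["All-perm"]] < th$perm_r2
  }
  out
}
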