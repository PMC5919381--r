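#' Five-class inheritance label from the two contrast significance states
#'
#' Maps the significance state of the hybrid vs better parent (b) and
#' hybrid vs worse parent (w) contrasts onto the metabolic inheritance
#' pattern label. A state is +1 (significantly above), 0 (indistinguishable
#' at the chosen level) or -1 (significantly below). The mapping is total:
#'
#' * above b, above w -> +2 (positive overdominance)
#' * above exactly one parent -> +1 (positive dominance)
#' * indistinguishable from both, or below b and above w -> 0 (additivity)
#' * below exactly one parent -> -1 (negative dominance)
#' * below b, below w -> -2 (negative overdominance)
#'
#' The state (above b, below w) cannot arise because the hybrid - b
#' estimate never exceeds the hybrid - w estimate; it maps to 0.
#'
#' @param state_b,state_w integer vectors in \{-1, 0, 1\}.
#' @return integer labels in \{-2, -1, 0, 1, 2\}.
#' @export
mip_label <- function(state_b, state_w) {
  stopifnot(all(state_b %in% -1:1), all(state_w %in% -1:1),
            length(state_b) == length(state_w))
  lab <- integer(length(state_b))
  lab[state_b ==  1 & state_w ==  1] <-  2L
  lab[xor(state_b == 1, state_w == 1) & state_b != -1 & state_w != -1] <- 1L
  lab[xor(state_b == -1, state_w == -1) & state_b != 1 & state_w != 1] <- -1L
  lab[state_b == -1 & state_w == -1] <- -2L
  # (0,0), (-1,+1) and the unreachable (+1,-1) stay 0
  lab
}

#' Encode the metabolic inheritance pattern of one cross
#'
#' Translates a [moderated_contrasts()] result into per-analyte mIP labels:
#' "equal" in the inheritance conditionals means "contrast not significant
#' at `alpha`" (two-sided, unadjusted).
#'
#' @param contrast [moderated_contrasts()] result.
#' @param alpha two-sided significance level (default 0.05).
#' @return named integer vector of labels in \{-2, ..., 2\}, one per analyte.
#' @export
encode_mip <- function(contrast, alpha = 0.05) {
  state <- function(p, s) ifelse(p < alpha & s != 0, s, 0L)
  lab <- mip_label(state(contrast$p_hb, contrast$sign_hb),
                   state(contrast$p_hw, contrast$sign_hw))
  setNames(lab, contrast$analyte)
}

#' Encode the inheritance matrix for a whole panel
#'
#' Runs [moderated_contrasts()] + [encode_mip()] for every cross of the
#' design and assembles the |H| x m label matrix T.
#'
#' @param design [mating_design()].
#' @param profiles [profile_matrix()].
#' @param analytes analyte ids to encode (default: all columns).
#' @param alpha two-sided significance level for the contrasts.
#' @param prior `"subset"` (default) estimates the variance prior per cross
#'   subset across that subset's analytes; `"panel"` estimates one prior
#'   from all crosses' residual variances first.
#' @return object of class `inheritance_matrix`: integer matrix (rows =
#'   cross ids in design order, columns = analytes) with attributes `alpha`
#'   and `excluded` (named list analyte -> excluded cross ids; filled by
#'   [class_balance_filter()], excluded cells are `NA`).
#' @export
encode_inheritance <- function(design, profiles, analytes = NULL,
                               alpha = 0.05, prior = c("subset", "panel")) {
  prior <- match.arg(prior)
  analytes <- analytes %||% colnames(profiles$values)
  cr <- design$crosses
  vals <- profiles$values[, analytes, drop = FALSE]
  geno <- profiles$genotype
  rows_of <- split(seq_along(geno), geno)
  miss <- cr$cross_id[!(cr$cross_id %in% names(rows_of))]
  if (length(miss)) stop("no replicate profiles for cross(es): ",
                         paste(miss, collapse = ", "))

  subset_of <- function(i) {
    rows <- c(rows_of[[cr$dent[i]]], rows_of[[cr$flint[i]]],
              rows_of[[cr$cross_id[i]]])
    list(values = vals[rows, , drop = FALSE], genotype = geno[rows],
         role = setNames(c("dent", "flint", "hybrid"),
                         c(cr$dent[i], cr$flint[i], cr$cross_id[i])))
  }

  panel_prior <- NULL
  if (prior == "panel") {
    s2 <- unlist(lapply(seq_len(nrow(cr)), function(i) {
      s <- subset_of(i)
      moderated_contrasts(s$values, s$genotype, s$role,
                          prior = list(d0 = 0, s02 = NA))$s2
    }))
    dfs <- vapply(seq_len(nrow(cr)), function(i) {
      rows <- c(rows_of[[cr$dent[i]]], rows_of[[cr$flint[i]]],
                rows_of[[cr$cross_id[i]]])
      length(rows) - 3L
    }, integer(1))
    panel_prior <- estimate_variance_prior(s2, rep(dfs, each = ncol(vals)))
  }

  labels <- matrix(NA_integer_, nrow(cr), ncol(vals),
                   dimnames = list(cr$cross_id, colnames(vals)))
  for (i in seq_len(nrow(cr))) {
    s <- subset_of(i)
    ct <- moderated_contrasts(s$values, s$genotype, s$role, prior = panel_prior)
    labels[i, ] <- encode_mip(ct, alpha = alpha)
  }
  structure(labels, alpha = alpha, excluded = list(),
            class = c("inheritance_matrix", class(labels)))
}

#' Class-balance filter for encoded analytes
#'
#' Drops encoded analytes whose realized class distribution is too
#' unbalanced for classification: (i) any class covering more than
#' `max_class_fraction` of the hybrids, or (ii) any realized class with
#' fewer than `min_class_count` occurrences — unless the only offending
#' class is a single class with a single occurrence, in which case the
#' analyte is kept and that one hybrid is excluded for that analyte only.
#' Several singleton classes (or a singleton alongside a 2-3-count class)
#' drop the analyte. Absent classes never trigger removal unless
#' `strict_absent = TRUE`.
#'
#' @param labels `inheritance_matrix` from [encode_inheritance()].
#' @param max_class_fraction default 0.75.
#' @param min_class_count default 4.
#' @param strict_absent treat classes with zero occurrences as offending
#'   (sensitivity analysis; default `FALSE`).
#' @return `inheritance_matrix` restricted to the retained analytes, with
#'   excluded cells set `NA`; attributes `excluded` (analyte -> cross ids)
#'   and `filter_log` (per-analyte decision data.frame).
#' @export
class_balance_filter <- function(labels, max_class_fraction = 0.75,
                                 min_class_count = 4, strict_absent = FALSE) {
  stopifnot(ncol(labels) >= 1L)
  n <- nrow(labels)
  decide <- function(v) {
    cnt <- table(factor(v[!is.na(v)], levels = -2:2))
    realized <- cnt[cnt > 0]
    if (any(cnt / n > max_class_fraction))
      return(list(keep = FALSE, why = "class fraction above maximum", excl = NULL))
    low <- if (strict_absent) cnt[cnt < min_class_count]
           else realized[realized < min_class_count]
    if (!length(low))
      return(list(keep = TRUE, why = "balanced", excl = NULL))
    if (length(low) == 1L && low == 1L) {
      cls <- as.integer(names(low))
      return(list(keep = TRUE, why = "singleton class; hybrid excluded",
                  excl = rownames(labels)[which(v == cls)]))
    }
    list(keep = FALSE,
         why = if (sum(low == 1L) > 1L) "multiple singleton classes (ambiguous)"
               else "class below minimum count", excl = NULL)
  }
  dec <- lapply(seq_len(ncol(labels)), function(j) decide(labels[, j]))
  keep <- vapply(dec, `[[`, TRUE, "keep")
  out <- labels[, keep, drop = FALSE]
  excluded <- list()
  for (j in which(keep)) {
    ex <- dec[[j]]$excl
    if (!is.null(ex) && length(ex)) {
      a <- colnames(labels)[j]
      excluded[[a]] <- ex
      out[ex, a] <- NA_integer_
    }
  }
  structure(out, alpha = attr(labels, "alpha"), excluded = excluded,
            filter_log = data.frame(
              analyte = colnames(labels), kept = keep,
              reason = vapply(dec, `[[`, "", "why"),
              stringsAsFactors = FALSE),
            class = c("inheritance_matrix", "matrix", "array"))
}

#' Correlation between non-additive inheritance fraction and performance
#'
#' For every phenotyped hybrid, the fraction of retained analytes with a
#' non-additive label (label != 0, excluded cells skipped) is correlated
#' (Pearson) with field biomass, per trial and pooled.
#'
#' @param labels (filtered) `inheritance_matrix`.
#' @param pheno [phenotype_table()].
#' @return data.frame with one row per scope (`pooled` plus each trial):
#'   n, r, p; r and p are `NA` with a note when the fraction is constant.
#' @export
nonadditivity_vs_hp <- function(labels, pheno) {
  common <- intersect(rownames(labels), pheno$cross_id)
  if (length(common) < 3L) stop("need at least 3 phenotyped hybrids")
  frac <- rowMeans(labels[common, , drop = FALSE] != 0, na.rm = TRUE)
  bm <- setNames(pheno$biomass, pheno$cross_id)[common]
  tr <- setNames(pheno$trial, pheno$cross_id)[common]
  one <- function(scope, idx) {
    if (length(idx) < 3L)
      return(data.frame(scope = scope, n = length(idx), r = NA, p = NA,
                        note = "too few hybrids"))
    if (stats::sd(frac[idx]) == 0 || stats::sd(bm[idx]) == 0)
      return(data.frame(scope = scope, n = length(idx), r = NA, p = NA,
                        note = "undefined: constant values"))
    ct <- stats::cor.test(frac[idx], bm[idx])
    data.frame(scope = scope, n = length(idx), r = unname(ct$estimate),
               p = ct$p.value, note = "")
  }
  res <- one("pooled", seq_along(common))
  for (lab in sort(unique(tr[!is.na(tr)])))
    res <- rbind(res, one(lab, which(tr == lab)))
  res
}
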