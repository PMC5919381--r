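#' Mating design of a partial factorial Dent x Flint panel
#'
#' @param dents character vector of Dent (maternal) line identifiers.
#' @param flints character vector of Flint (paternal) line identifiers.
#' @param crosses data.frame with columns `dent` and `flint`, one row per
#'   realized hybrid. The realized set may be any subset of the full
#'   factorial.
#' @param trial optional named character vector mapping cross ids to a field
#'   trial label (e.g. `"2010"` / `"2012"`).
#' @param sep separator used to canonicalize cross ids as
#'   `"<dent><sep><flint>"`.
#' @return object of class `mating_design` with elements `dents`, `flints`,
#'   `crosses` (data.frame `dent`, `flint`, `cross_id`), `trial`, `sep`.
#' @export
mating_design <- function(dents, flints, crosses, trial = NULL, sep = "x") {
  dents <- as.character(dents); flints <- as.character(flints)
  stopifnot(is.data.frame(crosses), all(c("dent", "flint") %in% names(crosses)))
  if (anyDuplicated(dents) || anyDuplicated(flints))
    stop("duplicated parental line identifiers")
  bad_d <- setdiff(crosses$dent, dents)
  if (length(bad_d)) stop("cross references unknown Dent line(s): ",
                          paste(bad_d, collapse = ", "))
  bad_f <- setdiff(crosses$flint, flints)
  if (length(bad_f)) stop("cross references unknown Flint line(s): ",
                          paste(bad_f, collapse = ", "))
  cross_id <- paste(crosses$dent, crosses$flint, sep = sep)
  if (anyDuplicated(cross_id))
    stop("duplicated crosses: ", paste(unique(cross_id[duplicated(cross_id)]),
                                       collapse = ", "))
  if (!is.null(trial)) {
    trial <- trial[names(trial) %in% cross_id]
  }
  structure(list(dents = dents, flints = flints,
                 crosses = data.frame(dent = as.character(crosses$dent),
                                      flint = as.character(crosses$flint),
                                      cross_id = cross_id,
                                      stringsAsFactors = FALSE),
                 trial = trial, sep = sep),
            class = "mating_design")
}

#' @method print mating_design
#' @export
print.mating_design <- function(x, ...) {
  cat("Mating design:", length(x$dents), "Dent x", length(x$flints),
      "Flint lines,", nrow(x$crosses), "realized crosses\n")
  if (!is.null(x$trial)) {
    tb <- table(x$trial)
    cat("Trials:", paste(sprintf("%s (n=%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Replicate-level analyte intensity matrix
#'
#' Container for the replicate x analyte matrix of log-transformed
#' intensities with genotype and role annotation.
#'
#' @param values numeric matrix, rows = biological replicates, columns =
#'   analytes (column names are the analyte ids). No missing values are
#'   allowed: missingness must be resolved upstream.
#' @param genotype character vector (length `nrow(values)`) giving the
#'   genotype of each replicate row.
#' @param role named character vector mapping each genotype to one of
#'   `"dent"`, `"flint"`, `"hybrid"`.
#' @return object of class `profile_matrix`.
#' @export
profile_matrix <- function(values, genotype, role) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  genotype <- as.character(genotype)
  stopifnot(length(genotype) == nrow(values))
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("analyte ids (column names) must be present and unique")
  if (anyNA(values)) stop("missing intensities are not allowed")
  role <- setNames(as.character(role), names(role))
  miss <- setdiff(unique(genotype), names(role))
  if (length(miss)) stop("no role for genotype(s): ", paste(miss, collapse = ", "))
  if (!all(role %in% c("dent", "flint", "hybrid")))
    stop("roles must be 'dent', 'flint' or 'hybrid'")
  reps <- table(genotype)
  few <- names(reps)[reps < 2L]
  if (length(few))
    stop("genotype(s) with fewer than 2 replicates: ", paste(few, collapse = ", "))
  structure(list(values = values, genotype = genotype, role = role),
            class = "profile_matrix")
}

#' @method print profile_matrix
#' @export
print.profile_matrix <- function(x, ...) {
  tb <- table(x$role[unique(x$genotype)])
  cat("Profile matrix:", nrow(x$values), "replicates x", ncol(x$values),
      "analytes;", paste(sprintf("%d %s", tb, names(tb)), collapse = ", "),
      "genotypes\n")
  invisible(x)
}

# Genotype-mean profiles (genotype x analyte).
genotype_means <- function(profiles) {
  g <- factor(profiles$genotype, levels = unique(profiles$genotype))
  out <- rowsum(profiles$values, g) / as.vector(table(g))
  rownames(out) <- levels(g)
  out
}

#' Hybrid phenotype (field performance) table
#'
#' @param biomass named numeric vector of whole-plant biomass (dt/ha), one
#'   entry per phenotyped cross id. Values must be strictly positive.
#' @param trial named character vector of field-trial labels for the same
#'   crosses.
#' @param design optional [mating_design()]; when supplied, every phenotyped
#'   cross must exist in the design.
#' @return object of class `phenotype_table`: data.frame `cross_id`,
#'   `biomass`, `trial`.
#' @export
phenotype_table <- function(biomass, trial = NULL, design = NULL) {
  stopifnot(!is.null(names(biomass)))
  if (any(!is.finite(biomass)) || any(biomass <= 0))
    stop("biomass values must be strictly positive and finite")
  if (!is.null(design)) {
    bad <- setdiff(names(biomass), design$crosses$cross_id)
    if (length(bad)) stop("phenotyped cross(es) not in design: ",
                          paste(bad, collapse = ", "))
  }
  tr <- if (is.null(trial)) rep(NA_character_, length(biomass))
        else as.character(trial[names(biomass)])
  structure(data.frame(cross_id = names(biomass), biomass = unname(biomass),
                       trial = tr, stringsAsFactors = FALSE),
            class = c("phenotype_table", "data.frame"))
}

read_table_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading spreadsheets requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path))
  } else {
    sep <- if (ext == "tsv") "\t" else ","
    utils::read.csv(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
}

#' Load a panel (profiles + phenotypes) from tabular files
#'
#' The profile table must have columns `replicate`, `genotype`, `role`
#' followed by one numeric column per analyte; the phenotype table must have
#' columns `cross_id`, `biomass`, `trial`. CSV (default), TSV and XLSX are
#' accepted. Hybrid genotype ids are parsed into their parents with the
#' cross separator; every hybrid's parents must carry profiles.
#'
#' @param profile_path path to the replicate-level profile table.
#' @param phenotype_path path to the hybrid phenotype table (optional:
#'   `NULL` loads an unphenotyped panel).
#' @param sep cross-id separator (see [mating_design()]).
#' @return list with elements `design` ([mating_design()]), `profiles`
#'   ([profile_matrix()]), `phenotypes` ([phenotype_table()] or `NULL`).
#'   Hybrids lacking a phenotype are kept in the design and flagged in
#'   `design$crosses$phenotyped`.
#' @export
load_panel <- function(profile_path, phenotype_path = NULL, sep = "x") {
  stopifnot(file.exists(profile_path))
  tab <- read_table_any(profile_path)
  need <- c("replicate", "genotype", "role")
  if (!all(need %in% names(tab)))
    stop("profile table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$replicate))
    stop("duplicated replicate id(s): ",
         paste(unique(tab$replicate[duplicated(tab$replicate)]), collapse = ", "))
  acols <- setdiff(names(tab), need)
  if (!length(acols)) stop("profile table has no analyte columns")
  vals <- as.matrix(tab[, acols, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing intensity at row %d, column '%s'",
                 bad[1], acols[bad[2]]))
  }
  rownames(vals) <- tab$replicate
  role <- tapply(tab$role, tab$genotype, function(r) unique(r)[1])
  profiles <- profile_matrix(vals, tab$genotype, role)

  geno <- unique(tab$genotype)
  dents  <- geno[role[geno] == "dent"]
  flints <- geno[role[geno] == "flint"]
  hybs   <- geno[role[geno] == "hybrid"]
  parts <- strsplit(hybs, sep, fixed = TRUE)
  bad <- hybs[lengths(parts) != 2L]
  if (length(bad))
    stop("hybrid id(s) not parseable as <dent>", sep, "<flint>: ",
         paste(bad, collapse = ", "))
  pd <- vapply(parts, `[`, "", 1L); pf <- vapply(parts, `[`, "", 2L)
  miss <- c(setdiff(pd, dents), setdiff(pf, flints))
  if (length(miss))
    stop("hybrid parent(s) lack profiles: ", paste(unique(miss), collapse = ", "))

  pheno <- NULL; trial <- NULL
  if (!is.null(phenotype_path)) {
    stopifnot(file.exists(phenotype_path))
    ptab <- read_table_any(phenotype_path)
    if (!all(c("cross_id", "biomass") %in% names(ptab)))
      stop("phenotype table must have columns cross_id, biomass")
    bm <- setNames(as.numeric(ptab$biomass), ptab$cross_id)
    tr <- if ("trial" %in% names(ptab))
      setNames(as.character(ptab$trial), ptab$cross_id) else NULL
    unknown <- setdiff(names(bm), hybs)
    if (length(unknown))
      stop("phenotyped cross(es) without profiles: ",
           paste(unknown, collapse = ", "))
    pheno <- phenotype_table(bm, tr)
    trial <- tr
  }
  design <- mating_design(dents, flints,
                          data.frame(dent = pd, flint = pf), trial, sep)
  design$crosses$phenotyped <-
    if (is.null(pheno)) FALSE else design$crosses$cross_id %in% pheno$cross_id
  list(design = design, profiles = profiles, phenotypes = pheno)
}

#' Write a panel back to CSV files
#'
#' Inverse of [load_panel()]: writes `profiles.csv` (and `phenotypes.csv`
#' when phenotypes are present) into `dir` in the dialect [load_panel()]
#' reads, so that a written panel round-trips.
#'
#' @param panel list as returned by [load_panel()] or [simulate_panel()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- panel$profiles
  tab <- data.frame(replicate = rownames(pr$values) %||%
                      paste0("r", seq_len(nrow(pr$values))),
                    genotype = pr$genotype,
                    role = unname(pr$role[pr$genotype]),
                    pr$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  ppath <- file.path(dir, "profiles.csv")
  utils::write.csv(tab, ppath, row.names = FALSE)
  paths <- ppath
  if (!is.null(panel$phenotypes)) {
    fpath <- file.path(dir, "phenotypes.csv")
    utils::write.csv(as.data.frame(panel$phenotypes), fpath, row.names = FALSE)
    paths <- c(paths, fpath)
  }
  invisible(paths)
}

#' Compare hybrid performance between the two field trials
#'
#' Two-sample t-test of biomass between the two trial labels (pooled
#' variance by default, Welch optionally).
#'
#' @param pheno [phenotype_table()] with exactly two trial labels, each with
#'   at least two hybrids.
#' @param var_equal pooled-variance t-test (`TRUE`, default) or Welch.
#' @return list with `groups` (per-trial n and mean), `t`, `df`, `p`,
#'   `method`.
#' @export
compare_trials <- function(pheno, var_equal = TRUE) {
  tr <- pheno$trial
  if (all(is.na(tr))) stop("nothing to compare: no trial labels")
  labs <- sort(unique(tr[!is.na(tr)]))
  if (length(labs) < 2L) stop("nothing to compare: single trial")
  if (length(labs) > 2L)
    stop("more than two trial labels; subset the table to one pair")
  a <- pheno$biomass[tr == labs[1]]; b <- pheno$biomass[tr == labs[2]]
  if (length(a) < 2L || length(b) < 2L)
    stop("each trial needs at least 2 hybrids")
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(groups = data.frame(trial = labs, n = c(length(a), length(b)),
                           mean = c(mean(a), mean(b))),
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       method = if (var_equal) "pooled two-sample t" else "Welch t")
}
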