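#' Default pipeline configuration
#'
#' All tunable parameters of the framework in one structured list; every
#' value defaults to the framework's standard setting (redundancy r
#' threshold 0.85, contrast alpha 0.05, class-balance thresholds 0.75 and
#' 4, class weights \{10,5,1,5,10\}, 5 classification and 25
#' hybrid-performance repetitions, 75/25 and 80/20 partitions, 3-fold inner
#' cross-validation with 5 and 10 repetitions).
#'
#' @param ... overrides of any default element.
#' @return named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    r_threshold = 0.85,
    alpha = 0.05,
    max_class_fraction = 0.75,
    min_class_count = 4,
    weights = c(10, 5, 1, 5, 10),
    methods = mip_methods(),
    mip_repetitions = 5L,
    mip_train_fraction = 0.75,
    mip_cv_folds = 3L, mip_cv_reps = 5L,
    rank_method = NULL,          # NULL: pick by minimal kappa CV
    rank_cv_reps = 10L,
    hp_scenarios = hp_scenarios()$id,
    hp_repetitions = 25L,
    hp_train_fraction = 0.8,
    hp_cv_folds = 3L, hp_cv_reps = 10L,
    hp_threshold = "mean",
    seed = 1L,
    simulate = NULL,             # sim_config() arguments, or NULL
    profiles = NULL, phenotypes = NULL   # input paths when not simulating
  )
  utils::modifyList(cfg, list(...))
}

write_stage <- function(obj, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(obj), path, row.names = FALSE)
  path
}

#' Run the full two-step pipeline
#'
#' Executes load (or simulate) -> redundancy filter -> predictor matrix ->
#' inheritance encoding + balance filter -> classifier evaluation + model
#' selection -> parental-analyte ranking -> hybrid-performance prediction,
#' writing each stage's tables as CSV plus a JSON run manifest (parameters,
#' seed, stage file checksums) into `out_dir`.
#'
#' @param config list from [default_config()], or a path to a YAML file of
#'   overrides.
#' @param out_dir output directory.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- do.call(default_config, yaml::read_yaml(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stages <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stages <<- c(stages, name)
    res
  }

  panel <- stage("load", {
    if (!is.null(config$simulate)) {
      sim <- do.call(sim_config, config$simulate)
      simulate_panel(sim, seed = config$seed)
    } else {
      if (is.null(config$profiles)) stop("no input: set profiles or simulate")
      load_panel(config$profiles, config$phenotypes)
    }
  })
  files <- c(files, write_panel(panel, out_dir))

  prep <- stage("preprocess", {
    rf <- redundancy_filter(panel$profiles, config$r_threshold)
    xdf <- build_predictor_matrix(panel$design, panel$profiles, rf$retained)
    list(filter = rf, xdf = xdf)
  })
  files <- c(files,
             write_stage(prep$filter$log, out_dir, "redundancy_log"),
             write_stage(data.frame(analyte = prep$filter$retained),
                         out_dir, "retained_analytes"),
             write_stage(cbind(cross_id = rownames(prep$xdf),
                               as.data.frame(unclass(prep$xdf))),
                         out_dir, "predictor_matrix"))

  enc <- stage("encode", {
    lab <- encode_inheritance(panel$design, panel$profiles,
                              analytes = prep$filter$retained,
                              alpha = config$alpha)
    filt <- class_balance_filter(lab, config$max_class_fraction,
                                 config$min_class_count)
    list(labels = lab, filtered = filt)
  })
  files <- c(files,
             write_stage(cbind(cross_id = rownames(enc$filtered),
                               as.data.frame(unclass(enc$filtered))),
                         out_dir, "inheritance_labels"),
             write_stage(attr(enc$filtered, "filter_log"), out_dir,
                         "balance_filter_log"))

  evals <- stage("classify",
    evaluate_classifiers(prep$xdf, enc$filtered, methods = config$methods,
                         repetitions = config$mip_repetitions,
                         train_fraction = config$mip_train_fraction,
                         cv_folds = config$mip_cv_folds,
                         cv_reps = config$mip_cv_reps,
                         seed = config$seed, grids = config$grids))
  files <- c(files, write_stage(evals, out_dir, "classifier_kappa"))

  sel <- stage("select", select_ranking_model(evals))
  files <- c(files, write_stage(sel$table, out_dir, "classifier_cv"))

  ranking <- stage("rank",
    rank_parental_analytes(prep$xdf, enc$filtered,
                           method = config$rank_method %||% sel$method,
                           cv_reps = config$rank_cv_reps,
                           seed = config$seed))
  files <- c(files, write_stage(ranking, out_dir, "analyte_ranking"))

  hp <- stage("predict", {
    if (is.null(panel$phenotypes)) NULL else {
      scn <- hp_scenarios(config$hp_scenarios)
      reg <- predict_hp_regression(prep$xdf, panel$phenotypes, ranking,
                                   scenarios = scn,
                                   repetitions = config$hp_repetitions,
                                   train_fraction = config$hp_train_fraction,
                                   cv_folds = config$hp_cv_folds,
                                   cv_reps = config$hp_cv_reps,
                                   seed = config$seed)
      cls <- predict_hp_classification(prep$xdf, panel$phenotypes, ranking,
                                       scenarios = scn,
                                       threshold = config$hp_threshold,
                                       repetitions = config$hp_repetitions,
                                       train_fraction = config$hp_train_fraction,
                                       cv_folds = config$hp_cv_folds,
                                       cv_reps = config$hp_cv_reps,
                                       seed = config$seed)
      list(regression = reg, classification = cls)
    }
  })
  if (!is.null(hp)) {
    files <- c(files,
               write_stage(hp$regression, out_dir, "hp_regression"),
               write_stage(hp$classification, out_dir, "hp_classification"))
  }

  manifest <- list(
    package = "hybripred",
    version = as.character(utils::packageVersion("hybripred")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("profiles", "phenotypes"))],
    stages = stages,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(panel = panel, preprocess = prep, encode = enc,
                 evals = evals, selection = sel, ranking = ranking,
                 hp = hp, manifest = manifest))
}
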