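#' Pipeline configuration
#'
#' Flat configuration for [run_pipeline()].  Inputs are either HDF5 files
#' (`input`) or a simulation request (`simulate = TRUE` with cohort
#' settings).  All analysis thresholds default to the package conventions
#' (see [mea_config()]).
#'
#' @param input Character vector of HDF5 recording paths (ignored when
#'   `simulate`).
#' @param simulate Generate a synthetic cohort instead of reading files.
#' @param sim_ages Ages (DIV) to simulate.
#' @param sim_n_per_group Recordings per region per age.
#' @param sim_n_electrodes,sim_duration Array geometry and length for
#'   simulation.
#' @param config An [mea_config].
#' @param ml_method `"forest"` or `"svm"`.
#' @param ml_repeats Random splits per age for classification.
#' @param ntree Trees per forest.
#' @param stats_family FDR family rule, see [comparison_table()].
#' @param seed Master seed (required when simulating or classifying).
#' @param out_dir Output directory (created if absent).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = character(), simulate = FALSE,
                            sim_ages = c(7, 14, 21), sim_n_per_group = 10,
                            sim_n_electrodes = 59, sim_duration = 900,
                            config = mea_config(), ml_method = "forest",
                            ml_repeats = 500, ntree = 500,
                            stats_family = "pooled", seed = 1,
                            out_dir = "meadev-out") {
  if (!simulate && !length(input))
    stop("config needs input files or simulate = TRUE")
  if (!simulate) {
    missing <- input[!file.exists(input)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(list(input = input, simulate = simulate, sim_ages = sim_ages,
                 sim_n_per_group = sim_n_per_group,
                 sim_n_electrodes = sim_n_electrodes,
                 sim_duration = sim_duration, config = config,
                 ml_method = ml_method, ml_repeats = ml_repeats,
                 ntree = ntree, stats_family = stats_family,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Reads (or simulates) recordings, extracts the 11-feature table, runs the
#' per-age group comparison, per-age PCA, and per-age classification, and
#' writes everything plus a reproducibility manifest under
#' `config$out_dir`: `features.csv`, `comparison.csv`, `pca_div<k>.csv`,
#' `classification.json`, `incremental_div<k>.csv`, `manifest.json`.
#' Stages run in order; if one fails, earlier outputs are kept and the
#' manifest records the failure point.
#'
#' @param cfg A [pipeline_config].
#' @return Invisibly, a list with the in-memory results (`features`,
#'   `comparison`, `pca`, `classification`, `incremental`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("meadev")),
                   r_version = R.version.string, seed = cfg$seed,
                   started = format(Sys.time(), tz = "UTC"),
                   simulate = cfg$simulate, stage_reached = "start")
  save_manifest <- function() jsonlite::write_json(
    manifest, file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res <- list()
  tryCatch({
    recs <- if (cfg$simulate) {
      unlist(lapply(seq_along(cfg$sim_ages), function(i) {
        simulate_cohort(age_div = cfg$sim_ages[i],
                        n_per_group = cfg$sim_n_per_group,
                        n_electrodes = cfg$sim_n_electrodes,
                        duration = cfg$sim_duration,
                        seed = derive_seed(cfg$seed, i))
      }), recursive = FALSE)
    } else lapply(cfg$input, read_mea_h5)
    manifest$n_recordings <- length(recs)
    manifest$stage_reached <- "load"

    res$features <- features_table(recs, cfg$config)
    utils::write.csv(res$features, file.path(cfg$out_dir, "features.csv"),
                     row.names = FALSE)
    manifest$stage_reached <- "features"

    res$comparison <- comparison_table(res$features,
                                       family = cfg$stats_family)
    utils::write.csv(res$comparison, file.path(cfg$out_dir, "comparison.csv"),
                     row.names = FALSE)
    manifest$stage_reached <- "group_stats"

    res$pca <- list(); res$classification <- list()
    for (a in sort(unique(res$features$age_div))) {
      fa <- res$features[res$features$age_div == a, ]
      if (length(unique(fa$region)) < 2 || nrow(fa) < 6) next
      fm <- feature_matrix(fa)
      xi <- fm$x
      for (j in seq_len(ncol(xi)))  # cohort-median imputation for PCA
        xi[is.na(xi[, j]), j] <-
          if (all(is.na(fm$x[, j]))) 0
          else stats::median(fm$x[, j], na.rm = TRUE)
      pc <- withCallingHandlers(pca_project(xi, labels = fm$y),
                                warning = function(w) invokeRestart("muffleWarning"))
      pdf_ <- data.frame(array_id = fa$array_id, region = fa$region,
                         pc$projections[, seq_len(min(3, ncol(pc$projections))),
                                        drop = FALSE])
      utils::write.csv(pdf_, file.path(cfg$out_dir,
                                       sprintf("pca_div%02d.csv", a)),
                       row.names = FALSE)
      res$pca[[as.character(a)]] <- pc

      cl <- evaluate_classifier(fm$x, fm$y, method = cfg$ml_method,
                                n_repeats = cfg$ml_repeats,
                                seed = derive_seed(cfg$seed, 100 + a),
                                ntree = cfg$ntree)
      res$classification[[as.character(a)]] <- cl
    }
    jsonlite::write_json(
      lapply(res$classification, function(cl)
        list(method = cl$method, mean_accuracy = cl$mean_accuracy,
             accuracy_sd = cl$accuracy_sd, n_repeats = cl$n_repeats,
             importance = as.list(cl$importance))),
      file.path(cfg$out_dir, "classification.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest$stage_reached <- "classification"
    manifest$finished <- format(Sys.time(), tz = "UTC")
    save_manifest()
  }, error = function(e) {
    manifest$error <<- conditionMessage(e)
    save_manifest()
    stop(e)
  })
  invisible(res)
}

#' Importance-ordered accuracy matrix across ages
#'
#' Builds the summary matrix of the analysis: features ranked by their
#' average normalised Gini importance across ages, and for each rank k the
#' per-age mean accuracy using only the top-k features.
#'
#' @param features Tidy feature table covering several ages.
#' @param method,n_repeats,seed,ntree Passed to the evaluation.
#' @param min_per_group Skip ages with fewer recordings than this per
#'   region.
#' @return List: `ranking` (data frame feature/score) and `accuracy`
#'   (matrix, feature rank x age).
#' @export
importance_table <- function(features, method = "forest", n_repeats = 100,
                             seed = 1, ntree = 500, min_per_group = 3) {
  ages <- sort(unique(features$age_div))
  imp_acc <- NULL; n_ages <- 0
  per_age <- list()
  for (a in ages) {
    fa <- features[features$age_div == a, ]
    if (min(table(factor(fa$region, c("CTX", "HPC")))) < min_per_group) next
    fm <- feature_matrix(fa)
    cl <- evaluate_classifier(fm$x, fm$y, method = "forest",
                              n_repeats = n_repeats,
                              seed = derive_seed(seed, a), ntree = ntree)
    imp_acc <- if (is.null(imp_acc)) cl$importance else imp_acc + cl$importance
    n_ages <- n_ages + 1
    per_age[[as.character(a)]] <- fm
  }
  if (!n_ages) stop("no age has enough recordings per group")
  score <- imp_acc / n_ages
  score <- score / max(score)
  ranking <- names(sort(score, decreasing = TRUE))
  acc <- matrix(NA_real_, length(ranking), length(per_age),
                dimnames = list(ranking, names(per_age)))
  for (a in names(per_age)) {
    fm <- per_age[[a]]
    inc <- incremental_performance(fm$x, fm$y, ranking, method = method,
                                   n_repeats = n_repeats,
                                   seed = derive_seed(seed, 500 + as.integer(a)),
                                   ntree = ntree)
    acc[, a] <- inc$mean_accuracy
  }
  list(ranking = data.frame(feature = ranking,
                            score = round(score[ranking], 2),
                            stringsAsFactors = FALSE),
       accuracy = acc)
}
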