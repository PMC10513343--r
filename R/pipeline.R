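#' Study run configuration
#'
#' Bundles every module's parameters plus the master seed. Serializable to
#' YAML, so a run is fully determined by the file and the package version.
#' Per-module seeds are derived from the master seed by a fixed splitting
#' rule (`sample.int` under `set.seed(master_seed)`), so modules can be
#' re-run independently.
#'
#' @param generator a [gen_config()] of the shared generator parameters.
#' @param n_sequences number of artworks (default 8).
#' @param rating_model a [rating_model()] for synthetic ratings.
#' @param master_seed integer master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(generator = gen_config(velocity = 1 / 60),
                       n_sequences = 8L,
                       rating_model = genart::rating_model(),
                       master_seed = 1L) {
  structure(list(generator = generator, n_sequences = as.integer(n_sequences),
                 rating_model = rating_model,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Write a run configuration to YAML
#' @param config a [run_config()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  ser <- list(generator = unclass(config$generator),
              n_sequences = config$n_sequences,
              rating_model = lapply(unclass(config$rating_model), function(x)
                if (is.null(names(x))) x else as.list(x)),
              master_seed = config$master_seed)
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by [write_run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gc_args <- y$generator
  gc_args$perm <- NULL
  rm_args <- y$rating_model
  rm_args$coefficients <- unlist(rm_args$coefficients)
  run_config(generator = do.call(gen_config, gc_args),
             n_sequences = y$n_sequences,
             rating_model = do.call(rating_model, rm_args),
             master_seed = y$master_seed)
}

#' Run the full study pipeline
#'
#' Generation, feature extraction, (synthetic or supplied) ratings,
#' correlation report and the three panel regressions, written to a run
#' directory: images as PNG, tables as CSV, diagnostics and a manifest
#' (seeds plus config hash) as YAML.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; a manifest from a previous
#'   identical run makes the images step resume/skip).
#' @param ratings optional external aggregate ratings data frame
#'   (`sequence_id`, `time_s`, `mean_rating`); if supplied, the synthetic
#'   rating stage is skipped and these are used verbatim.
#' @param write_images write PNG files (default `TRUE`).
#' @param predictors predictor set for the regressions; `NULL` (default)
#'   runs best-subset selection over all non-constant features.
#' @return invisibly, a list with `features`, `ratings`, `correlations`,
#'   `selection`, `fits` (pooled/fixed/random), `hausman`, `diagnostics`.
#' @export
run_study <- function(config, out_dir, ratings = NULL, write_images = TRUE,
                      predictors = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(config$master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)  # stimuli, ratings, spare
  seqs <- make_study_stimuli(config$generator, config$n_sequences,
                             master_seed = seeds[1])
  if (write_images)
    for (s in seqs) write_sequence_png(s, file.path(out_dir, "images"))
  logs <- do.call(rbind, lapply(seqs, `[[`, "color_log"))
  utils::write.csv(logs, file.path(out_dir, "color_log.csv"),
                   row.names = FALSE)
  features <- extract_study_features(seqs)
  utils::write.csv(features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  if (is.null(ratings)) {
    std_feats <- .standardize_features(features)
    rt <- simulate_ratings(std_feats, config$rating_model, seed = seeds[2])
    ratings <- rt$aggregates
    utils::write.csv(rt$ratings, file.path(out_dir, "ratings_individual.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(ratings, file.path(out_dir, "ratings_aggregate.csv"),
                   row.names = FALSE)
  correlations <- table_correlations(features, ratings)
  utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  pan <- standardize_panel(panel_table(features, ratings))
  avail <- setdiff(names(pan), c("entity", "time", "response"))
  selection <- NULL
  if (is.null(predictors)) {
    # exhaustive search is feasible up to ~12 candidates; prefilter by
    # marginal correlation with the response
    if (length(avail) > 12L) {
      r <- vapply(avail, function(p) abs(stats::cor(pan[[p]], pan$response)),
                  numeric(1))
      avail <- avail[order(-r)][1:12]
    }
    selection <- best_subset(pan, avail)
    predictors <- selection$chosen
  }
  fits <- list(pooled = pooled_ols(pan, predictors),
               fixed = suppressWarnings(fixed_effects(pan, predictors)),
               random = suppressWarnings(
                 random_effects_nerlove(pan, predictors)))
  hm <- hausman(fits$fixed, fits$random)
  diag <- residual_diagnostics(fits$fixed)
  coefs <- do.call(rbind, lapply(names(fits), function(k) {
    d <- fits[[k]]$coefficients
    d$model <- k
    d$adjusted_r2 <- fits[[k]]$adjusted_r2
    d$aic <- fits[[k]]$aic
    d
  }))
  utils::write.csv(coefs, file.path(out_dir, "regression_coefficients.csv"),
                   row.names = FALSE)
  cfg_path <- file.path(out_dir, "run_config.yaml")
  write_run_config(config, cfg_path)
  manifest <- list(master_seed = config$master_seed,
                   derived_seeds = as.list(seeds),
                   config_hash = unname(tools::md5sum(cfg_path)),
                   n_images = sum(vapply(seqs, function(s)
                     length(s$images), integer(1))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  yaml::write_yaml(list(hausman = hm,
                        shapiro = diag$shapiro, grubbs = diag$grubbs),
                   file.path(out_dir, "diagnostics.yaml"))
  invisible(list(features = features, ratings = ratings,
                 correlations = correlations, selection = selection,
                 fits = fits, hausman = hm, diagnostics = diag))
}

# standardize feature columns of a feature table (not a panel)
.standardize_features <- function(features) {
  for (f in setdiff(names(features), c("sequence_id", "time_s"))) {
    s <- stats::sd(features[[f]])
    features[[f]] <- if (is.finite(s) && s > 1e-12)
      (features[[f]] - mean(features[[f]])) / s else 0
  }
  features
}

#' Load an external per-image feature/rating table
#'
#' Reads a CSV with one row per image carrying the feature columns (named
#' as in [feature_names()], case/punctuation-insensitively) plus a mean
#' rating, and validates it into a balanced panel layout. Column aliases:
#' case is ignored and non-alphanumeric characters are treated as
#' underscores; `is`/`sequence` map to `sequence_id`, `time`/`t` to
#' `time_s`, `rating`/`mean`/`avg_rating` to `mean_rating`.
#'
#' @param path CSV file path.
#' @return list with `features` and `ratings` data frames ready for
#'   [panel_table()].
#' @export
load_supplementary <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  norm <- function(x) gsub("[^a-z0-9]+", "_", tolower(trimws(x)))
  nm <- norm(names(d))
  alias <- c(is = "sequence_id", sequence = "sequence_id",
             seq = "sequence_id", sequence_id = "sequence_id",
             time = "time_s", t = "time_s", time_s = "time_s",
             rating = "mean_rating", mean = "mean_rating",
             avg_rating = "mean_rating", mean_rating = "mean_rating",
             average_rating = "mean_rating")
  canon <- stats::setNames(feature_names(), norm(feature_names()))
  extra_alias <- c(number_of_colors = "n_colors", colors = "n_colors",
                   hue_average = "hue_avg", hue_sd = "hue_std",
                   horizontal_com = "horizontal_balance",
                   vertical_com = "vertical_balance",
                   first_order_entropy = "first_order_entropy",
                   complexity = "complexity_gs")
  mapped <- ifelse(nm %in% names(alias), alias[nm],
                   ifelse(nm %in% names(canon), canon[nm],
                          ifelse(nm %in% names(extra_alias),
                                 extra_alias[nm], nm)))
  dup <- mapped[duplicated(mapped)]
  if (length(dup)) stop("duplicated columns after alias resolution: ",
                        paste(unique(dup), collapse = ", "))
  names(d) <- mapped
  need <- c("sequence_id", "time_s", "mean_rating")
  missing <- setdiff(need, names(d))
  if (length(missing)) stop("missing required columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(d[, c("sequence_id", "time_s")]))
    stop("duplicated (sequence, time) rows")
  tab <- table(d$sequence_id)
  if (length(unique(tab)) != 1)
    stop("panel is not balanced across sequences")
  feats <- d[, c("sequence_id", "time_s",
                 intersect(feature_names(), names(d)))]
  ratings <- d[, c("sequence_id", "time_s", "mean_rating")]
  list(features = feats, ratings = ratings)
}
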