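#' Synthetic rating model
#'
#' Parameters of the synthetic-ratings generator that stands in for a
#' large rating survey. Individual ratings are built as
#' `clip_1_7(round(4 + profile(t) + sum(beta_j x_j) + u_seq + eps))` with a
#' rise-then-fall temporal profile, sequence-level random effects and a
#' residual SD that grows linearly with time (individual judgments diverge
#' as the artwork evolves). All parameters are artifact-side choices; none
#' is an estimate from survey data.
#'
#' @param peak_time time (seconds) of the profile maximum (default 36, so
#'   the peak falls in the 12--60 s window).
#' @param width log-scale width of the log-normal-shaped bump.
#' @param amplitude profile height at the peak, in rating units.
#' @param coefficients named vector of feature effects on standardized
#'   features (rating units per SD). Defaults carry the signs of the
#'   fixed-effects analysis: negative for skewness, horizontal balance,
#'   left-right symmetry and mean hue; positive for vertical balance and
#'   anisotropy.
#' @param entity_sd SD of the per-sequence random effect.
#' @param resid_sd0 residual SD at t = 0.
#' @param resid_growth residual-SD growth per second.
#' @param n_raters raters per sequence (default 212).
#' @return an object of class `rating_model`.
#' @export
rating_model <- function(peak_time = 36, width = 0.6, amplitude = 2.0,
                         coefficients = c(skewness = -0.05,
                                          horizontal_balance = -0.05,
                                          vertical_balance = 0.05,
                                          symmetry_lr = -0.45,
                                          anisotropy = 0.3,
                                          hue_avg = -0.2),
                         entity_sd = 0.15, resid_sd0 = 0.6,
                         resid_growth = 0.004, n_raters = 212L) {
  stopifnot(peak_time > 0, width > 0, amplitude >= 0, entity_sd >= 0,
            resid_sd0 >= 0, resid_growth >= 0, n_raters >= 1)
  structure(list(peak_time = peak_time, width = width, amplitude = amplitude,
                 coefficients = coefficients, entity_sd = entity_sd,
                 resid_sd0 = resid_sd0, resid_growth = resid_growth,
                 n_raters = as.integer(n_raters)),
            class = "rating_model")
}

#' Baseline temporal rating profile
#'
#' A unimodal log-normal-shaped bump
#' `amplitude * exp(-(log(t / peak_time))^2 / (2 width^2))` whose argmax is
#' `peak_time`; zero at `t = 0`. Over the 12--144 s sampling grid the mean
#' rating therefore rises, peaks between 12 and 60 seconds, and declines.
#'
#' @param t time(s) in seconds (>= 0).
#' @param model a [rating_model()].
#' @return profile value(s) in rating units.
#' @export
temporal_profile <- function(t, model) {
  stopifnot(all(t >= 0))
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- model$amplitude *
    exp(-(log(t[pos] / model$peak_time))^2 / (2 * model$width^2))
  out
}

#' Simulate individual ratings for a feature panel
#'
#' One integer rating in 1..7 per (rater, image). Raters are independent;
#' each sequence has its own rater pool (as in a between-subjects survey)
#' and a shared sequence-level effect `u_seq`.
#'
#' @param features data frame with `sequence_id`, `time_s` and (already
#'   standardized) predictor columns matching
#'   `names(model$coefficients)`; coefficients of absent features are
#'   ignored with a warning.
#' @param model a [rating_model()].
#' @param seed integer seed.
#' @return list of class `rating_table` with `ratings` (long data frame:
#'   `sequence_id`, `time_s`, `rater_id`, `rating`) and `aggregates`
#'   (per-image `mean_rating`, `sd_rating`, `n`).
#' @export
simulate_ratings <- function(features, model, seed = 1L) {
  stopifnot(inherits(model, "rating_model"))
  beta <- model$coefficients
  miss <- setdiff(names(beta), names(features))
  if (length(miss)) {
    warning("coefficients ignored for absent features: ",
            paste(miss, collapse = ", "))
    beta <- beta[setdiff(names(beta), miss)]
  }
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  ents <- unique(features$sequence_id)
  u <- stats::setNames(stats::rnorm(length(ents), 0, model$entity_sd), ents)
  lin <- if (length(beta))
    as.matrix(features[, names(beta), drop = FALSE]) %*% beta else 0
  mu <- 4 + temporal_profile(features$time_s, model) + as.vector(lin) +
    u[features$sequence_id]
  sd_t <- model$resid_sd0 + model$resid_growth * features$time_s
  n_img <- nrow(features)
  R <- model$n_raters
  eps <- matrix(stats::rnorm(n_img * R, 0, rep(sd_t, R)), n_img, R)
  ratings <- pmin(pmax(round(mu + eps), 1), 7)
  long <- data.frame(
    sequence_id = rep(features$sequence_id, R),
    time_s = rep(features$time_s, R),
    rater_id = paste0(rep(features$sequence_id, R), "_r",
                      rep(seq_len(R), each = n_img)),
    rating = as.vector(ratings))
  agg <- data.frame(sequence_id = features$sequence_id,
                    time_s = features$time_s,
                    mean_rating = rowMeans(ratings),
                    sd_rating = apply(ratings, 1, stats::sd),
                    n = R)
  structure(list(ratings = long, aggregates = agg), class = "rating_table")
}

#' Coefficient-recovery experiment
#'
#' Repeatedly simulates ratings for a fixed feature panel, runs best-subset
#' selection over a candidate pool and fits the fixed-effects estimator on
#' the selected set, then summarizes bias, selection rates and confidence
#' interval coverage per true coefficient.
#'
#' @param features standardized feature panel (`sequence_id`, `time_s` and
#'   predictor columns).
#' @param model the generating [rating_model()] (its `coefficients` are the
#'   recovery targets).
#' @param n_reps number of replications (>= 2).
#' @param candidates candidate predictor pool for subset selection
#'   (default: the model's active features plus all other numeric feature
#'   columns present).
#' @param select_criterion subset-selection criterion passed to
#'   [best_subset()]; the default `"aic"` keeps false inclusions of
#'   zero-coefficient predictors rare.
#' @param seed integer seed.
#' @return data frame with one row per candidate: `mean_estimate`, `bias`,
#'   `selected_rate`, `coverage` (95% CI coverage among reps where the
#'   predictor was selected), and `truth`.
#' @export
recovery_experiment <- function(features, model, n_reps = 50L,
                                candidates = NULL,
                                select_criterion = "aic", seed = 1L) {
  stopifnot(n_reps >= 2)
  fcols <- setdiff(names(features), c("sequence_id", "time_s"))
  if (is.null(candidates)) candidates <- fcols
  truth <- stats::setNames(numeric(length(candidates)), candidates)
  act <- intersect(names(model$coefficients), candidates)
  truth[act] <- model$coefficients[act]
  est <- sel <- cov <- matrix(NA_real_, n_reps, length(candidates),
                              dimnames = list(NULL, candidates))
  for (r in seq_len(n_reps)) {
    rt <- simulate_ratings(features, model, seed = seed + r)
    pan <- panel_table(features, rt$aggregates)
    # keep the response in rating units so estimates are comparable to truth
    pan <- standardize_panel(pan, include_response = FALSE)
    ss <- best_subset(pan, intersect(candidates, names(pan)),
                      criterion = select_criterion)
    fit <- fixed_effects(pan, ss$chosen)
    co <- fit$coefficients
    for (p in candidates) {
      i <- match(p, co$term)
      sel[r, p] <- as.numeric(!is.na(i))
      if (!is.na(i)) {
        est[r, p] <- co$estimate[i]
        cov[r, p] <- as.numeric(co$ci_low[i] <= truth[p] &
                                truth[p] <= co$ci_high[i])
      }
    }
  }
  data.frame(predictor = candidates, truth = unname(truth),
             mean_estimate = colMeans(est, na.rm = TRUE),
             bias = colMeans(est, na.rm = TRUE) - unname(truth),
             selected_rate = colMeans(sel),
             coverage = colMeans(cov, na.rm = TRUE), row.names = NULL)
}
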