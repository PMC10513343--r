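#' Assemble a balanced panel table
#'
#' Joins a feature table and aggregate ratings into a panel indexed by
#' (entity = sequence, time). The panel must be balanced: every
#' entity-time cell present exactly once.
#'
#' @param features feature table (`sequence_id`, `time_s`, features).
#' @param ratings aggregate ratings (`sequence_id`, `time_s`,
#'   `mean_rating`).
#' @return data frame of class `panel_table` with columns `entity`,
#'   `time`, the predictors, and `response`.
#' @export
panel_table <- function(features, ratings) {
  d <- merge(features, ratings[, c("sequence_id", "time_s", "mean_rating")],
             by = c("sequence_id", "time_s"))
  d$entity <- factor(d$sequence_id)
  d$time <- d$time_s
  d$response <- d$mean_rating
  d$sequence_id <- d$time_s <- d$mean_rating <- NULL
  tab <- table(d$entity, d$time)
  if (any(tab != 1)) stop("panel is not balanced: every (entity, time) cell must appear exactly once")
  class(d) <- c("panel_table", "data.frame")
  d
}

#' Standardize a panel
#'
#' Centers and scales every predictor (and, optionally, the response) to
#' mean 0 and SD 1 over all rows. Zero-variance predictors are dropped
#' with a warning. Idempotent.
#'
#' @param panel a `panel_table` (or data frame with `entity`, `time`,
#'   `response`).
#' @param include_response standardize the response too (default `TRUE`).
#' @return the standardized panel.
#' @export
standardize_panel <- function(panel, include_response = TRUE) {
  keep <- c("entity", "time", "response")
  preds <- setdiff(names(panel), keep)
  for (p in preds) {
    s <- stats::sd(panel[[p]])
    if (!is.finite(s) || s < 1e-12) {
      warning(sprintf("dropping zero-variance predictor '%s'", p))
      panel[[p]] <- NULL
    } else {
      panel[[p]] <- (panel[[p]] - mean(panel[[p]])) / s
    }
  }
  if (include_response)
    panel$response <- (panel$response - mean(panel$response)) /
      stats::sd(panel$response)
  panel
}

# design matrix (no intercept column) for a predictor set
.panel_X <- function(panel, predictors) {
  missing <- setdiff(predictors, names(panel))
  if (length(missing)) stop("unknown predictors: ", paste(missing, collapse = ", "))
  as.matrix(panel[, predictors, drop = FALSE])
}

.lm_summary <- function(coef, se, df, level = 0.95) {
  tval <- coef / se
  p <- 2 * stats::pt(-abs(tval), df)
  q <- stats::qt(1 - (1 - level) / 2, df)
  data.frame(term = names(coef), estimate = unname(coef), se = unname(se),
             t = unname(tval), p = unname(p),
             ci_low = unname(coef - q * se), ci_high = unname(coef + q * se),
             row.names = NULL)
}

# Gaussian AIC with estimated variance: n log(2*pi*RSS/n) + n + 2(k_total+1)
.gaussian_aic <- function(rss, n, k_total) {
  n * log(2 * pi * rss / n) + n + 2 * (k_total + 1)
}

#' Pooled OLS on a panel
#'
#' Ordinary least squares on all rows with an intercept; adjusted R2 and
#' Gaussian AIC.
#'
#' @param panel a (standardized) `panel_table`.
#' @param predictors character vector of predictor names.
#' @return a `regression_result`: list with `kind`, `coefficients` (data
#'   frame), `adjusted_r2`, `aic`, `residuals`, `fitted`, `df_residual`.
#' @export
pooled_ols <- function(panel, predictors) {
  X <- .panel_X(panel, predictors)
  y <- panel$response
  fit <- stats::lm(y ~ X)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  sm <- summary(fit)
  co <- stats::coef(sm)
  rownames(co) <- c("(Intercept)", colnames(X))
  n <- length(y); k <- ncol(X)
  rss <- sum(stats::resid(fit)^2)
  res <- list(kind = "pooled",
              coefficients = .lm_summary(stats::setNames(co[, 1], rownames(co)),
                                         stats::setNames(co[, 2], rownames(co)),
                                         fit$df.residual),
              r2 = sm$r.squared, adjusted_r2 = sm$adj.r.squared,
              aic = .gaussian_aic(rss, n, k + 1),
              residuals = unname(stats::resid(fit)),
              fitted = unname(stats::fitted(fit)),
              df_residual = fit$df.residual,
              vcov = {vc <- stats::vcov(fit); dimnames(vc) <- list(rownames(co), rownames(co)); vc},
              predictors = predictors, n = n)
  class(res) <- "regression_result"
  res
}

#' Fixed-effects (within) estimator
#'
#' Entity-demeaned OLS with residual degrees of freedom
#' `n - n_entities - k`. Predictors that are constant within every entity
#' are dropped with a warning (they are absorbed by the entity effects).
#' The reported adjusted R2 counts the entity effects among the model
#' parameters; `f_test` is the joint test of the `k` slope coefficients
#' against the entity-effects-only model.
#'
#' @param panel a (standardized) `panel_table`.
#' @param predictors character vector of predictor names.
#' @return a `regression_result` with additional fields `effects`
#'   (estimated entity effects) and `f_test`.
#' @export
fixed_effects <- function(panel, predictors) {
  X <- .panel_X(panel, predictors)
  y <- panel$response
  ent <- panel$entity
  demean <- function(m) m - ave(m, rep(ent, ncol(m)), FUN = mean)
  Xd <- apply(X, 2, function(col) col - ave(col, ent, FUN = mean))
  within_sd <- apply(Xd, 2, stats::sd)
  drop <- within_sd < 1e-10
  if (all(drop)) stop("all predictors are time-invariant within entities")
  if (any(drop)) {
    warning("dropping within-entity-constant predictors: ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, !drop, drop = FALSE]
    Xd <- Xd[, !drop, drop = FALSE]
    predictors <- predictors[!drop]
  }
  yd <- y - ave(y, ent, FUN = mean)
  fit <- stats::lm(yd ~ Xd - 1)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  n <- length(y); k <- ncol(Xd); ne <- nlevels(ent)
  df_res <- n - ne - k
  if (df_res <= 0) stop("not enough degrees of freedom")
  rss <- sum(stats::resid(fit)^2)
  sigma2 <- rss / df_res
  XtX_inv <- solve(crossprod(Xd))
  vc <- sigma2 * XtX_inv
  se <- sqrt(diag(vc))
  beta <- stats::coef(fit)
  names(beta) <- names(se) <- colnames(X)
  dimnames(vc) <- list(colnames(X), colnames(X))
  # entity effects and overall fit including them
  ybar <- tapply(y, ent, mean)
  xbar <- apply(X, 2, function(col) tapply(col, ent, mean))
  effects <- ybar - as.vector(xbar %*% beta)
  tss <- sum((y - mean(y))^2)
  r2_full <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2_full) * (n - 1) / df_res
  rss_restricted <- sum(yd^2)  # entity effects only
  fstat <- ((rss_restricted - rss) / k) / (rss / df_res)
  res <- list(kind = "fixed",
              coefficients = .lm_summary(beta, se, df_res),
              r2 = r2_full, adjusted_r2 = adj_r2,
              aic = .gaussian_aic(rss, n, k + ne),
              residuals = unname(stats::resid(fit)),
              fitted = y - unname(stats::resid(fit)),
              df_residual = df_res, vcov = vc,
              effects = effects,
              f_test = list(F = fstat, df1 = k, df2 = df_res,
                            p = stats::pf(fstat, k, df_res, lower.tail = FALSE)),
              predictors = predictors, n = n)
  class(res) <- "regression_result"
  res
}

#' Random-effects estimator with Nerlove variance components
#'
#' Balanced-panel GLS by quasi-demeaning with
#' `theta = 1 - sqrt(sigma2_e / (T * sigma2_u + sigma2_e))`, where
#' `sigma2_e` is the within residual sum of squares divided by `n*T` and
#' `sigma2_u` is the sample variance (denominator `n_entities - 1`) of the
#' fixed-effects entity effects. A negative variance estimate is clamped
#' to zero with a warning.
#'
#' @param panel a (standardized) balanced `panel_table`.
#' @param predictors character vector of predictor names.
#' @param theta_override optionally force the quasi-demeaning weight
#'   (used for limit checks; `0` reproduces pooled OLS, `1` the within
#'   estimator).
#' @return a `regression_result` with additional fields `theta`,
#'   `sigma2_u`, `sigma2_e`.
#' @export
random_effects_nerlove <- function(panel, predictors, theta_override = NULL) {
  X <- .panel_X(panel, predictors)
  y <- panel$response
  ent <- panel$entity
  ne <- nlevels(ent)
  Tt <- length(y) / ne
  if (abs(Tt - round(Tt)) > 1e-9) stop("panel must be balanced")
  fe <- suppressWarnings(fixed_effects(panel, predictors))
  # within residual variance, Nerlove convention (no df correction)
  sigma2_e <- sum(fe$residuals^2) / length(y)
  sigma2_u <- stats::var(fe$effects)
  if (sigma2_u < 0) { warning("negative variance clamped to 0"); sigma2_u <- 0 }
  theta <- if (!is.null(theta_override)) theta_override else
    1 - sqrt(sigma2_e / (Tt * sigma2_u + sigma2_e))
  qd <- function(vcol) vcol - theta * ave(vcol, ent, FUN = mean)
  ys <- qd(y)
  Xs <- apply(X, 2, qd)
  # at theta -> 1 the quasi-demeaned intercept column vanishes (within limit)
  keep_int <- (1 - theta) > 1e-8
  Z <- if (keep_int) cbind("(Intercept)" = qd(rep(1, length(y))), Xs) else Xs
  fit <- stats::lm(ys ~ Z - 1)
  n <- length(y); k <- ncol(X)
  df_res <- n - k - as.integer(keep_int)
  rss <- sum(stats::resid(fit)^2)
  sigma2 <- rss / df_res
  vc <- sigma2 * solve(crossprod(Z))
  se <- sqrt(diag(vc))
  beta <- stats::coef(fit)
  names(beta) <- names(se) <- colnames(Z)
  dimnames(vc) <- list(colnames(Z), colnames(Z))
  tss <- sum((ys - mean(ys))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res
  res <- list(kind = "random-nerlove",
              coefficients = .lm_summary(beta, se, df_res),
              r2 = r2, adjusted_r2 = adj_r2,
              aic = .gaussian_aic(rss, n, k + 1),
              residuals = unname(stats::resid(fit)),
              fitted = unname(y - stats::resid(fit)),
              df_residual = df_res, vcov = vc,
              theta = theta, sigma2_u = sigma2_u, sigma2_e = sigma2_e,
              predictors = predictors, n = n)
  class(res) <- "regression_result"
  res
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing predictor `j` on the others.
#' Perfectly collinear predictors are flagged with `Inf`.
#'
#' @param panel a `panel_table` (or data frame).
#' @param predictors character vector (>= 2 predictors).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(panel, predictors) {
  stopifnot(length(predictors) >= 2)
  X <- .panel_X(panel, predictors)
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(out, colnames(X))
}

#' Exhaustive best-subset selection
#'
#' Scores every predictor subset up to `max_size` on the pooled model;
#' records the best subset of each size (by R2, equivalently RSS) and
#' chooses the final set by adjusted R2 with an AIC tie-break.
#'
#' @param panel a (standardized) `panel_table`.
#' @param predictors candidate predictors (at most 20).
#' @param max_size largest subset size considered (default all).
#' @param criterion final choice criterion: `"adjusted_r2"` (default;
#'   AIC breaks ties) or `"aic"`, which penalizes model size more
#'   strongly and is preferred when false inclusions are costly (e.g.
#'   recovery experiments).
#' @return list of class `subset_selection` with `by_size` (data frame of
#'   the best subset per size), `chosen` (character vector) and `table`
#'   (all evaluated subsets).
#' @export
best_subset <- function(panel, predictors, max_size = length(predictors),
                        criterion = c("adjusted_r2", "aic")) {
  criterion <- match.arg(criterion)
  p <- length(predictors)
  if (p > 20) stop("exhaustive search limited to 20 predictors")
  if (p >= nrow(panel)) stop("more predictors than observations")
  X <- .panel_X(panel, predictors)
  y <- panel$response
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  rows <- list()
  for (k in seq_len(min(max_size, p))) {
    sets <- utils::combn(p, k, simplify = FALSE)
    for (s in sets) {
      Z <- cbind(1, X[, s, drop = FALSE])
      fit <- stats::lm.fit(Z, y)
      rss <- sum(fit$residuals^2)
      r2 <- 1 - rss / tss
      adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
      rows[[length(rows) + 1L]] <- data.frame(
        size = k, subset = paste(predictors[s], collapse = "+"),
        r2 = r2, adjusted_r2 = adj,
        aic = .gaussian_aic(rss, n, k + 1))
    }
  }
  tab <- do.call(rbind, rows)
  by_size <- do.call(rbind, lapply(split(tab, tab$size), function(d)
    d[which.max(d$r2), ]))
  ord <- if (criterion == "adjusted_r2")
    order(-by_size$adjusted_r2, by_size$aic)
  else order(by_size$aic, -by_size$adjusted_r2)
  chosen <- strsplit(by_size$subset[ord[1]], "+", fixed = TRUE)[[1]]
  structure(list(by_size = by_size, chosen = chosen, table = tab),
            class = "subset_selection")
}

# Moore-Penrose pseudo-inverse via SVD
.pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
    t(s$u[, pos, drop = FALSE])
}

#' Hausman specification test
#'
#' Compares fixed- and random-effects estimates on their shared slope
#' coefficients: `(b_FE - b_RE)' (V_FE - V_RE)^-1 (b_FE - b_RE)`. A
#' non-invertible (or non-positive-definite) variance difference falls
#' back to the Moore-Penrose inverse with a warning, and the statistic is
#' clamped at zero.
#'
#' @param fe,re `regression_result`s from [fixed_effects()] and
#'   [random_effects_nerlove()].
#' @return named list `chi2`, `df`, `p`.
#' @export
hausman <- function(fe, re) {
  shared <- intersect(fe$coefficients$term, re$coefficients$term)
  shared <- setdiff(shared, "(Intercept)")
  if (length(shared) == 0) stop("no shared coefficients")
  bf <- fe$coefficients$estimate[match(shared, fe$coefficients$term)]
  br <- re$coefficients$estimate[match(shared, re$coefficients$term)]
  Vf <- fe$vcov[shared, shared, drop = FALSE]
  Vr <- re$vcov[shared, shared, drop = FALSE]
  d <- bf - br
  V <- Vf - Vr
  chi2 <- tryCatch({
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(abs(ev))) stop("not positive definite")
    drop(t(d) %*% solve(V, d))
  }, error = function(e) {
    warning("variance difference not positive definite; using pseudo-inverse")
    drop(t(d) %*% .pinv(V) %*% d)
  })
  chi2 <- max(chi2, 0)
  df <- length(shared)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Principal-component regression on a panel
#'
#' PCA of the (standardized) predictors; the chosen estimator is then fit
#' on the first `n_components` scores.
#'
#' @param panel a standardized `panel_table`.
#' @param predictors predictor names to decompose.
#' @param n_components number of leading components to use.
#' @param estimator one of "pooled", "fixed", "random".
#' @return list with the `regression_result` (`fit`), the `rotation`
#'   (loading matrix) and `cumulative_variance`.
#' @export
pc_regression <- function(panel, predictors, n_components,
                          estimator = c("pooled", "fixed", "random")) {
  estimator <- match.arg(estimator)
  X <- .panel_X(panel, predictors)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (n_components > sum(pc$sdev > 1e-10)) stop("n_components exceeds rank")
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  d <- panel[, c("entity", "time", "response")]
  for (j in seq_len(n_components)) d[[paste0("PC", j)]] <- scores[, j]
  class(d) <- class(panel)
  pcs <- paste0("PC", seq_len(n_components))
  fit <- switch(estimator,
                pooled = pooled_ols(d, pcs),
                fixed = fixed_effects(d, pcs),
                random = random_effects_nerlove(d, pcs))
  list(fit = fit, rotation = pc$rotation,
       cumulative_variance = cumsum(pc$sdev^2) / sum(pc$sdev^2))
}

#' Grubbs's single-outlier test
#'
#' `G = max |e_i - mean| / sd` with the usual two-sided t-based p-value.
#'
#' @param x numeric vector (n >= 7 recommended).
#' @return named list `G`, `p`.
#' @export
grubbs_test <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  G <- max(abs(x - mean(x))) / stats::sd(x)
  denom <- (n - 1)^2 - n * G^2
  p <- if (denom <= 0) 0 else {
    tval <- sqrt(n * (n - 2) * G^2 / denom)
    min(1, 2 * n * stats::pt(-tval, n - 2))
  }
  list(G = G, p = p)
}

#' Residual diagnostics for a regression result
#'
#' Shapiro-Wilk normality and Grubbs's outlier test on the residuals.
#'
#' @param result a `regression_result`.
#' @return list with `shapiro` (`W`, `p`) and `grubbs` (`G`, `p`).
#' @export
residual_diagnostics <- function(result) {
  e <- result$residuals
  if (length(e) < 7) stop("need at least 7 residuals")
  list(shapiro = shapiro_wilk(e), grubbs = grubbs_test(e))
}
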