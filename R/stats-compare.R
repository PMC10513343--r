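#' Spearman correlation with a Fisher-z confidence interval
#'
#' Spearman's rho with midranks for ties; the confidence interval applies
#' the Fisher z transform to rho with variance `1.06 / (n - 3)`, the usual
#' large-sample approximation for rank correlations. The p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @param level confidence level (default 0.95).
#' @return data frame with `rho`, `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
spearman_ci <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  rho <- stats::cor(rank(x), rank(y))
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  se <- sqrt(1.06 / (n - 3))
  q <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  data.frame(rho = rho, ci_low = tanh(z - q * se), ci_high = tanh(z + q * se),
             p_value = p, n = n)
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Thin wrapper returning the H statistic (tie-corrected), degrees of
#' freedom and p-value.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return named list `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' All group pairs are tested; raw p-values are multiplied by the number
#' of comparisons and capped at 1. The exact distribution is used for
#' groups smaller than 10 (without ties), the normal approximation with
#' continuity correction otherwise.
#'
#' @param groups named list of numeric vectors.
#' @return symmetric matrix of adjusted p-values (diagonal `NA`).
#' @export
pairwise_wilcoxon_bonferroni <- function(groups) {
  g <- length(groups)
  stopifnot(g >= 2)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(g))
  m <- choose(g, 2)
  out <- matrix(NA_real_, g, g, dimnames = list(nm, nm))
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      exact <- min(length(groups[[i]]), length(groups[[j]])) < 10
      p <- suppressWarnings(
        stats::wilcox.test(groups[[i]], groups[[j]], exact = exact,
                           correct = TRUE)$p.value)
      out[i, j] <- out[j, i] <- min(1, p * m)
    }
  }
  out
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric vector with 3 to 5000 observations.
#' @return named list `W`, `p`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  st <- stats::shapiro.test(x)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Feature correlation report (features vs time and vs rating)
#'
#' For every image feature, Spearman rho with the sampling time and with
#' the mean aesthetic rating, each with its Fisher-z confidence interval,
#' computed over the pooled image-level observations. A feature that is
#' constant (e.g. a color feature in a perfectly balanced design) yields
#' `NA` entries rather than an error.
#'
#' @param features feature table from [extract_study_features()] (columns
#'   `sequence_id`, `time_s` and the 22 features).
#' @param ratings aggregate ratings with columns `sequence_id`, `time_s`,
#'   `mean_rating`.
#' @param level confidence level (default 0.95).
#' @return data frame with one row per feature: `feature`, `rho_time`,
#'   `ci_low_time`, `ci_high_time`, `p_time`, `rho_rating`,
#'   `ci_low_rating`, `ci_high_rating`, `p_rating`.
#' @export
table_correlations <- function(features, ratings, level = 0.95) {
  need <- c("sequence_id", "time_s")
  if (!all(need %in% names(features)) || !all(c(need, "mean_rating") %in% names(ratings)))
    stop("missing required columns")
  d <- merge(features, ratings[, c("sequence_id", "time_s", "mean_rating")],
             by = c("sequence_id", "time_s"))
  fn <- intersect(feature_names(), names(d))
  one <- function(x, y) {
    r <- tryCatch(spearman_ci(x, y, level), error = function(e) NULL)
    if (is.null(r)) c(NA_real_, NA_real_, NA_real_, NA_real_) else
      c(r$rho, r$ci_low, r$ci_high, r$p_value)
  }
  rows <- lapply(fn, function(f) {
    a <- one(d[[f]], d$time_s)
    b <- one(d[[f]], d$mean_rating)
    data.frame(feature = f, rho_time = a[1], ci_low_time = a[2],
               ci_high_time = a[3], p_time = a[4], rho_rating = b[1],
               ci_low_rating = b[2], ci_high_rating = b[3], p_rating = b[4])
  })
  do.call(rbind, rows)
}
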