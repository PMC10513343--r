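test_that("Spearman rho hits the exact endpoints and brute-force ranks", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3)
  expect_equal(spearman_ci(x, x)$rho, 1)
  expect_equal(spearman_ci(x, -x)$rho, -1)
  set.seed(10)
  y <- rnorm(10)
  r <- spearman_ci(x, y)
  # independent oracle: Pearson correlation of explicitly computed ranks
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(r$rho, oracle)
  expect_true(r$ci_low <= r$rho && r$rho <= r$ci_high)
  expect_error(spearman_ci(rep(1, 5), rnorm(5)), "constant")
})

test_that("Fisher-z interval has near-nominal coverage on normal data", {
  set.seed(12)
  n <- 30; rho <- 0.5; hits <- 0; reps <- 500
  for (i in seq_len(reps)) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    true_rs <- 6 / pi * asin(rho / 2)  # population Spearman for bivariate normal
    ci <- spearman_ci(x, y)
    hits <- hits + (ci$ci_low <= true_rs && true_rs <= ci$ci_high)
  }
  expect_gt(hits / reps, 0.92)
  expect_lt(hits / reps, 0.99)
})

test_that("Kruskal-Wallis H matches a brute-force midrank computation", {
  set.seed(13)
  groups <- list(rnorm(12), rnorm(12, 0.5), rnorm(12, 1))
  kw <- kruskal_wallis(groups)
  expect_equal(kw$df, 2)
  # oracle: direct rank-sum formula without ties
  allv <- unlist(groups)
  rk <- rank(allv)
  n <- length(allv)
  idx <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  H <- 12 / (n * (n + 1)) *
    sum(tapply(rk, idx, sum)^2 / tapply(rk, idx, length)) - 3 * (n + 1)
  expect_equal(kw$H, H, tolerance = 1e-10)
  # identical groups: H near zero (only tie noise)
  same <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_lt(kruskal_wallis(same)$H, 1e-10)
  expect_equal(kruskal_wallis(rep(list(rnorm(5)), 8))$df, 7)
  expect_error(kruskal_wallis(list(rnorm(3), numeric(0))), "empty")
})

test_that("pairwise Wilcoxon with Bonferroni inflates and caps p-values", {
  set.seed(14)
  groups <- list(a = rnorm(12), b = rnorm(12, 0.3), c = rnorm(12, 3))
  m <- pairwise_wilcoxon_bonferroni(groups)
  expect_equal(dim(m), c(3, 3))
  expect_true(all(is.na(diag(m))))
  expect_true(all(m[upper.tri(m)] <= 1))
  raw <- suppressWarnings(
    stats::wilcox.test(groups$a, groups$b, exact = FALSE,
                       correct = TRUE)$p.value)
  expect_equal(m["a", "b"], min(1, raw * 3))
  expect_gte(m["a", "b"], raw)
  # disjoint groups reach the minimal achievable adjusted p
  disj <- list(x = 1:12, y = 13:24)
  md <- pairwise_wilcoxon_bonferroni(disj)
  raw_min <- suppressWarnings(
    stats::wilcox.test(disj$x, disj$y, exact = FALSE,
                       correct = TRUE)$p.value)
  expect_equal(md["x", "y"], raw_min)
  # identical groups give adjusted p of 1
  same <- list(p = c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2, 3, 4),
               q = c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2, 3, 4))
  expect_equal(unname(pairwise_wilcoxon_bonferroni(same)["p", "q"]), 1)
})

test_that("Shapiro-Wilk wrapper bounds W and rejects bimodal data", {
  set.seed(15)
  nrm <- shapiro_wilk(rnorm(200))
  expect_true(nrm$W > 0 && nrm$W <= 1)
  rejections <- 0
  for (i in 1:20) {
    bim <- c(rnorm(50, -4, 0.3), rnorm(50, 4, 0.3))
    if (shapiro_wilk(bim)$p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections, 19)
  expect_error(shapiro_wilk(rnorm(2)), "3 <= n")
})

test_that("the correlation report covers every feature against both targets", {
  set.seed(16)
  feats <- data.frame(sequence_id = rep(c("A", "B"), each = 12),
                      time_s = rep(seq(12, 144, by = 12), 2))
  for (f in feature_names()) feats[[f]] <- rnorm(24)
  feats$n_colors <- 5  # constant column must yield NA, not an error
  ratings <- data.frame(sequence_id = feats$sequence_id,
                        time_s = feats$time_s,
                        mean_rating = rnorm(24, 4))
  rep_ <- table_correlations(feats, ratings)
  expect_equal(nrow(rep_), 22)
  expect_true(all(c("rho_time", "rho_rating") %in% names(rep_)))
  expect_true(is.na(rep_$rho_time[rep_$feature == "n_colors"]))
  ok <- rep_$feature != "n_colors"
  expect_true(all(abs(rep_$rho_time[ok]) <= 1))
})
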