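test_that("standardization gives exact moments and is idempotent", {
  pan <- synthetic_panel(betas = c(x1 = 1, x2 = -0.5), seed = 20)
  class(pan) <- c("panel_table", "data.frame")
  sp <- standardize_panel(pan)
  for (p in c("x1", "x2")) {
    expect_lt(abs(mean(sp[[p]])), 1e-12)
    expect_equal(sd(sp[[p]]), 1, tolerance = 1e-12)
  }
  expect_equal(sd(sp$response), 1, tolerance = 1e-12)
  sp2 <- standardize_panel(sp)
  expect_equal(sp2$x1, sp$x1, tolerance = 1e-12)
  pan$flat <- 3
  expect_warning(standardize_panel(pan), "zero-variance")
})

test_that("standardized simple regression slope equals the correlation", {
  pan <- synthetic_panel(betas = c(x1 = 2), entity_sd = 0, noise_sd = 1,
                         seed = 21)
  class(pan) <- c("panel_table", "data.frame")
  sp <- standardize_panel(pan)
  fit <- pooled_ols(sp, "x1")
  r <- cor(sp$x1, sp$response)
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "x1"], r,
               tolerance = 1e-10)
})

test_that("pooled OLS matches the textbook hat-matrix computation", {
  set.seed(22)
  d <- data.frame(entity = factor(rep(c("a", "b"), 5)), time = rep(1:5, 2),
                  response = rnorm(10), x1 = rnorm(10), x2 = rnorm(10))
  fit <- pooled_ols(d, c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d$response)
  expect_equal(fit$coefficients$estimate, as.vector(beta), tolerance = 1e-10)
  # residual orthogonality (normal equations)
  expect_lt(max(abs(t(X) %*% fit$residuals)), 1e-10)
  # perfect fit case
  d$response <- d$x1
  perfect <- suppressWarnings(pooled_ols(d, "x1"))  # perfect-fit warning
  expect_equal(perfect$r2, 1, tolerance = 1e-12)
  expect_equal(perfect$coefficients$estimate[2], 1, tolerance = 1e-10)
})

test_that("fixed effects equal the dummy-variable OLS oracle", {
  pan <- synthetic_panel(betas = c(x1 = 1.5, x2 = -1, x3 = 0.2),
                         entity_sd = 2, seed = 23)
  fe <- fixed_effects(pan, c("x1", "x2", "x3"))
  oracle <- lm(response ~ x1 + x2 + x3 + entity, data = pan)
  expect_equal(fe$coefficients$estimate,
               unname(coef(oracle)[c("x1", "x2", "x3")]), tolerance = 1e-8)
  expect_equal(fe$coefficients$se,
               unname(sqrt(diag(vcov(oracle)))[c("x1", "x2", "x3")]),
               tolerance = 1e-8)
  # df: n - entities - k
  expect_equal(fe$df_residual, 96 - 8 - 3)
})

test_that("within transform is invariant to per-entity response shifts", {
  pan <- synthetic_panel(betas = c(x1 = 1), seed = 24)
  fe1 <- fixed_effects(pan, "x1")
  pan2 <- pan
  shift <- rnorm(nlevels(pan$entity), 0, 10)
  pan2$response <- pan$response + shift[as.integer(pan$entity)]
  fe2 <- fixed_effects(pan2, "x1")
  expect_equal(fe1$coefficients$estimate, fe2$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("time-invariant predictors are dropped with a warning", {
  pan <- synthetic_panel(betas = c(x1 = 1), seed = 25)
  pan$const_in_entity <- as.numeric(pan$entity)
  expect_warning(fe <- fixed_effects(pan, c("x1", "const_in_entity")),
                 "const_in_entity")
  expect_equal(fe$coefficients$term, "x1")
  pan$only <- as.numeric(pan$entity)
  expect_error(suppressWarnings(fixed_effects(pan, "only")), "time-invariant")
})

test_that("random effects interpolate between pooled and within estimates", {
  pan <- synthetic_panel(betas = c(x1 = 1, x2 = -0.7), entity_sd = 1,
                         seed = 26)
  preds <- c("x1", "x2")
  po <- pooled_ols(pan, preds)
  fe <- fixed_effects(pan, preds)
  re0 <- random_effects_nerlove(pan, preds, theta_override = 0)
  expect_equal(re0$coefficients$estimate, po$coefficients$estimate,
               tolerance = 1e-10)
  # at theta = 1 the intercept vanishes and the fit is the within estimator
  re1 <- random_effects_nerlove(pan, preds, theta_override = 1 - 1e-9)
  est1 <- re1$coefficients
  expect_equal(est1$estimate[match(preds, est1$term)],
               fe$coefficients$estimate, tolerance = 1e-5)
  # estimated theta lies strictly between the limits
  re <- random_effects_nerlove(pan, preds)
  expect_true(re$theta > 0 && re$theta < 1)
})

test_that("Nerlove components match an independent quasi-demeaning pipeline", {
  pan <- synthetic_panel(betas = c(x1 = 1), entity_sd = 1.5, seed = 27)
  re <- random_effects_nerlove(pan, "x1")
  # oracle: recompute from scratch with explicit loops
  fe <- fixed_effects(pan, "x1")
  s2e <- sum(fe$residuals^2) / nrow(pan)
  s2u <- var(fe$effects)
  Tt <- 12
  theta <- 1 - sqrt(s2e / (Tt * s2u + s2e))
  expect_equal(re$theta, theta)
  ybar <- ave(pan$response, pan$entity)
  xbar <- ave(pan$x1, pan$entity)
  ys <- pan$response - theta * ybar
  xs <- pan$x1 - theta * xbar
  ones <- 1 - theta
  Z <- cbind(ones, xs)
  beta <- solve(t(Z) %*% Z, t(Z) %*% ys)
  expect_equal(re$coefficients$estimate, as.vector(beta), tolerance = 1e-10)
})

test_that("VIF matches its closed form for two predictors", {
  set.seed(28)
  n <- 200
  x1 <- rnorm(n); x2 <- 0.8 * x1 + sqrt(1 - 0.64) * rnorm(n)
  d <- data.frame(entity = factor(rep(1:4, 50)), time = rep(1:50, 4),
                  response = rnorm(n), x1 = x1, x2 = x2)
  v <- vif(d, c("x1", "x2"))
  r2 <- cor(x1, x2)^2
  expect_equal(unname(v["x1"]), 1 / (1 - r2), tolerance = 1e-10)
  # orthogonal designs give VIF 1; duplicates are flagged infinite
  d$x3 <- d$x2
  expect_true(is.infinite(suppressWarnings(vif(d, c("x2", "x3")))["x3"]))
})

test_that("best subset equals a brute-force scan and recovers active predictors", {
  pan <- synthetic_panel(betas = c(x1 = 1, x2 = 0.8), noise_sd = 0.2,
                         entity_sd = 0, seed = 29, n_extra = 3)
  preds <- c("x1", "x2", paste0("noise", 1:3))
  sel <- best_subset(pan, preds)
  expect_true(all(c("x1", "x2") %in% sel$chosen))
  # oracle: evaluate all 31 subsets by lm and compare the chosen criterion
  best_adj <- -Inf; best_set <- NULL
  for (k in 1:5) for (s in combn(preds, k, simplify = FALSE)) {
    f <- lm(reformulate(s, "response"), data = pan)
    adj <- summary(f)$adj.r.squared
    if (adj > best_adj) { best_adj <- adj; best_set <- s }
  }
  expect_setequal(sel$chosen, best_set)
  expect_equal(max(sel$by_size$adjusted_r2), best_adj, tolerance = 1e-10)
  # unadjusted R2 of per-size winners is non-decreasing
  expect_true(all(diff(sel$by_size$r2) >= -1e-12))
})

test_that("subset selection recovers the active pair at moderate SNR", {
  hits <- 0
  for (i in 1:40) {
    pan <- synthetic_panel(betas = c(x1 = 1, x2 = 1), noise_sd = 0.45,
                           entity_sd = 0, seed = 400 + i, n_extra = 8)
    sel <- best_subset(pan, c("x1", "x2", paste0("noise", 1:8)))
    if (all(c("x1", "x2") %in% sel$chosen)) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("Hausman statistic is zero for identical fits and >= 0 always", {
  pan <- synthetic_panel(betas = c(x1 = 1, x2 = -0.5), entity_sd = 0.8,
                         seed = 31)
  fe <- fixed_effects(pan, c("x1", "x2"))
  hm0 <- suppressWarnings(hausman(fe, fe))  # zero variance difference
  expect_equal(hm0$chi2, 0, tolerance = 1e-10)
  re <- random_effects_nerlove(pan, c("x1", "x2"))
  hm <- suppressWarnings(hausman(fe, re))
  expect_gte(hm$chi2, 0)
  expect_equal(hm$df, 2)
})

test_that("Hausman does not over-reject under exogeneity", {
  # with few entities the test is conservative (FE and RE estimates are
  # strongly correlated at large theta), so the check is one-sided: the
  # size must not exceed the nominal 5% by more than Monte Carlo error
  set.seed(32)
  rej <- 0; reps <- 200; stats <- numeric(reps)
  for (i in seq_len(reps)) {
    pan <- synthetic_panel(betas = c(x1 = 1), entity_sd = 1, noise_sd = 1,
                           seed = 5000 + i)
    fe <- fixed_effects(pan, "x1")
    re <- random_effects_nerlove(pan, "x1")
    hm <- suppressWarnings(hausman(fe, re))
    stats[i] <- hm$chi2
    if (hm$p < 0.05) rej <- rej + 1
  }
  expect_lte(rej / reps, 0.08)
  expect_true(all(is.finite(stats)) && all(stats >= 0))
  expect_gt(mean(stats), 0)
})

test_that("principal-component regression matches the eigendecomposition", {
  pan <- synthetic_panel(betas = c(x1 = 1, x2 = -1, x3 = 0.5),
                         entity_sd = 0.5, seed = 33, n_extra = 2)
  preds <- c("x1", "x2", "x3", "noise1", "noise2")
  class(pan) <- c("panel_table", "data.frame")
  sp <- standardize_panel(pan)
  pcr <- pc_regression(sp, preds, n_components = 3, estimator = "pooled")
  scores <- as.matrix(sp[, preds]) %*% pcr$rotation[, 1:3]
  G <- crossprod(scale(scores, scale = FALSE))
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  ev <- eigen(cor(as.matrix(sp[, preds])), symmetric = TRUE)
  expect_equal(abs(unname(pcr$rotation[, 1])), abs(unname(ev$vectors[, 1])),
               tolerance = 1e-8)
  expect_true(all(diff(pcr$cumulative_variance) >= -1e-12))
  expect_error(pc_regression(sp, preds, n_components = 9), "rank")
})

test_that("Grubbs test matches its closed form and flags gross outliers", {
  x <- c(rep(-1, 5), rep(1, 5))
  g <- grubbs_test(x)
  expect_equal(g$G, max(abs(x)) / sd(x))
  set.seed(34)
  e <- rnorm(50); e[7] <- 9
  expect_lt(grubbs_test(e)$p, 0.01)
  clean <- rnorm(50)
  expect_gt(grubbs_test(clean)$p, 0.001)
})

test_that("residual diagnostics bundle Shapiro and Grubbs", {
  pan <- synthetic_panel(betas = c(x1 = 1), seed = 35)
  fe <- fixed_effects(pan, "x1")
  d <- residual_diagnostics(fe)
  expect_named(d, c("shapiro", "grubbs"))
  expect_true(d$shapiro$W <= 1)
  expect_gte(d$grubbs$G, 0)
})

test_that("coefficient CIs cover the truth at close to nominal rate", {
  reps <- 200; hits <- 0
  for (i in seq_len(reps)) {
    pan <- synthetic_panel(betas = c(x1 = 0.7), entity_sd = 0.6,
                           noise_sd = 0.5, seed = 7000 + i)
    fe <- fixed_effects(pan, "x1")
    co <- fe$coefficients
    if (co$ci_low[1] <= 0.7 && 0.7 <= co$ci_high[1]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.90)
  expect_lte(hits / reps, 0.99)
})
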