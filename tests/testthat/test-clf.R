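test_that("fully penalized fit is intercept-only at the class log-odds", {
  fx <- latent_group_fixture(seed = 2)
  fit <- fit_enet_logistic(fx$x, fx$y, enet_spec(), lambda = 1e4)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, qlogis(mean(fx$y == "HCC")), tolerance = 1e-4)
})

test_that("unpenalized fit matches the logistic MLE from glm", {
  fx <- latent_group_fixture(n_pos = 15, n_neg = 20, bayes_auc = 0.75,
                             seed = 4)
  fit <- fit_enet_logistic(fx$x, fx$y, enet_spec(standardize = FALSE),
                           lambda = 0)
  ref <- glm(I(fx$y == "HCC") ~ fx$x, family = binomial())
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-5)
  expect_equal(unname(fit$beta), unname(coef(ref)[-1]), tolerance = 1e-5)
})

test_that("elastic-net solution satisfies the subgradient KKT conditions", {
  fx <- latent_group_fixture(n_pos = 12, n_neg = 18, bayes_auc = 0.8,
                             seed = 6)
  spec <- enet_spec(alpha = 0.66, standardize = FALSE)
  lambda <- 0.02
  fit <- fit_enet_logistic(fx$x, fx$y, spec, lambda)
  y01 <- as.integer(fx$y == "HCC")
  n <- nrow(fx$x)
  eta <- fit$intercept + drop(fx$x %*% fit$beta)
  p <- plogis(eta)
  # gradient of the negative mean log-likelihood
  g <- -crossprod(fx$x, y01 - p) / n
  g0 <- -sum(y01 - p) / n
  expect_lt(abs(g0), 1e-7)
  for (j in seq_along(fit$beta)) {
    gj <- g[j] + lambda * (1 - spec$alpha) * fit$beta[j]
    if (fit$beta[j] != 0) {
      expect_lt(abs(gj + lambda * spec$alpha * sign(fit$beta[j])), 1e-7)
    } else {
      expect_lte(abs(gj), lambda * spec$alpha + 1e-7)
    }
  }
})

test_that("LOOCV bookkeeping is honest and the 1se rule is respected", {
  fx <- latent_group_fixture(seed = 8)
  cv <- loocv_enet(fx$x, fx$y)
  expect_length(cv$oof_scores, nrow(fx$x))
  expect_true(all(is.finite(cv$oof_scores)))
  expect_gte(cv$lambda_1se, cv$lambda_min)
  # 1se definition against the stored curve
  imin <- which.min(cv$cvm)
  ok <- cv$cvm <= cv$cvm[imin] + cv$cvsd[imin]
  expect_equal(cv$lambda_1se, max(cv$lambda[ok]))

  # leaving out sample i must change nothing about its own influence:
  # recompute fold i manually at the same grid
  i <- 5
  fit_i <- glmnet::glmnet(fx$x[-i, ], as.integer(fx$y[-i] == "HCC"),
                          family = "binomial", alpha = 0.66,
                          lambda = cv$lambda, standardize = TRUE)
  s_i <- as.numeric(glmnet::predict.glmnet(
    fit_i, fx$x[i, , drop = FALSE], s = cv$lambda_1se, type = "link"))
  expect_equal(unname(cv$oof_scores[i]), s_i, tolerance = 1e-8)
})

test_that("a single informative feature is selected from noise", {
  # one feature separates with margin, three are pure noise; the 1se rule
  # should retain exactly the informative one
  fx <- latent_group_fixture(n_pos = 9, n_neg = 16, k = 4,
                             bayes_auc = 0.95, seed = 1)
  cv <- loocv_enet(fx$x, fx$y)
  expect_identical(cv$support, "F1")
})

test_that("coefficient path shrinks monotonically in lambda", {
  fx <- latent_group_fixture(seed = 13)
  spec <- enet_spec()
  y01 <- as.integer(fx$y == "HCC")
  fit <- glmnet::glmnet(fx$x, y01, family = "binomial", alpha = spec$alpha,
                        nlambda = 50)
  l1 <- colSums(abs(as.matrix(fit$beta)))
  # lambda is decreasing along the path, so the l1 norm must not decrease
  expect_true(all(diff(l1) >= -1e-8))
})

test_that("roc_analysis computes the Mann-Whitney AUC with its invariants", {
  lab <- c(0, 0, 1, 1)
  expect_equal(roc_analysis(c(0.1, 0.2, 0.8, 0.9), lab)$auc, 1)
  r <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), lab)
  expect_equal(r$auc, 0.75)

  # label swap symmetry
  r_sw <- roc_analysis(c(0.1, 0.4, 0.35, 0.8), 1 - lab)
  expect_equal(r_sw$auc, 1 - r$auc)

  # ties counted 1/2
  expect_equal(roc_analysis(c(0.5, 0.5, 0.5, 0.5, 1), c(0, 1, 0, 1, 1))$auc,
               (0.5 + 0.5 + 1 + 0.5 + 0.5 + 1) / 6)

  # pair-counting equals trapezoidal area under the empirical ROC
  set.seed(17)
  for (rep in 1:5) {
    sc <- rnorm(30)
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    r2 <- roc_analysis(sc, y)
    pts <- roc_points(sc, y)
    trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
    expect_equal(r2$auc, trap, tolerance = 1e-12)
  }
})

test_that("the Youden point maximizes sens + spec - 1 with coherent confusion counts", {
  set.seed(19)
  sc <- rnorm(40)
  y <- rbinom(40, 1, 0.5)
  r <- roc_analysis(sc, y)
  # exhaustive threshold oracle
  best <- max(vapply(sort(unique(sc)), function(t) {
    pred <- as.integer(sc >= t)
    sum(pred & y) / sum(y) + sum(!pred & !y) / sum(!y) - 1
  }, numeric(1)))
  expect_equal(r$youden_index, best, tolerance = 1e-12)
  expect_equal(sum(r$confusion), 40)
  expect_equal(r$accuracy,
               (r$confusion[["TP"]] + r$confusion[["TN"]]) / 40)

  # constant scores are degenerate with AUC 1/2
  rc <- roc_analysis(rep(1, 10), rep(c(0, 1), 5))
  expect_equal(rc$auc, 0.5)
  expect_true(rc$degenerate)
})

test_that("DeLong interval brackets the AUC and matches pROC", {
  skip_if_not_installed("pROC")
  set.seed(23)
  sc <- rnorm(30)
  y <- rep(c(0, 1), 15)
  sc[y == 1] <- sc[y == 1] + 1
  r <- roc_analysis(sc, y)
  ref <- pROC::roc(y, sc, levels = c(0, 1), direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_lte(r$ci_95[1], r$auc)
  expect_gte(r$ci_95[2], r$auc)
})

test_that("permutation null is seeded and ranks the observed AUC sensibly", {
  fx <- latent_group_fixture(n_pos = 8, n_neg = 10, k = 3,
                             bayes_auc = 0.55, seed = 29)
  spec <- enet_spec(nlambda = 30)
  p1 <- permutation_auc(fx$x, fx$y, spec, n_permutations = 99, seed = 7)
  p2 <- permutation_auc(fx$x, fx$y, spec, n_permutations = 99, seed = 7)
  expect_identical(p1$null_aucs, p2$null_aucs)
  expect_gt(p1$p_value, 0)
  expect_lte(p1$p_value, 1)
  if (p1$observed_auc < median(p1$null_aucs)) {
    expect_gt(p1$p_value, 0.5)
  }
  expect_error(permutation_auc(fx$x, fx$y, spec, n_permutations = 10),
               "permutation")
})

test_that("evaluate_latent_classifier screens then classifies", {
  fx <- latent_group_fixture(n_pos = 9, n_neg = 16, k = 6,
                             bayes_auc = 0.97, seed = 31)
  ev <- evaluate_latent_classifier(fx$x, fx$y)
  expect_true("F1" %in% ev$screened)
  expect_gte(ev$roc$auc, 0.8)

  ev_in <- evaluate_latent_classifier(fx$x, fx$y, screen = "in-fold")
  expect_length(ev_in$cv$oof_scores, 25)

  # no-signal data: screening refuses
  set.seed(33)
  null_x <- matrix(rnorm(25 * 4), 25, 4)
  expect_error(evaluate_latent_classifier(null_x, fx$y), "screening")
})
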