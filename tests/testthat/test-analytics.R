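# Screening statistics, SVR fitting against independent oracles, grid
# search, evaluation, importance scaling, Shapley attribution, pipeline.

test_that("spearman is rank-invariant and matches the permutation oracle", {
  x <- c(3.2, 1.5, 9.8, 4.4, 7.7, 2.2, 8.8, 5.1)
  expect_equal(spearman(x, exp(x))$rho, 1)            # monotone transform
  expect_equal(spearman(x, -2 * x + 5)$rho, -1)       # reversing transform
  expect_error(spearman(x, rep(1, 8)), "constant")
  expect_error(spearman(1:2, 1:2), "length >= 3")

  y <- c(7, 1, 5, 2, 6, 4, 3, 8)                     # moderate association
  got <- spearman(x, y)
  exact <- oracle_perm_spearman_p(x, y)
  expect_lt(abs(got$p_value - exact) / exact, 0.10)
})

test_that("VIF is 1 for orthogonal designs and Inf for exact collinearity", {
  base <- cbind(a = c(-1, 1, -1, 1), b = c(-1, -1, 1, 1), c = c(1, -1, -1, 1))
  X <- as.data.frame(base[rep(1:4, 3), ])
  v <- compute_vif(X, c("a", "b", "c"))
  expect_equal(unname(v$vif), rep(1, 3), tolerance = 1e-12)
  expect_identical(v$retained, c("a", "b", "c"))

  set.seed(1)
  Y <- data.frame(a = rnorm(30), b = rnorm(30))
  Y$dup <- Y$a
  v2 <- compute_vif(Y, c("a", "b", "dup"))
  expect_identical(unname(v2$vif[c("a", "dup")]), c(Inf, Inf))
  expect_identical(v2$retained, "b")
})

test_that("VIF matches an independent normal-equations solve", {
  set.seed(7)
  Z <- matrix(rnorm(200 * 9), 200, 9) %*% chol(0.5 * diag(9) + 0.5)
  colnames(Z) <- paste0("f", 1:9)
  tab <- as.data.frame(Z)
  got <- compute_vif(tab, colnames(Z))$vif
  for (j in 1:9) {
    A <- cbind(1, Z[, -j]); yj <- Z[, j]
    beta <- solve(crossprod(A), crossprod(A, yj))
    r2 <- 1 - sum((yj - A %*% beta)^2) / sum((yj - mean(yj))^2)
    expect_equal(unname(got[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("the VIF threshold retains features in input order", {
  expect_identical(apply_vif_threshold(c(a = 11, b = 2)), "b")
  expect_identical(apply_vif_threshold(c(a = 11, b = 2), Inf), c("a", "b"))
  expect_identical(apply_vif_threshold(c(x = 3, y = 10, z = 10.01)),
                   c("x", "y"))
})

test_that("split sizes follow half-up rounding and scaling uses train stats", {
  tab <- generate_tracts(generator_config(n_tracts = 178, seed = 13))
  feats <- tract_features()
  sp <- split_standardize(tab, "obesity_prev", feats,
                          analytics_config(split_seed = 4))
  expect_identical(nrow(sp$X_train), 151L) # round(178 * 0.85) half-up
  expect_identical(nrow(sp$X_test), 27L)
  expect_lt(max(abs(colMeans(sp$X_train))), 1e-12)
  expect_lt(max(abs(apply(sp$X_train, 2, sd) - 1)), 1e-12)
  sp2 <- split_standardize(tab, "obesity_prev", feats,
                           analytics_config(split_seed = 4))
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_error(split_standardize(tab[1:5, ], "obesity_prev", feats,
                                 analytics_config(train_fraction = 0.95)),
               "empty")
})

test_that("SVR handles the zero-loss case and recovers noiseless OLS", {
  set.seed(2)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("u", "v")))
  m <- fit_svr_linear(X, rep(7, 40), C = 1, epsilon = 0.1)
  expect_equal(unname(m$weights), c(0, 0))
  expect_equal(unname(predict(m, X)), rep(7, 40))

  beta <- c(u = 1.5, v = -0.8)
  y <- drop(X %*% beta) + 2
  m2 <- fit_svr_linear(X, y, C = 1e4, epsilon = 1e-6)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(m2$weights), unname(ols[-1]), tolerance = 1e-3)
  expect_equal(m2$intercept, unname(ols[1]), tolerance = 1e-3)
})

test_that("the SVR solution agrees with an independent dual QP solve", {
  skip_if_not_installed("kernlab")
  set.seed(5)
  n <- 30; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(n, 0, 0.5)
  C <- 2; eps <- 0.1
  m <- fit_svr_linear(X, y, C, eps)
  prim <- upho:::svr_objective(m, X, y)

  K <- tcrossprod(X)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * n)
  cc <- c(eps - y, eps + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), 1)
  sol <- kernlab::ipop(cc, H, A, 0, rep(0, 2 * n), rep(C, 2 * n), 0,
                       sigf = 9, maxiter = 400)
  a <- kernlab::primal(sol)
  dual <- -(sum(cc * a) + 0.5 * drop(t(a) %*% H %*% a))
  # strong duality: the relative duality gap vanishes at the optimum
  expect_lt(abs(prim - dual) / abs(dual), 1e-6)
})

test_that("grid search returns the CV-RMSE argmin with deterministic ties", {
  set.seed(11)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- drop(X %*% c(2, -1, 0.5)) + rnorm(60, 0, 0.3)

  one <- grid_search_cv(X, y, analytics_config(
    split_seed = 1, grid_C = 2, grid_epsilon = 0.1))
  expect_identical(unname(one$best), c(2, 0.1))

  # noiseless data: a tight-epsilon, high-C point drives CV RMSE to zero
  y0 <- drop(X %*% c(2, -1, 0.5))
  gz <- grid_search_cv(X, y0, analytics_config(
    split_seed = 1, grid_C = c(0.25, 100), grid_epsilon = c(1e-6, 0.5)))
  expect_identical(unname(gz$best), c(100, 1e-6))
  expect_lt(min(gz$cv_table$mean_rmse), 1e-4)

  # winner never beaten, and the table matches an independent recomputation
  cfg <- analytics_config(split_seed = 9, grid_C = c(0.5, 2),
                          grid_epsilon = c(0.1, 0.5))
  gs <- grid_search_cv(X, y, cfg)
  expect_true(all(gs$cv_table$mean_rmse >=
                  gs$cv_table$mean_rmse[gs$cv_table$C == gs$best[["C"]] &
                                        gs$cv_table$epsilon == gs$best[["epsilon"]]]))
  set.seed(9)
  idx <- sample.int(60)
  fold_of <- rep(1:5, each = 12)
  for (g in seq_len(nrow(gs$cv_table))) {
    rmses <- vapply(1:5, function(k) {
      hold <- idx[fold_of == k]
      fit <- e1071::svm(X[-hold, ], y[-hold], type = "eps-regression",
                        kernel = "linear", cost = gs$cv_table$C[g],
                        epsilon = gs$cv_table$epsilon[g], scale = FALSE,
                        tolerance = 1e-6)
      pred <- drop(X[hold, ] %*% drop(t(fit$coefs) %*% fit$SV)) - fit$rho
      sqrt(mean((y[hold] - pred)^2))
    }, 0)
    expect_equal(gs$cv_table$mean_rmse[g], mean(rmses), tolerance = 1e-6)
  }
})

test_that("evaluation computes RMSE and R-squared as defined", {
  m <- structure(list(weights = c(x = 1), intercept = 0, C = 1, epsilon = 0,
                      scaling_stats = NULL), class = "svr_model")
  X <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "x"))
  perfect <- evaluate(m, X, c(1, 2, 3))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)

  m0 <- structure(list(weights = c(x = 0), intercept = 2, C = 1, epsilon = 0,
                       scaling_stats = NULL), class = "svr_model")
  at_mean <- evaluate(m0, X, c(1, 2, 3))
  expect_equal(at_mean$r2, 0)

  m3 <- structure(list(weights = c(x = 1), intercept = 0, C = 1, epsilon = 0,
                       scaling_stats = NULL), class = "svr_model")
  X3 <- matrix(c(1, 2, 4), 3, 1, dimnames = list(NULL, "x"))
  hand <- evaluate(m3, X3, c(1, 2, 3)) # predictions (1,2,4) vs (1,2,3)
  expect_equal(hand$rmse, sqrt(1 / 3))
  expect_equal(hand$r2, 0.5)
  expect_error(evaluate(m, X, c(2, 2, 2)), "zero-variance")
})

test_that("importance spans exactly 0 to 100 unless degenerate", {
  m <- structure(list(weights = c(a = 0.2, b = -1.4, c = 0.7)),
                 class = "svr_model")
  imp <- importance(m)
  expect_equal(min(imp$scaled), 0)
  expect_equal(max(imp$scaled), 100)
  expect_identical(imp$feature[which.max(imp$scaled)], "b")

  m2 <- structure(list(weights = c(a = 2, b = -2)), class = "svr_model")
  expect_warning(imp2 <- importance(m2), "equal")
  expect_identical(imp2$scaled, c(0, 0))
})

test_that("closed-form Shapley equals the exhaustive coalition oracle", {
  set.seed(21)
  p <- 5
  feats <- paste0("f", 1:p)
  bg <- as.data.frame(matrix(rnorm(40 * p, 10, 3), 40, p,
                             dimnames = list(NULL, feats)))
  mu <- colMeans(bg); sdev <- vapply(bg, sd, 0)
  w_std <- c(1.2, -0.4, 0.9, 0, 2.5)
  model <- structure(list(weights = setNames(w_std, feats), intercept = 40,
                          C = 1, epsilon = 0.1,
                          scaling_stats = list(mean = mu, sd = sdev)),
                     class = "svr_model")
  x <- setNames(as.numeric(bg[3, ]), feats)
  got <- shapley_linear(model, x, bg)
  want <- oracle_shapley(w_std / sdev, x, colMeans(as.matrix(bg)))
  expect_equal(unname(got$phi), want, tolerance = 1e-9)
  # efficiency, and the baseline instance attributes nothing
  expect_equal(sum(got$phi),
               got$instance_prediction - got$baseline_prediction,
               tolerance = 1e-9)
  base <- shapley_linear(model, colMeans(as.matrix(bg)), bg)
  expect_equal(unname(base$phi), rep(0, p), tolerance = 1e-12)
  expect_error(shapley_linear(model, x[-1], bg), "missing feature")
})

test_that("the pipeline reaches the reported fit-quality regime on low noise", {
  cfg <- generator_config(n_tracts = 178, seed = 31, outcome_noise_sd = 1)
  tab <- generate_tracts(cfg)
  fit <- run_analytics(tab, focus_geoid = tab$geoid[1],
                       config = analytics_config(split_seed = 31))
  expect_gte(fit$evaluation$r2_test, 0.9)
  expect_gte(fit$evaluation$r2_train, 0.9)
  # determinism field by field
  fit2 <- run_analytics(tab, focus_geoid = tab$geoid[1],
                        config = analytics_config(split_seed = 31))
  expect_equal(fit2[setdiff(names(fit2), "config")],
               fit[setdiff(names(fit), "config")])
  # attribution efficiency on the pipeline output
  expect_equal(sum(fit$attribution$phi),
               fit$attribution$instance_prediction -
                 fit$attribution$baseline_prediction, tolerance = 1e-9)
})

test_that("a table with outcome-independent features fails screening", {
  set.seed(6)
  n <- 40
  tab <- data.frame(geoid = sprintf("47157%06d", 1:n),
                    obesity_prev = runif(n, 20, 60),
                    poverty = runif(n, 5, 50),
                    unemployment = runif(n, 2, 25),
                    stringsAsFactors = FALSE)
  # verify the fixture: both features uncorrelated with the outcome
  stopifnot(spearman(tab$poverty, tab$obesity_prev)$p_value > 0.1,
            spearman(tab$unemployment, tab$obesity_prev)$p_value > 0.1)
  expect_error(run_analytics(tab, features = c("poverty", "unemployment")),
               "survive Spearman screening")
})
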