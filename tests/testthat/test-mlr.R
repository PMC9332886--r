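test_that("OLS coefficients match the normal-equations oracle", {
  set.seed(42)
  X <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + X %*% c(0.5, -1, 2) + rnorm(30, sd = 0.3)
  m <- fit_ols(X, drop(y))
  expect_equal(unname(m$coefficients), unname(oracle_normal_equations(X, drop(y))),
               tolerance = 1e-10)
  # standard errors against lm
  lmfit <- lm(y ~ X)
  expect_equal(unname(m$se), unname(summary(lmfit)$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(m$stats$F, summary(lmfit)$fstatistic[["value"]],
               tolerance = 1e-10)
})

test_that("OLS degenerate cases behave as defined", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y_exact <- drop(2 + X %*% c(1, -2, 0.5))
  m <- fit_ols(X, y_exact)
  expect_equal(m$stats$R2, 1, tolerance = 1e-12)
  expect_lt(m$stats$RSS_tr, 1e-20)

  y_const_fit <- fit_ols(X, rnorm(20))
  expect_equal(y_const_fit$stats$RSS_tr,
               y_const_fit$stats$RMSE_tr^2 * 20, tolerance = 1e-12)
  expect_lte(y_const_fit$stats$R2adj, y_const_fit$stats$R2)

  Xs <- cbind(X, d = X[, 1] * 2)  # exact collinearity
  expect_error(fit_ols(Xs, y_exact), "collinear.*[ad]")
})

test_that("hat-matrix LOO equals brute-force refits to 1e-10", {
  set.seed(7)
  X <- matrix(rnorm(80), 20, 4)
  colnames(X) <- paste0("d", 1:4)
  y <- drop(1 + X %*% c(1, 0.5, -0.5, 0.2) + rnorm(20, sd = 0.5))
  fast <- q2_loo(X, y)
  slow <- oracle_loo(X, y)
  expect_equal(fast$Q2_LOO, slow$Q2, tolerance = 1e-10)
  expect_equal(fast$PRESS, slow$PRESS, tolerance = 1e-10)
  expect_equal(fast$pred, slow$pred, tolerance = 1e-10)
})

test_that("LOO brackets: perfect fit gives 1, PRESS dominates RSS, noise gives Q2 < R2", {
  set.seed(8)
  X <- matrix(rnorm(100), 25, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y_perfect <- drop(X %*% c(1, 2, 3, 4))
  expect_equal(q2_loo(X, y_perfect)$Q2_LOO, 1, tolerance = 1e-10)

  for (s in 1:5) {
    set.seed(s)
    Xn <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, paste0("d", 1:3)))
    yn <- rnorm(50)
    m <- fit_ols(Xn, yn)
    loo <- q2_loo(Xn, yn)
    expect_gt(m$stats$R2, loo$Q2_LOO)
    expect_gte(loo$PRESS, m$stats$RSS_tr)
  }
  # pure-noise Q2 is negative in expectation
  q2s <- vapply(1:40, function(s) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(150), 50, 3)
    q2_loo(Xn, rnorm(50))$Q2_LOO
  }, 0)
  expect_lt(mean(q2s), 0)
})

test_that("LMO approaches LOO for strong signal and is seed-deterministic", {
  ds <- make_planted(n = 67, p = 8, k = 5, target_r2 = 0.85, seed = 2)
  Xs <- ds$X[, ds$truth$idx]
  loo <- q2_loo(Xs, ds$y)$Q2_LOO
  lmo <- q2_lmo(Xs, ds$y, leave_fraction = 0.3, n_iter = 500, seed = 5)
  expect_lt(abs(lmo$Q2_LMO - loo), 0.05)
  expect_identical(lmo$Q2_LMO,
                   q2_lmo(Xs, ds$y, 0.3, n_iter = 500, seed = 5)$Q2_LMO)
  expect_error(q2_lmo(Xs, ds$y, leave_fraction = 0.95), "infeasible")
})

test_that("concordance correlation obeys its closed forms", {
  set.seed(3)
  x <- rnorm(30)
  expect_equal(ccc(x, x), 1)
  # location shift only: cov = var = S, so CCC = 2S / (2S + c^2)
  cshift <- 0.7
  S <- mean((x - mean(x))^2)
  expect_equal(ccc(x, x + cshift), 2 * S / (2 * S + cshift^2),
               tolerance = 1e-12)
  xc <- x - mean(x)
  expect_equal(ccc(xc, -xc), -1)
  expect_error(ccc(rep(1, 5), rep(1, 5)), "undefined")
})

test_that("external validation matches a spreadsheet-style oracle", {
  set.seed(9)
  Xtr <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("d", 1:3)))
  ytr <- drop(2 + Xtr %*% c(1, -0.5, 0.8) + rnorm(20, sd = 0.4))
  m <- fit_ols(Xtr, ytr)
  Xe <- matrix(rnorm(24), 8, 3, dimnames = list(NULL, paste0("d", 1:3)))
  ye <- drop(2 + Xe %*% c(1, -0.5, 0.8) + rnorm(8, sd = 0.4))
  ext <- external_validation(m, Xe, ye, q2_loo_value = q2_loo(Xtr, ytr)$Q2_LOO)
  ora <- oracle_external(ye, predict(m, Xe), ytr)
  expect_equal(ext$Q2_F1, ora$Q2_F1, tolerance = 1e-12)
  expect_equal(ext$Q2_F2, ora$Q2_F2, tolerance = 1e-12)
  expect_equal(ext$Q2_F3, ora$Q2_F3, tolerance = 1e-12)

  # perfect prediction: all statistics saturate
  perfect <- external_validation(m, Xe, predict(m, Xe))
  expect_equal(perfect$Q2_F2, 1)
  expect_equal(perfect$CCC_ex, 1)
  expect_equal(perfect$rm2_delta, 0, tolerance = 1e-12)

  # predicting the training mean gives Q2_F1 = 0
  m0 <- m
  m0$coefficients[] <- c(mean(ytr), 0, 0, 0)
  ext0 <- external_validation(m0, Xe, ye)
  expect_equal(ext0$Q2_F1, 0, tolerance = 1e-12)
})

test_that("Y-randomization: scrambled fits are weak, identity reproduces training R2", {
  ds <- make_planted(n = 67, p = 10, k = 5, target_r2 = 0.85, seed = 4)
  Xs <- ds$X[, ds$truth$idx]
  m <- fit_ols(Xs, ds$y)
  yr <- y_randomization(Xs, ds$y, n_iter = 200, seed = 6)
  expect_lt(yr$mean_R2, 0.2)
  expect_lt(yr$max_R2, m$stats$R2)
  ident <- y_randomization(Xs, ds$y, perms = list(seq_along(ds$y)))
  expect_equal(ident$R2, m$stats$R2, tolerance = 1e-12)
  empty <- y_randomization(Xs, ds$y, n_iter = 0)
  expect_true(empty$no_op)
  expect_length(empty$R2, 0)
})

test_that("QUIK K index matches the eigenvalue oracle and flags duplicates", {
  set.seed(10)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("d", 1:4)))
  y <- drop(X %*% c(2, 0, 0, 0) + rnorm(50, sd = 0.5))
  q <- quik_check(X, y)
  expect_equal(q$K_xx, oracle_k_index(X), tolerance = 1e-12)
  expect_equal(q$K_xxy, oracle_k_index(cbind(X, y)), tolerance = 1e-12)
  expect_gt(q$K_xxy, q$K_xx)

  # identical descriptor columns: K_xx hits its maximum of 1, so no y helps
  Xdup <- cbind(a = X[, 1], b = X[, 1])
  qd <- quik_check(Xdup, y)
  expect_equal(qd$K_xx, 1)
  expect_false(qd$pass)

  # exactly uncorrelated two-column block has uniform eigenvalues: K_xx = 0
  u <- rnorm(20)
  v <- residuals(lm(rnorm(20) ~ u))   # orthogonal to u after centring
  expect_equal(quik_check(cbind(a = u, b = v), rnorm(20))$K_xx, 0,
               tolerance = 1e-12)
  expect_error(quik_check(cbind(X[, 1], rep(1, 50)), y), "constant")
})

test_that("applicability domain: leverage identities and outlier labels", {
  set.seed(11)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("d", 1:3)))
  y <- drop(1 + X %*% c(1, 1, 1) + rnorm(20, sd = 0.3))
  m <- fit_ols(X, y)
  ad <- applicability_domain(m)
  expect_equal(sum(ad$table$leverage), ncol(X) + 1, tolerance = 1e-10)
  expect_equal(ad$h_star, 3 * 4 / 20)

  # single centred predictor: query at the training mean has h = 1/n
  x1 <- matrix(rnorm(12), 12, 1, dimnames = list(NULL, "d1"))
  x1 <- x1 - mean(x1)
  m1 <- fit_ols(x1, drop(2 * x1 + rnorm(12, sd = .2)))
  adq <- applicability_domain(m1, Xq = matrix(0, 1, 1,
                                              dimnames = list(NULL, "d1")))
  expect_equal(adq$table$leverage[adq$table$set == "test"], 1 / 12,
               tolerance = 1e-12)

  # constructed high-leverage training point is flagged as X outlier
  xx <- matrix(c(rnorm(9, sd = 0.2), 8), 10, 1,
               dimnames = list(NULL, "d1"))
  yy <- drop(1 + xx * 2) + c(rnorm(9, sd = .1), 0)
  mx <- fit_ols(xx, yy)
  adx <- applicability_domain(mx)
  expect_match(adx$table$label[10], "X_outlier")
  expect_error(
    applicability_domain(m, Xq = matrix(0, 1, 1,
                                        dimnames = list(NULL, "wrong"))),
    "do not match")
})

test_that("model equations format with standard errors and parse back", {
  set.seed(12)
  X <- matrix(rnorm(80), 20, 4,
              dimnames = list(NULL, c("avg_molweight", "fringCH3B",
                                      "fNringC6B", "lipo_ringS_8Bc")))
  y <- drop(13 - 0.8 * X[, 1] - 0.2 * X[, 2] + 0.3 * X[, 3] +
              4.5 * X[, 4] + rnorm(20, sd = 0.3))
  m <- fit_ols(X, y)
  eq <- format_model_equation(m)
  expect_match(eq, "^pEC50 = ")
  expect_match(eq, "lipo_ringS_8Bc")
  back <- parse_model_equation(eq)
  expect_equal(back$intercept, unname(m$coefficients[1]), tolerance = 1e-3)
  expect_equal(back$coefficients[m$descriptors],
               m$coefficients[-1], tolerance = 1e-3)
})

test_that("the full battery reproduces the expected statistic ordering", {
  ds <- make_planted(n = 84, p = 12, k = 5, target_r2 = 0.83, seed = 13)
  sp <- split_dataset(84, 0.8, seed = 13)
  Xs <- ds$X[, ds$truth$idx]
  rep <- validate_model(Xs[sp$train, ], ds$y[sp$train],
                        Xs[sp$test, ], ds$y[sp$test],
                        lmo_iter = 200, yrand_iter = 200, seed = 13)
  s <- rep$model$stats
  expect_gt(s$R2, rep$internal$Q2_LOO)
  expect_gte(rep$internal$Q2_LOO, rep$internal$Q2_LMO - 0.02)
  expect_gte(rep$internal$PRESS_cv, s$RSS_tr)
  expect_gt(s$CCC_tr, rep$internal$CCC_cv)
  expect_true(all(unlist(rep$internal[c("Q2_LOO", "Q2_LMO")]) <= 1))
  expect_true(rep$external$R2_ext <= 1 && rep$external$Q2_F2 <= 1)
  labs <- rep$domain$table$label
  expect_true(all(labs %in% c("inside", "X_outlier", "Y_outlier",
                              "XY_outlier", "model_outlier")))
})
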