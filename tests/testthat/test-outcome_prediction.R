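synthetic_regression <- function(n = 40, p = 6, informative = c(1, 2),
                                 beta = c(3, -2), noise = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * p, 0, 50), n, p,
              dimnames = list(sprintf("s%02d", 1:n),
                              sprintf("f%d", 1:p)))
  y <- as.numeric(X[, informative] %*% beta) + rnorm(n, 0, noise)
  list(X = X, y = y)
}

test_that("the lambda grid is log-spaced and inclusive of its endpoints", {
  expect_equal(lambda_grid(3, 0.01, 100), c(0.01, 1, 100),
               tolerance = 1e-12)
  g <- lambda_grid()
  expect_length(g, 100)
  expect_equal(g[1], 1e-5)
  expect_equal(g[100], 1e5)
  expect_true(all(diff(log(g)) > 0))
  # constant ratio between consecutive values (log spacing)
  expect_lt(diff(range(diff(log(g)))), 1e-12)
  expect_equal(lambda_grid(2, 0.5, 8), c(0.5, 8))
  expect_error(lambda_grid(1), "n")
  expect_error(lambda_grid(10, 0), "low")
  expect_error(lambda_grid(10, 2, 1), "high")
})

test_that("noise-free linear outcomes are recovered almost perfectly", {
  fx <- synthetic_regression()
  # OLS oracle: the system is exactly linear, so lm explains everything
  expect_gt(suppressWarnings(summary(lm(fx$y ~ fx$X))$r.squared), 0.999)
  res <- fit_lasso_loo(fx$X, fx$y)
  expect_gte(res$r2, 0.95)
  expect_true(all(abs(res$coefficients[c("f1", "f2")]) > 0))
  expect_true(res$lambda_selected %in% res$lambda_grid)
  expect_length(res$loo_predictions, 40)
})

test_that("full shrinkage drives all coefficients to fold means", {
  fx <- synthetic_regression(n = 12)
  res <- fit_lasso_loo(fx$X, fx$y, grid = c(1e9))
  expect_true(all(res$coefficients[-1] == 0))
  fold_means <- vapply(seq_len(12), function(i) mean(fx$y[-i]), numeric(1))
  expect_equal(unname(res$loo_predictions), fold_means, tolerance = 1e-6)
})

test_that("permuted outcomes yield near-zero out-of-sample R2", {
  fx <- synthetic_regression(n = 30, noise = 0.5, seed = 2)
  set.seed(3)
  r2s <- vapply(1:10, function(i)
    fit_lasso_loo(fx$X, sample(fx$y))$r2, numeric(1))
  expect_lte(mean(r2s), 0.1)
})

test_that("degenerate inputs are flagged or rejected", {
  fx <- synthetic_regression(n = 10)
  expect_error(fit_lasso_loo(fx$X[1:2, ], fx$y[1:2]), "fewer subjects")
  res <- fit_lasso_loo(fx$X, rep(2, 10))
  expect_false(res$r2_defined)
  expect_equal(res$r2, 0)
  # determinism: identical inputs give identical results
  res1 <- fit_lasso_loo(fx$X, fx$y)
  res2 <- fit_lasso_loo(fx$X, fx$y)
  expect_identical(res1$lambda_selected, res2$lambda_selected)
  expect_identical(res1$loo_predictions, res2$loo_predictions)
})

test_that("benchmark and combined models quantify the covariate channel", {
  set.seed(4)
  n <- 30
  records <- data.frame(subject_id = sprintf("s%02d", 1:n),
                        age = round(runif(n, 45, 90)),
                        sex = rbinom(n, 1, 0.5),
                        nihss = round(runif(n, 0, 30)))
  # outcome driven by the covariates, noise-free
  records$mrs <- round(pmin(6, pmax(0, 0.15 * records$nihss +
                                      0.02 * (records$age - 60))))
  bench <- benchmark_model(records)
  expect_gt(bench$r2, 0.8)

  # an uninformative atlas: combined ~ benchmark, delta ~ benchmark gain
  Xz <- matrix(0, n, 3, dimnames = list(records$subject_id,
                                        paste0("p", 1:3)))
  comb <- combined_model(Xz, records, atlas_result = NULL)
  expect_equal(comb$r2, bench$r2, tolerance = 0.05)
  atlas_only <- fit_lasso_loo(Xz, records$mrs)
  expect_equal(comb$delta_vs_benchmark, comb$r2 - atlas_only$r2,
               tolerance = 1e-12)

  # outcome independent of covariates: benchmark explains ~nothing
  set.seed(5)
  records2 <- records
  records2$mrs <- sample(0:6, n, replace = TRUE)
  expect_lte(benchmark_model(records2)$r2, 0.1)

  expect_error(combined_model(Xz[1:10, ], records), "subject mismatch")
})

test_that("model comparison sorts by R2 with deterministic ties", {
  mk <- function(id, r2) structure(list(model_id = id, r2 = r2,
                                        r2_insample = r2, loo_sd = 1,
                                        lambda_selected = 0.1,
                                        coefficients = c("(Intercept)" = 0),
                                        delta_vs_benchmark = NA_real_),
                                   class = "prediction_result")
  tab <- compare_models(list(mk("b", 0.3), mk("a", 0.4), mk("c", 0.1)))
  expect_equal(tab$model_id, c("a", "b", "c"))
  tab2 <- compare_models(list(mk("z", 0.2), mk("m", 0.2)))
  expect_equal(tab2$model_id, c("m", "z"))
  expect_equal(nrow(compare_models(list(mk("only", 0)))), 1L)
  expect_error(compare_models(list()), "no models")
})

test_that("stronger penalties never add coefficients on the full fit", {
  fx <- synthetic_regression(n = 25, noise = 1, seed = 6)
  grid <- lambda_grid(30, 1e-4, 1e4)
  nz <- vapply(grid, function(l) {
    res <- fit_lasso_loo(fx$X, fx$y, grid = c(l))
    sum(abs(res$coefficients[-1]) > 0)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))  # ascending lambda, nonincreasing support
})
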