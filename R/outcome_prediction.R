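#' Log-spaced regularization grid
#'
#' @param n number of values (>= 2).
#' @param low,high positive endpoints, `low < high`; both included.
#' @return Ascending numeric vector of `n` log-spaced values. The default
#'   covers 1e-5 to 1e5 in 100 steps, the standard search range for the
#'   Lasso L1 penalty here.
#' @export
lambda_grid <- function(n = 100L, low = 1e-5, high = 1e5) {
  if (n < 2L) stop("n must be >= 2")
  if (low <= 0) stop("low must be > 0")
  if (high <= low) stop("high must be > low")
  exp(seq(log(low), log(high), length.out = n))
}

## glmnet may stop a path early when the near-unpenalized end does not
## converge on a rank-deficient fold; the caller recycles the smallest
## converged solution, whose held-out error still enters model selection,
## so that specific warning is muffled rather than surfaced per fold
quiet_path_glmnet <- function(...) {
  withCallingHandlers(
    glmnet::glmnet(...),
    warning = function(w) {
      if (grepl("Convergence for .* lambda value not reached",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

## standardize train columns, drop constants, fit the lasso path and
## predict the held-out rows at every lambda (descending order)
fold_lasso_predict <- function(Xtr, ytr, Xte, lam_desc) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, sd)
  keep <- which(sdv > 1e-10)
  if (length(keep) == 0L || sd(ytr) < 1e-12)
    return(matrix(mean(ytr), nrow(Xte), length(lam_desc)))
  Xs <- scale(Xtr[, keep, drop = FALSE], center = mu[keep],
              scale = sdv[keep])
  Xts <- scale(Xte[, keep, drop = FALSE], center = mu[keep],
               scale = sdv[keep])
  if (ncol(Xs) == 1L) {                  # glmnet needs >= 2 columns
    Xs <- cbind(Xs, 0)
    Xts <- cbind(Xts, 0)
  }
  fit <- quiet_path_glmnet(Xs, ytr, alpha = 1, lambda = lam_desc,
                           family = "gaussian", standardize = FALSE,
                           thresh = 1e-9, maxit = 1e6)
  p <- predict(fit, newx = Xts)
  ## guard against a truncated path: recycle the last column if needed
  if (ncol(p) < length(lam_desc))
    p <- cbind(p, matrix(p[, ncol(p)], nrow(p),
                         length(lam_desc) - ncol(p)))
  p
}

## full-data lasso fit at one lambda; coefficients on the original scale
full_lasso_fit <- function(X, y, lam_desc, lambda) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  keep <- which(sdv > 1e-10)
  coefs <- setNames(rep(0, ncol(X)), colnames(X))
  if (length(keep) == 0L || sd(y) < 1e-12) {
    intercept <- mean(y)
  } else {
    Xs <- scale(X[, keep, drop = FALSE], center = mu[keep],
                scale = sdv[keep])
    pad <- ncol(Xs) == 1L
    if (pad) Xs <- cbind(Xs, 0)
    fit <- quiet_path_glmnet(Xs, y, alpha = 1, lambda = lam_desc,
                             family = "gaussian", standardize = FALSE,
                             thresh = 1e-9, maxit = 1e6)
    cf <- as.numeric(predict(fit, type = "coefficients", s = lambda,
                             exact = FALSE))
    b_std <- cf[-1]
    if (pad) b_std <- b_std[1]
    coefs[keep] <- b_std / sdv[keep]
    intercept <- cf[1] - sum(b_std * mu[keep] / sdv[keep])
  }
  fitted <- as.numeric(intercept + X %*% coefs)
  list(coefficients = c("(Intercept)" = intercept, coefs),
       fitted = fitted)
}

#' Lasso regression with leave-one-out selection of the L1 penalty
#'
#' For every lambda in the grid, each subject is predicted by a Lasso model
#' fitted on the remaining subjects (features standardized inside the
#' training fold only, so no information leaks into the held-out
#' prediction). The lambda maximizing the negative mean squared LOO error
#' is selected, ties resolved toward the larger (sparser) lambda. The
#' reported headline R-squared is out-of-sample, computed from the held-out
#' predictions; the in-sample variant from the final full-data fit is also
#' returned.
#'
#' @param X numeric matrix, subjects x features, subject ids as rownames.
#' @param y numeric outcome (e.g. 3-month mRS treated as a numeric target).
#' @param grid lambda values (any order; used descending internally).
#' @param model_id label carried into reports.
#' @return Object of class `prediction_result`: `model_id`,
#'   `lambda_selected`, `coefficients` (original scale, with intercept),
#'   `loo_predictions`, `r2` (out-of-sample), `r2_insample`, `loo_sd` (SD
#'   over folds of the squared LOO error), `neg_mse` (per ascending
#'   lambda), `r2_defined` and `delta_vs_benchmark` (`NA` here; see
#'   [combined_model()]).
#' @export
fit_lasso_loo <- function(X, y, grid = lambda_grid(), model_id = "model") {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 3L) stop("fewer subjects than 3")
  if (length(y) != n) stop("y must have one value per subject")
  if (is.null(rownames(X))) rownames(X) <- sprintf("s%03d", seq_len(n))
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  grid <- sort(as.numeric(grid))
  lam_desc <- rev(grid)
  preds <- matrix(NA_real_, n, length(lam_desc))
  for (i in seq_len(n))
    preds[i, ] <- fold_lasso_predict(X[-i, , drop = FALSE], y[-i],
                                     X[i, , drop = FALSE], lam_desc)
  neg_mse <- -colMeans((preds - y)^2)
  sel <- which.max(neg_mse)              # descending order: ties -> larger
  lambda_selected <- lam_desc[sel]
  loo_pred <- setNames(preds[, sel], rownames(X))
  ss_tot <- sum((y - mean(y))^2)
  r2_defined <- ss_tot > 0
  r2 <- if (r2_defined) 1 - sum((y - loo_pred)^2) / ss_tot else 0
  final <- full_lasso_fit(X, y, lam_desc, lambda_selected)
  r2_in <- if (r2_defined) 1 - sum((y - final$fitted)^2) / ss_tot else 0
  structure(list(model_id = model_id,
                 lambda_selected = lambda_selected,
                 lambda_grid = grid,
                 coefficients = final$coefficients,
                 loo_predictions = loo_pred,
                 r2 = r2, r2_insample = r2_in,
                 loo_sd = sd((y - loo_pred)^2),
                 neg_mse = setNames(rev(neg_mse), grid),
                 n = n, r2_defined = r2_defined,
                 delta_vs_benchmark = NA_real_),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "<prediction_result> %s: R2(LOO)=%.3f, lambda=%.3g, %d/%d nonzero\n",
    x$model_id, x$r2, x$lambda_selected,
    sum(abs(x$coefficients[-1]) > 0), length(x$coefficients) - 1L))
  invisible(x)
}

covariate_matrix <- function(records) {
  need <- c("subject_id", "mrs", "age", "sex", "nihss")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  X <- as.matrix(records[, c("age", "sex", "nihss")])
  rownames(X) <- records$subject_id
  X
}

#' Clinical benchmark model (age, sex, admission NIHSS)
#'
#' Same Lasso/LOO machinery as the atlas models with the demographic and
#' clinical covariates as the only predictors.
#'
#' @param records data.frame with `subject_id`, `mrs`, `age`, `sex`,
#'   `nihss`.
#' @param grid lambda grid.
#' @return A `prediction_result` with `model_id = "benchmark"`.
#' @export
benchmark_model <- function(records, grid = lambda_grid()) {
  fit_lasso_loo(covariate_matrix(records), records$mrs, grid,
                model_id = "benchmark")
}

#' Atlas-plus-covariates model and its gain over the atlas alone
#'
#' Concatenates the atlas design matrix with the clinical covariates, fits
#' the same Lasso/LOO model, and reports the delta in out-of-sample
#' R-squared relative to the atlas-only model (how much the covariates add
#' to, or how much they rescue, the topographical prediction).
#'
#' @param X_atlas design matrix from [build_design_matrix()].
#' @param records outcome records matching its rownames.
#' @param grid lambda grid.
#' @param atlas_result optional precomputed atlas-only `prediction_result`
#'   (refitted here when `NULL`).
#' @param model_id label; defaults to `<atlas kind>_combined`.
#' @return A `prediction_result` with `delta_vs_benchmark` filled in.
#' @export
combined_model <- function(X_atlas, records, grid = lambda_grid(),
                           atlas_result = NULL, model_id = NULL) {
  covs <- covariate_matrix(records)
  if (!identical(sort(rownames(X_atlas)), sort(rownames(covs))))
    stop("subject mismatch between atlas features and records")
  covs <- covs[rownames(X_atlas), , drop = FALSE]
  y <- records$mrs[match(rownames(X_atlas), records$subject_id)]
  if (is.null(atlas_result))
    atlas_result <- fit_lasso_loo(X_atlas, y, grid, model_id = "atlas")
  if (is.null(model_id))
    model_id <- paste0(attr(X_atlas, "atlas_kind") %||% "atlas",
                       "_combined")
  res <- fit_lasso_loo(cbind(X_atlas, covs), y, grid, model_id = model_id)
  res$delta_vs_benchmark <- res$r2 - atlas_result$r2
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank fitted models by out-of-sample R-squared
#'
#' @param results list of `prediction_result`s.
#' @return `data.frame` sorted by `r2` descending (ties by `model_id`)
#'   with columns `model_id`, `r2`, `r2_insample`, `loo_sd`,
#'   `lambda_selected`, `n_nonzero`, `delta_vs_benchmark`.
#' @export
compare_models <- function(results) {
  if (length(results) == 0L) stop("no models to compare")
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(model_id = r$model_id, r2 = r$r2,
               r2_insample = r$r2_insample, loo_sd = r$loo_sd,
               lambda_selected = r$lambda_selected,
               n_nonzero = sum(abs(r$coefficients[-1]) > 0),
               delta_vs_benchmark = r$delta_vs_benchmark,
               stringsAsFactors = FALSE)))
  df <- df[order(-df$r2, df$model_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
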