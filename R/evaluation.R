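#' Per-site train/test split
#'
#' Randomly splits each site's rows into a training fraction kept at the
#' site and a test remainder; test rows are pooled across sites for
#' scoring (data never needs to leave a site to train, and one model is
#' scored on one test set).
#'
#' @param sites list of [sma_site()] objects.
#' @param fraction training fraction in (0, 1), default 0.7.
#' @param seed optional seed; the same seed reproduces the partition.
#' @return list with `train` (list of `sma_site`, one per site) and
#'   `test` (one pooled `sma_site`).
#' @export
train_test_split <- function(sites, fraction = 0.7, seed = NULL) {
  stopifnot(length(sites) >= 1, fraction > 0, fraction < 1,
            all(vapply(sites, inherits, logical(1), "sma_site")))
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(sites, function(s) {
    n <- nrow(s$x)
    n_train <- floor(fraction * n)
    if (n_train < 2 || n_train >= n)
      stop("site ", s$site_id, " is too small to split at fraction ",
           fraction, " (n = ", n, ")")
    idx <- sample.int(n, n_train)
    list(train = sma_site(s$x[idx, , drop = FALSE], s$y[idx],
                          feature_names = s$feature_names,
                          site_id = s$site_id),
         test_x = s$x[-idx, , drop = FALSE],
         test_y = s$y[-idx])
  })
  test <- sma_site(do.call(rbind, lapply(parts, `[[`, "test_x")),
                   unlist(lapply(parts, `[[`, "test_y")),
                   feature_names = sites[[1]]$feature_names,
                   site_id = "test_pool")
  list(train = lapply(parts, `[[`, "train"), test = test)
}

#' Score a global model on a test pool
#'
#' Mean squared prediction error and R-squared (`1 - SSE/SST`, `SST`
#' about the test-pool mean). A zero-variance test outcome makes
#' R-squared undefined; it is reported as `NA`.
#'
#' @param model an `sma_global_model`.
#' @param test an [sma_site()] (the pooled test rows).
#' @return list with `mse` and `r2`.
#' @export
score_model <- function(model, test) {
  stopifnot(inherits(model, "sma_global_model"), inherits(test, "sma_site"))
  pred <- predict(model, test)
  resid <- test$y - pred
  mse <- mean(resid^2)
  sst <- sum((test$y - mean(test$y))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(resid^2) / sst
  list(mse = mse, r2 = r2)
}

#' Centralized-over-distributed MSE ratio
#'
#' The headline accuracy metric: mean squared error of the centralized
#' baseline divided by that of the secure multiparty fit. Values near 1
#' mean the secure distributed procedure loses no accuracy.
#'
#' @param mse_ca,mse_sma positive mean squared errors.
#' @return `mse_ca / mse_sma`.
#' @examples
#' mse_ratio(3.364, 3.417)   # 0.984
#' @export
mse_ratio <- function(mse_ca, mse_sma) {
  stopifnot(is.numeric(mse_ca), is.numeric(mse_sma))
  if (any(mse_ca <= 0) || any(mse_sma <= 0))
    stop("MSE values must be strictly positive")
  mse_ca / mse_sma
}

#' Repeated train/test comparison of the centralized and secure fits
#'
#' Repeats (split at `fraction` within each site) -> (fit centralized
#' baseline on the pooled training rows; fit the multiparty algorithm on
#' the per-site training rows) -> (score both on the pooled test rows),
#' with a fresh seeded split each repetition, and reports per-repetition
#' and mean MSE and R-squared for both methods plus the MSE ratio
#' `mean MSE(central) / mean MSE(multiparty)`.
#'
#' @param sites list of `m >= 2` [sma_site()] objects.
#' @param repetitions number of repeated splits (>= 1).
#' @param fraction training fraction per site.
#' @param seed master seed; repetition `r` splits with `seed + r`.
#' @param lambda_policy,lambda,nfolds penalty policy, see [lasso_select()].
#' @param secure run the multiparty fit through the encrypted protocols
#'   (default) or their plaintext twins (statistically identical).
#' @param key Paillier keypair reused across repetitions; generated with
#'   `key_bits` when `NULL` and `secure = TRUE`.
#' @param key_bits key size for a fresh keypair.
#' @return an object of class `sma_evaluation`: `per_rep` data.frame
#'   (`rep`, `mse_central`, `mse_sma`, `r2_central`, `r2_sma`), the mean
#'   of each column, `mse_ratio`, and the run geometry (`m`, `p`, `N`,
#'   `n_i`, `repetitions`, `seed`).
#' @export
repeated_experiment <- function(sites, repetitions = 50, fraction = 0.7,
                                seed = 1, lambda_policy = "cv_min",
                                lambda = NULL, nfolds = 5, secure = TRUE,
                                key = NULL, key_bits = 512) {
  stopifnot(length(sites) >= 2, repetitions >= 1)
  if (secure && is.null(key)) key <- paillier_keygen(key_bits)
  rows <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    split <- train_test_split(sites, fraction = fraction, seed = seed + r)
    ca <- run_central(split$train, lambda_policy = lambda_policy,
                      lambda = lambda, nfolds = nfolds,
                      seed = seed + r)
    sma <- run_sma(split$train, lambda_policy = lambda_policy,
                   lambda = lambda, nfolds = nfolds, key = key,
                   secure = secure, seed = seed + r)
    sc_ca <- score_model(ca, split$test)
    sc_sma <- score_model(sma$model, split$test)
    rows[[r]] <- data.frame(rep = r, mse_central = sc_ca$mse,
                            mse_sma = sc_sma$mse, r2_central = sc_ca$r2,
                            r2_sma = sc_sma$r2)
  }
  per_rep <- do.call(rbind, rows)
  n_i <- vapply(sites, function(s) nrow(s$x), integer(1))
  structure(list(per_rep = per_rep,
                 mean_mse_central = mean(per_rep$mse_central),
                 mean_mse_sma = mean(per_rep$mse_sma),
                 mean_r2_central = mean(per_rep$r2_central),
                 mean_r2_sma = mean(per_rep$r2_sma),
                 mse_ratio = mse_ratio(mean(per_rep$mse_central),
                                       mean(per_rep$mse_sma)),
                 m = length(sites), p = ncol(sites[[1]]$x),
                 N = sum(n_i), n_i = n_i,
                 repetitions = repetitions, fraction = fraction,
                 seed = seed, secure = secure),
            class = "sma_evaluation")
}

#' @export
print.sma_evaluation <- function(x, ...) {
  cat("repeated evaluation: m =", x$m, ", p =", x$p, ", N =", x$N,
      ",", x$repetitions, "repetitions\n")
  cat(sprintf("  MSE  central %.4g | multiparty %.4g | ratio %.3f\n",
              x$mean_mse_central, x$mean_mse_sma, x$mse_ratio))
  cat(sprintf("  R2   central %.3f | multiparty %.3f\n",
              x$mean_r2_central, x$mean_r2_sma))
  invisible(x)
}
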