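test_that("lasso selection recovers a strong sparse signal and obeys the penalty limits", {
  site <- make_site(2000, c(5, 0, 0, 4, 0), sigma = 1, seed = 31)
  # one-SE rule: the parsimonious choice recovers the support exactly at
  # this signal-to-noise ratio (CV-min may admit near-zero extras, which
  # the cross-site majority vote exists to prune)
  sel <- lasso_select(site, "cv_1se", seed = 1)
  expect_identical(unname(sel$s), c(1L, 0L, 0L, 1L, 0L))
  expect_identical(unname(lasso_select(site, "fixed", lambda = 1e6)$s),
                   rep(0L, 5))
  expect_identical(unname(lasso_select(site, "fixed", lambda = 0)$s),
                   rep(1L, 5))
})

test_that("selection never grows as the penalty increases", {
  site <- make_site(500, c(3, -2, 1, 0.5, 0, 0, 0, 0), sigma = 1, seed = 32)
  lams <- c(0.01, 0.05, 0.2, 0.8, 3)
  sets <- lapply(lams, function(l) which(lasso_select(site, "fixed",
                                                      lambda = l)$s == 1))
  for (i in seq_len(length(lams) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("degenerate columns and outcomes are handled explicitly", {
  base <- make_site(300, c(2, 0, 1), sigma = 1, seed = 33)
  xc <- cbind(base$x, const = 7)
  site <- sma_site(xc, base$y, site_id = "deg")
  expect_warning(sel <- lasso_select(site, seed = 1), "constant feature")
  expect_identical(unname(sel$s[4]), 0L)
  flat <- sma_site(base$x, rep(2, 300))
  expect_warning(sel0 <- lasso_select(flat), "constant outcome")
  expect_identical(sum(sel0$s), 0L)
})

test_that("restricted OLS matches the normal-equations oracle", {
  set.seed(34)
  x <- matrix(rnorm(200 * 6), 200, 6)
  y <- drop(x %*% c(1, -2, 0, 3, 0, 0.5)) + rnorm(200)
  site <- sma_site(x, y)
  sel <- c(1, 2, 4, 6)
  fit <- ols_fit(site, sel)
  a <- cbind(1, x[, sel])
  oracle <- solve(t(a) %*% a, t(a) %*% y)
  expect_equal(unname(c(fit$intercept, fit$coefficients)), drop(oracle),
               tolerance = 1e-8)
  # exact line through the origin
  line <- sma_site(matrix(1:50, ncol = 1), 2 * (1:50))
  lf <- ols_fit(line, 1)
  expect_equal(unname(lf$coefficients), 2, tolerance = 1e-10)
  expect_equal(lf$intercept, 0, tolerance = 1e-8)
  # empty selection: intercept-only at the site mean
  ef <- ols_fit(site, integer(0))
  expect_length(ef$coefficients, 0)
  expect_equal(ef$intercept, mean(y))
})

test_that("rank-deficient restricted designs fall back to the minimum-norm fit", {
  set.seed(35)
  x1 <- rnorm(100)
  x <- cbind(x1, x1, rnorm(100))   # exact collinearity
  y <- 3 * x1 + rnorm(100, 0, 0.1)
  site <- sma_site(x, y, feature_names = c("a", "b", "c"))
  expect_warning(fit <- ols_fit(site, 1:3), "rank-deficient")
  expect_true(all(is.finite(c(fit$intercept, fit$coefficients))))
  a <- cbind(1, x)
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               drop(MASS::ginv(a) %*% y), tolerance = 1e-8)
})

test_that("the median probability model is the strict per-feature majority", {
  s1 <- c(1, 1, 0); s2 <- c(1, 0, 0); s3 <- c(1, 1, 1)
  expect_identical(median_probability_model(list(s1, s2, s3)), c(1L, 2L))
  # even m tie excluded
  expect_identical(median_probability_model(list(c(1), c(1), c(0), c(0))),
                   integer(0))
  set.seed(36)
  votes <- replicate(7, rbinom(40, 1, 0.5), simplify = FALSE)
  brute <- which(colSums(do.call(rbind, votes)) > 7 / 2)
  expect_identical(median_probability_model(votes), brute)
})

test_that("parameter averaging is the unweighted elementwise mean", {
  mk <- function(b, int = 0) structure(
    list(coefficients = b, intercept = int, selected = seq_along(b),
         site_id = "x"), class = "sma_local_model")
  avg <- average_parameters(list(mk(c(1, 3)), mk(c(3, 1))))
  expect_equal(unname(avg$coefficients), c(2, 2))
  same <- average_parameters(rep(list(mk(c(2.5, -1), 4)), 3))
  expect_equal(unname(same$coefficients), c(2.5, -1))
  expect_equal(same$intercept, 4)
  set.seed(37)
  models <- replicate(5, mk(rnorm(4), rnorm(1)), simplify = FALSE)
  avg5 <- average_parameters(models)
  expect_equal(unname(avg5$coefficients),
               colMeans(do.call(rbind, lapply(models, `[[`, "coefficients"))))
  bad <- mk(c(1, 2)); bad$selected <- c(2, 3)
  expect_error(average_parameters(list(mk(c(1, 2)), bad)), "disagree")
  # weighted variant
  w <- average_parameters(list(mk(c(0, 0)), mk(c(4, 4))), weights = c(1, 3))
  expect_equal(unname(w$coefficients), c(3, 3))
})

test_that("sample-size advisory conditions reproduce the threshold logic", {
  ok <- check_dsc_conditions(N = 1e6, n_i = rep(5e4, 20), p = 10, m = 20)
  expect_true(all(ok$pass))
  bad <- check_dsc_conditions(N = 100, n_i = rep(2, 50), p = 50, m = 50)
  expect_false(bad$pass[bad$condition == "n_min > p"])
  # m <= sqrt(N) boundary is exact in integer arithmetic
  N <- 1e6; mb <- floor(sqrt(N))
  at <- check_dsc_conditions(N, rep(N / mb, mb), p = 2, m = mb)
  expect_true(at$pass[at$condition == "m <= sqrt(N)"])
  over <- check_dsc_conditions(N, c(rep(999, 1000), 1000), p = 2, m = mb + 1)
  expect_false(over$pass[over$condition == "m <= sqrt(N)"])
  # p < log(N) uses the natural logarithm
  lg <- check_dsc_conditions(N = 1e6, n_i = rep(1e5, 10), p = 13, m = 10)
  expect_true(lg$pass[lg$condition == "p < log(N)"])
  lg2 <- check_dsc_conditions(N = 1e6, n_i = rep(1e5, 10), p = 14, m = 10)
  expect_false(lg2$pass[lg2$condition == "p < log(N)"])
})
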