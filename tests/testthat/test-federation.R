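test_that("two identical noiseless sites recover the generating line", {
  set.seed(51)
  x <- matrix(rnorm(200 * 2), 200, 2)
  y <- 2 * x[, 1]
  sites <- list(sma_site(x, y, site_id = "a"), sma_site(x, y, site_id = "b"))
  run <- run_sma(sites, lambda_policy = "fixed", lambda = 0.05, key = tkey)
  expect_identical(run$model$selected, 1L)
  expect_equal(unname(run$model$coefficients), 2, tolerance = 1e-6)
  expect_equal(run$model$intercept, 0, tolerance = 1e-6)
})

test_that("the secure run equals the plaintext split-and-merge pipeline", {
  syn <- generate_sites(N = 1200, p = 6, m = 3, beta = c(5, 0, -3, 0, 2, 0),
                        sigma = 1, seed = 52)
  sec <- run_sma(syn$sites, key = tkey, seed = 7)
  pln <- run_sma(syn$sites, secure = FALSE, seed = 7)
  expect_identical(sec$model$selected, pln$model$selected)
  expect_equal(sec$model$coefficients, pln$model$coefficients,
               tolerance = 1e-9)
  expect_equal(sec$model$intercept, pln$model$intercept, tolerance = 1e-9)
  # and the plaintext pipeline is what its parts say it is
  sels <- lapply(seq_along(syn$sites), function(i)
    lasso_select(syn$sites[[i]], seed = 7 + i))
  s_idx <- median_probability_model(sels)
  expect_identical(pln$model$selected, s_idx)
  avg <- average_parameters(lapply(syn$sites, ols_fit, selected = s_idx))
  expect_equal(unname(pln$model$coefficients), unname(avg$coefficients),
               tolerance = 1e-12)
})

test_that("a fixed seed makes repeated runs identical", {
  syn <- generate_sites(N = 800, p = 5, m = 4, sigma = 1, seed = 53)
  r1 <- run_sma(syn$sites, key = tkey, seed = 3)
  r2 <- run_sma(syn$sites, key = tkey, seed = 3)
  expect_identical(r1$model$selected, r2$model$selected)
  expect_equal(r1$model$coefficients, r2$model$coefficients,
               tolerance = 1e-12)
})

test_that("schema mismatch aborts before any message is sent", {
  syn <- generate_sites(N = 400, p = 3, m = 2, sigma = 1, seed = 54)
  odd <- syn$sites[[2]]
  odd$feature_names <- c("u", "v", "w")
  colnames(odd$x) <- odd$feature_names
  expect_error(run_sma(list(syn$sites[[1]], odd), key = tkey),
               "schema mismatch before any message")
  expect_error(run_sma(syn$sites[1], key = tkey), "at least 2")
})

test_that("each phase costs one submission per party plus one aggregate and one result", {
  syn <- generate_sites(N = 600, p = 4, m = 3, sigma = 1, seed = 55)
  run <- run_sma(syn$sites, key = tkey, seed = 1)
  for (tr in list(run$selection_transcript, run$average_transcript)) {
    types <- vapply(tr$messages, `[[`, character(1), "type")
    expect_identical(sum(types == "SUBMIT"), 3L)
    expect_identical(sum(types == "AGGREGATE"), 1L)
    expect_identical(sum(types == "RESULT"), 1L)
  }
  # publication minimality: the only plaintext payloads are the final
  # RESULT and the HELLO dimension announcements
  all_msgs <- c(run$selection_transcript$messages,
                run$average_transcript$messages)
  plain <- Filter(function(m) m$payload_kind == "plaintext", all_msgs)
  expect_true(all(vapply(plain, `[[`, character(1), "type") %in%
                    c("HELLO", "RESULT")))
})

test_that("an empty global selection publishes the averaged intercept-only model", {
  syn <- generate_sites(N = 400, p = 3, m = 2, sigma = 1, seed = 56)
  expect_warning(
    run <- run_sma(syn$sites, lambda_policy = "fixed", lambda = 1e9,
                   key = tkey),
    "intercept-only")
  expect_length(run$model$coefficients, 0)
  expect_equal(run$model$intercept,
               mean(vapply(syn$sites, function(s) mean(s$y), numeric(1))),
               tolerance = 1e-9)
})

test_that("a single site makes the central baseline the plain local pipeline", {
  site <- make_site(500, c(3, 0, -1), sigma = 1, seed = 57)
  ca <- run_central(list(site), seed = 2)
  sel <- lasso_select(site, seed = 2)
  fit <- ols_fit(site, which(sel$s == 1))
  expect_identical(ca$selected, fit$selected)
  expect_equal(ca$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_identical(ca$m, 1L)
})

test_that("global models serialize, restore and predict consistently", {
  syn <- generate_sites(N = 600, p = 4, m = 2, beta = c(2, 0, -1, 0),
                        sigma = 0.5, seed = 58)
  run <- run_sma(syn$sites, secure = FALSE, seed = 1)
  json <- write_global_model(run$model)
  back <- read_global_model(json)
  expect_identical(back$selected, run$model$selected)
  expect_equal(back$coefficients, run$model$coefficients)
  newx <- syn$sites[[1]]$x[1:5, , drop = FALSE]
  expect_equal(predict(back, newx), predict(run$model, newx))
  f <- tempfile(fileext = ".json")
  write_global_model(run$model, f)
  expect_equal(read_global_model(f)$intercept, run$model$intercept)
  unlink(f)
})
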