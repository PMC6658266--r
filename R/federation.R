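#' Run the secure multiparty linear regression (SMA) across sites
#'
#' Executes the two-phase split-and-merge fit over `m >= 2` data-holding
#' sites with secure aggregation at both merge points:
#'
#' 1. **Selection phase.** Every site runs the lasso on its own rows and
#'    submits its binary selection vector to [secure_median_binary()];
#'    the strict-majority (median probability model) feature set `S` is
#'    the only published selection output and is broadcast to all sites
#'    in canonical (ascending feature index) order.
#' 2. **Averaging phase.** Every site fits ordinary least squares on its
#'    rows restricted to `S` and submits `(intercept, beta_S)` to
#'    [secure_average()]; the published global model is the unweighted
#'    mean of the local fits.
#'
#' Only `S` and the averaged parameters are ever disclosed; individual
#' selections and local coefficients travel as Paillier ciphertexts. Both
#' phase transcripts are retained for audit. `secure = FALSE` swaps in
#' the plaintext twins ([median_probability_model()] and a plain mean) —
#' the statistics are identical to fixed-point precision; only the
#' privacy mechanism is bypassed.
#'
#' @param sites list of `m >= 2` [sma_site()] objects sharing one schema.
#' @param lambda_policy,lambda,nfolds per-site penalty policy, see
#'   [lasso_select()].
#' @param key Paillier keypair from [paillier_keygen()]; generated with
#'   `key_bits` when `NULL` and `secure = TRUE`.
#' @param key_bits key size for a fresh keypair (2048 recommended; 512 in
#'   simulations).
#' @param secure use the encrypted protocols (`TRUE`, default) or their
#'   plaintext twins.
#' @param roles optional [protocol_roles()] assignment.
#' @param seed optional master seed: seeds site `i`'s CV fold assignment
#'   with `seed + i` and (under `rng = "r"`) the encryption randomness,
#'   making the run exactly reproducible.
#' @param rng encryption randomness source, see [encrypt_real()].
#' @param weights optional per-site averaging weights (default: simple
#'   unweighted averaging).
#' @return an object of class `sma_run`: `model` (the
#'   `sma_global_model`), `selections` (per-site binary vectors — local
#'   bookkeeping, never transmitted in the clear), `conditions`
#'   (advisory [check_dsc_conditions()] report), and when `secure`, the
#'   `selection_transcript` and `average_transcript`.
#' @examples
#' syn <- generate_sites(N = 400, p = 4, m = 2, beta = c(2, 0, 0, 0),
#'                       sigma = 0, seed = 1)
#' run <- run_sma(syn$sites, lambda_policy = "fixed", lambda = 0.05,
#'                key_bits = 512, seed = 1)
#' run$model$coefficients   # ~2 on x1
#' @export
run_sma <- function(sites, lambda_policy = "cv_min", lambda = NULL,
                    nfolds = 5, key = NULL, key_bits = 2048, secure = TRUE,
                    roles = NULL, seed = NULL, rng = c("system", "r"),
                    weights = NULL) {
  rng <- match.arg(rng)
  m <- length(sites)
  if (m < 2) stop("the multiparty algorithm needs at least 2 sites")
  .check_schema(sites)   # pre-flight, before any ciphertext is produced
  p <- ncol(sites[[1]]$x)
  if (is.null(roles)) {
    roles <- protocol_roles(m, party_ids = vapply(sites, `[[`, character(1),
                                                  "site_id"))
  }
  if (secure && is.null(key)) key <- paillier_keygen(key_bits)

  # phase 1: local lasso -> secure strict-majority vote
  selections <- lapply(seq_len(m), function(i) {
    lasso_select(sites[[i]], lambda_policy = lambda_policy, lambda = lambda,
                 nfolds = nfolds,
                 seed = if (is.null(seed)) NULL else seed + i)
  })
  votes <- lapply(selections, `[[`, "s")
  if (secure) {
    med <- tryCatch(
      secure_median_binary(votes, key = key, roles = roles, rng = rng),
      error = function(e) stop("selection phase failed: ",
                               conditionMessage(e), call. = FALSE))
    s_idx <- which(med$result == 1L)
    sel_transcript <- med$transcript
  } else {
    s_idx <- median_probability_model(votes)
    sel_transcript <- NULL
  }
  s_idx <- sort(s_idx)   # canonical ordering broadcast with S

  if (length(s_idx) == 0L)
    warning("empty global selection: publishing an intercept-only model ",
            "(average of site means)")

  if (secure && !is.null(weights))
    stop("weighted averaging is only available with secure = FALSE ",
         "(the secure protocol publishes the unweighted mean)")

  # phase 2: local OLS on the shared set -> secure averaging of
  # (intercept, beta_S) in canonical order
  locals <- lapply(sites, ols_fit, selected = s_idx)
  vectors <- lapply(locals, function(mod) c(mod$intercept, mod$coefficients))
  if (secure) {
    avg <- tryCatch(
      secure_average(vectors, key = key, roles = roles, rng = rng),
      error = function(e) stop("averaging phase failed: ",
                               conditionMessage(e), call. = FALSE))
    mean_vec <- avg$result
    avg_transcript <- avg$transcript
  } else {
    w <- if (is.null(weights)) rep(1 / m, m) else weights / sum(weights)
    mean_vec <- Reduce(`+`, Map(`*`, vectors, w))
    avg_transcript <- NULL
  }
  fn <- sites[[1]]$feature_names[s_idx]
  coefs <- unname(mean_vec[-1])
  names(coefs) <- fn
  model <- structure(list(selected = s_idx, coefficients = coefs,
                          intercept = unname(mean_vec[1]), feature_names = fn,
                          m = m),
                     class = "sma_global_model")
  n_i <- vapply(sites, function(s) nrow(s$x), integer(1))
  structure(list(model = model,
                 selections = votes,
                 conditions = check_dsc_conditions(sum(n_i), n_i, p, m),
                 selection_transcript = sel_transcript,
                 average_transcript = avg_transcript,
                 secure = secure, seed = seed,
                 lambda_policy = lambda_policy),
            class = "sma_run")
}

#' @export
print.sma_run <- function(x, ...) {
  cat(if (x$secure) "secure" else "plaintext",
      "multiparty regression run over", x$model$m, "sites\n")
  print(x$model)
  if (!all(x$conditions$pass))
    cat("note:", sum(!x$conditions$pass), "advisory condition(s) failed;",
        "see $conditions\n")
  invisible(x)
}

#' Centralized baseline run
#'
#' Pools all sites' rows and runs the same selection-then-refit pipeline
#' on one machine ([central_fit()]). No privacy: exists purely as the
#' evaluation baseline.
#'
#' @inheritParams run_sma
#' @return an `sma_global_model` (with `m = 1`).
#' @export
run_central <- function(sites, lambda_policy = "cv_min", lambda = NULL,
                        nfolds = 5, seed = NULL) {
  if (length(sites) > 1) .check_schema(sites)
  central_fit(pool_sites(sites), lambda_policy = lambda_policy,
              lambda = lambda, nfolds = nfolds, seed = seed)
}

.check_schema <- function(sites) {
  stopifnot(length(sites) >= 1,
            all(vapply(sites, inherits, logical(1), "sma_site")))
  fn <- sites[[1]]$feature_names
  same <- vapply(sites, function(s) identical(s$feature_names, fn), logical(1))
  if (!all(same))
    stop("schema mismatch before any message was sent: sites ",
         paste(vapply(sites[!same], `[[`, character(1), "site_id"),
               collapse = ", "),
         " do not match the shared feature schema")
  invisible(TRUE)
}

#' Predict from a global model
#'
#' @param object an `sma_global_model`.
#' @param newdata numeric matrix with the full original feature columns
#'   (the model restricts to its selected set), or an [sma_site()].
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.sma_global_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "sma_site")) newdata$x else as.matrix(newdata)
  if (length(object$selected) == 0L) return(rep(object$intercept, nrow(x)))
  drop(object$intercept + x[, object$selected, drop = FALSE] %*%
         object$coefficients)
}

#' Serialize / restore a global model as a structured text record
#'
#' Stable JSON form `{feature_names, selected, coefficients, intercept,
#' m}` for exchange and audit between parties.
#'
#' @param model an `sma_global_model`.
#' @param path file path; when `NULL`, the JSON string is returned.
#' @return `write_global_model`: the path (or JSON string), invisibly.
#'   `read_global_model`: the restored `sma_global_model`.
#' @export
write_global_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "sma_global_model"))
  rec <- list(feature_names = model$feature_names,
              selected = model$selected,
              coefficients = unname(model$coefficients),
              intercept = model$intercept,
              m = model$m)
  if (is.null(path)) {
    return(invisible(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)))
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_global_model
#' @param input path or JSON string produced by [write_global_model()].
#' @export
read_global_model <- function(input) {
  rec <- jsonlite::fromJSON(input)
  coefs <- as.numeric(rec$coefficients)
  names(coefs) <- rec$feature_names
  structure(list(selected = as.integer(rec$selected), coefficients = coefs,
                 intercept = rec$intercept,
                 feature_names = as.character(rec$feature_names),
                 m = as.integer(rec$m)),
            class = "sma_global_model")
}
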