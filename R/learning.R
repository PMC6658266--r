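#' One site's dataset
#'
#' Container for a single data holder's rows of the shared schema: an
#' `n_i x p` numeric feature matrix and the length-`n_i` numeric outcome.
#'
#' @param x numeric feature matrix (rows = records).
#' @param y numeric outcome vector.
#' @param feature_names optional column names (taken from `x` if present).
#' @param site_id identifier of the data holder.
#' @return an object of class `sma_site`.
#' @export
sma_site <- function(x, y, feature_names = colnames(x), site_id = "site1") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2)
  if (anyNA(x) || anyNA(y)) stop("missing values in site ", site_id)
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(x)))
  colnames(x) <- feature_names
  structure(list(x = x, y = y, feature_names = feature_names,
                 site_id = site_id),
            class = "sma_site")
}

#' @export
print.sma_site <- function(x, ...) {
  cat("site", x$site_id, ":", nrow(x$x), "records,", ncol(x$x), "features\n")
  invisible(x)
}

#' Read one site's CSV file
#'
#' Generic ingest for per-site data: a headered CSV with one numeric
#' outcome column and numeric feature columns.
#'
#' @param path CSV file path.
#' @param outcome_col name of the outcome column.
#' @param site_id site identifier (defaults to the file name).
#' @return an [sma_site()].
#' @export
read_site_csv <- function(path, outcome_col = "y",
                          site_id = tools::file_path_sans_ext(basename(path))) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!outcome_col %in% names(df))
    stop("outcome column '", outcome_col, "' not found in ", path)
  y <- df[[outcome_col]]
  x <- as.matrix(df[setdiff(names(df), outcome_col)])
  sma_site(x, y, site_id = site_id)
}

#' Local lasso feature selection
#'
#' Fits the lasso on one site's data and returns the binary selection
#' vector (1 = nonzero coefficient at the policy-chosen penalty).
#' Features are standardized internally (within the site) by glmnet and
#' coefficients reported on the original scale; the intercept is never
#' penalized and never part of the vote.
#'
#' @param site an [sma_site()].
#' @param lambda_policy `"cv_min"` (5-fold CV, penalty minimizing CV MSE;
#'   the default), `"cv_1se"` (largest penalty within one standard error
#'   of the minimum), or `"fixed"` (use `lambda` as given).
#' @param lambda penalty value for the `"fixed"` policy.
#' @param nfolds CV folds for the CV policies.
#' @param nlambda length of the candidate penalty path (50 resolves the
#'   CV optimum to well under the fold-to-fold noise at a fraction of the
#'   default path's cost).
#' @param seed optional seed for the CV fold assignment (restores the
#'   caller's RNG state afterwards).
#' @return an object of class `sma_selection`: binary vector `s` (length
#'   `p`, named), the `lambda` used, `policy` and `site_id`.
#' @export
lasso_select <- function(site, lambda_policy = c("cv_min", "cv_1se", "fixed"),
                         lambda = NULL, nfolds = 5, nlambda = 50,
                         seed = NULL) {
  stopifnot(inherits(site, "sma_site"))
  lambda_policy <- match.arg(lambda_policy)
  p <- ncol(site$x)
  s <- integer(p)
  names(s) <- site$feature_names
  const_cols <- apply(site$x, 2, function(v) max(v) == min(v))
  if (any(const_cols))
    warning("constant feature column(s) at site ", site$site_id, ": ",
            paste(site$feature_names[const_cols], collapse = ", "),
            " (selection forced to 0)")
  if (max(site$y) == min(site$y)) {
    warning("constant outcome at site ", site$site_id, ": empty selection")
    return(structure(list(s = s, lambda = Inf, policy = lambda_policy,
                          site_id = site$site_id), class = "sma_selection"))
  }
  if (lambda_policy == "fixed") {
    stopifnot(is.numeric(lambda), lambda >= 0)
    fit <- glmnet::glmnet(site$x, site$y, lambda = lambda,
                          standardize = TRUE, intercept = TRUE)
    beta <- as.numeric(fit$beta[, 1])
    lam <- lambda
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    cv <- glmnet::cv.glmnet(site$x, site$y, nfolds = nfolds,
                            nlambda = nlambda, standardize = TRUE,
                            intercept = TRUE)
    lam <- if (lambda_policy == "cv_min") cv$lambda.min else cv$lambda.1se
    beta <- as.numeric(stats::coef(cv, s = lam))[-1]
  }
  s[beta != 0] <- 1L
  s[const_cols] <- 0L
  structure(list(s = s, lambda = lam, policy = lambda_policy,
                 site_id = site$site_id), class = "sma_selection")
}

#' @export
print.sma_selection <- function(x, ...) {
  cat("selection at", x$site_id, "(", x$policy, ", lambda =",
      format(x$lambda, digits = 4), "):",
      sum(x$s), "of", length(x$s), "features\n")
  invisible(x)
}

#' Local ordinary least squares on an agreed feature subset
#'
#' Minimizes the residual sum of squares of `y ~ intercept + X[, selected]`
#' on one site's data. Coefficients are on the original feature scale. An
#' empty subset yields the intercept-only model (site mean). A
#' rank-deficient restricted design falls back to the minimum-norm
#' solution via the Moore-Penrose pseudoinverse, with a warning.
#'
#' @param site an [sma_site()].
#' @param selected integer indices of the agreed feature set (possibly
#'   empty), in canonical (ascending) order.
#' @return an object of class `sma_local_model`: `coefficients` (named,
#'   length `|selected|`), `intercept`, `selected`, `site_id`.
#' @export
ols_fit <- function(site, selected = integer(0)) {
  stopifnot(inherits(site, "sma_site"))
  selected <- sort(as.integer(selected))
  if (length(selected) == 0L) {
    return(structure(list(coefficients = numeric(0), intercept = mean(site$y),
                          selected = selected, site_id = site$site_id),
                     class = "sma_local_model"))
  }
  stopifnot(all(selected >= 1), all(selected <= ncol(site$x)))
  a <- cbind(`(Intercept)` = 1, site$x[, selected, drop = FALSE])
  fit <- stats::lm.fit(a, site$y)
  if (fit$rank < ncol(a)) {
    warning("rank-deficient restricted design at site ", site$site_id,
            "; using the minimum-norm (pseudoinverse) solution")
    coefs <- as.numeric(MASS::ginv(a) %*% site$y)
  } else {
    coefs <- fit$coefficients
  }
  beta <- coefs[-1]
  names(beta) <- site$feature_names[selected]
  structure(list(coefficients = beta, intercept = unname(coefs[1]),
                 selected = selected, site_id = site$site_id),
            class = "sma_local_model")
}

#' Median probability model: plaintext majority vote over selections
#'
#' The plaintext twin of [secure_median_binary()], used by the
#' centralized-style baselines and tests: a feature enters the global set
#' iff strictly more than `m/2` sites selected it (even-`m` ties are
#' excluded).
#'
#' @param selections list of `m >= 2` `sma_selection` objects or binary
#'   vectors of equal length.
#' @return integer vector of selected feature indices.
#' @export
median_probability_model <- function(selections) {
  votes <- lapply(selections, function(s) {
    v <- if (inherits(s, "sma_selection")) s$s else s
    stopifnot(all(v %in% c(0, 1)))
    as.integer(v)
  })
  stopifnot(length(votes) >= 2,
            length(unique(vapply(votes, length, integer(1)))) == 1L)
  counts <- Reduce(`+`, votes)
  which(counts > length(votes) / 2)
}

#' Average local models into the global model
#'
#' Unweighted elementwise mean of the sites' coefficient vectors and
#' intercepts (simple averaging, regardless of per-site sample sizes;
#' set `weights` to per-site record counts for a weighted variant).
#'
#' @param models list of `m >= 2` [ols_fit()] results sharing the same
#'   `selected` set.
#' @param weights optional non-negative per-site weights (default equal).
#' @return an object of class `sma_global_model`.
#' @export
average_parameters <- function(models, weights = NULL) {
  stopifnot(length(models) >= 2,
            all(vapply(models, inherits, logical(1), "sma_local_model")))
  sel <- lapply(models, `[[`, "selected")
  if (!all(vapply(sel, identical, logical(1), sel[[1]])))
    stop("local models disagree on the selected feature set")
  m <- length(models)
  w <- if (is.null(weights)) rep(1 / m, m) else {
    stopifnot(length(weights) == m, all(weights >= 0), sum(weights) > 0)
    weights / sum(weights)
  }
  coefs <- Reduce(`+`, Map(function(mod, wi) wi * mod$coefficients, models, w))
  intercept <- sum(vapply(models, `[[`, numeric(1), "intercept") * w)
  structure(list(selected = sel[[1]],
                 coefficients = coefs,
                 intercept = intercept,
                 feature_names = names(models[[1]]$coefficients),
                 m = m),
            class = "sma_global_model")
}

#' @export
print.sma_global_model <- function(x, ...) {
  cat("global linear model from", x$m, "site(s);",
      length(x$selected), "selected feature(s)\n")
  cat("intercept:", format(x$intercept, digits = 6), "\n")
  if (length(x$coefficients)) print(round(x$coefficients, 6))
  invisible(x)
}

#' Centralized baseline: pooled lasso selection + OLS
#'
#' The non-private reference: the same selection-then-refit approach run
#' on the pooled rows of all sites on one machine.
#'
#' @param site an [sma_site()] holding the pooled data (see
#'   [pool_sites()]).
#' @inheritParams lasso_select
#' @return an `sma_global_model` with `m = 1`.
#' @export
central_fit <- function(site, lambda_policy = "cv_min", lambda = NULL,
                        nfolds = 5, seed = NULL) {
  sel <- lasso_select(site, lambda_policy = lambda_policy, lambda = lambda,
                      nfolds = nfolds, seed = seed)
  s_idx <- which(sel$s == 1L)
  fit <- ols_fit(site, s_idx)
  structure(list(selected = fit$selected,
                 coefficients = fit$coefficients,
                 intercept = fit$intercept,
                 feature_names = names(fit$coefficients),
                 m = 1L),
            class = "sma_global_model")
}

#' Pool several sites' rows into one dataset
#'
#' Row-concatenation of sites sharing the same schema (the centralized
#' baseline's input; defeats the privacy purpose and exists only for
#' evaluation).
#'
#' @param sites list of [sma_site()] objects with identical feature names.
#' @return a pooled `sma_site`.
#' @export
pool_sites <- function(sites) {
  stopifnot(length(sites) >= 1,
            all(vapply(sites, inherits, logical(1), "sma_site")))
  fn <- sites[[1]]$feature_names
  if (!all(vapply(sites, function(s) identical(s$feature_names, fn), logical(1))))
    stop("sites do not share an identical feature schema")
  sma_site(do.call(rbind, lapply(sites, `[[`, "x")),
           unlist(lapply(sites, `[[`, "y")),
           feature_names = fn, site_id = "pooled")
}

#' Advisory sample-size conditions for split-and-merge estimation
#'
#' Distributed averaging is as accurate as the centralized fit when each
#' site holds many records relative to the number of features and the
#' number of sites. This check reports, without ever aborting:
#' `n_min > p`, `n_min > m`, `m <= sqrt(N)`, and the linear-model
#' condition `p < log N` together with `m <= N*p / (log N)^2` (natural
#' logarithm).
#'
#' @param N total number of records across sites.
#' @param n_i integer vector of per-site record counts (must sum to `N`).
#' @param p number of features.
#' @param m number of sites (defaults to `length(n_i)`).
#' @return a data.frame of class `sma_conditions` with columns
#'   `condition`, `detail` and `pass`; failures are advisory warnings.
#' @examples
#' check_dsc_conditions(N = 1e6, n_i = rep(5e4, 20), p = 10, m = 20)
#' @export
check_dsc_conditions <- function(N, n_i, p, m = length(n_i)) {
  stopifnot(N >= 1, p >= 1, m >= 1, length(n_i) == m, all(n_i >= 1),
            sum(n_i) == N)
  n_min <- min(n_i)
  logN <- log(N)
  checks <- data.frame(
    condition = c("n_min > p", "n_min > m", "m <= sqrt(N)",
                  "p < log(N)", "m <= N*p/(log N)^2"),
    detail = c(sprintf("n_min = %d, p = %d", n_min, p),
               sprintf("n_min = %d, m = %d", n_min, m),
               sprintf("m = %d, sqrt(N) = %.2f", m, sqrt(N)),
               sprintf("p = %d, log(N) = %.3f", p, logN),
               sprintf("m = %d, N*p/(log N)^2 = %.1f", m, N * p / logN^2)),
    # m <= sqrt(N) tested in integer arithmetic to keep the boundary exact
    pass = c(n_min > p, n_min > m, m^2 <= N, p < logN, m <= N * p / logN^2),
    stringsAsFactors = FALSE)
  class(checks) <- c("sma_conditions", "data.frame")
  checks
}

#' @export
print.sma_conditions <- function(x, ...) {
  cat("split-and-merge advisory conditions:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-20s (%s)\n", if (x$pass[i]) "ok" else "WARN",
                x$condition[i], x$detail[i]))
  invisible(x)
}
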