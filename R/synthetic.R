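#' Generate horizontally partitioned linear-regression data
#'
#' Draws `N` i.i.d. records from one linear model `Y = X beta + eps`,
#' `eps ~ Normal(0, sigma^2)`, and assigns the rows to `m` sites so that
#' every stage of the distributed pipeline is testable without external
#' data. The default configuration matches the assumption the theory
#' rests on: identically distributed records divided equally between the
#' sites. A per-site mean-shift knob (`delta`) deliberately violates that
#' assumption for robustness experiments; it is off by default.
#'
#' @param N total number of records.
#' @param p number of features.
#' @param m number of sites.
#' @param k number of informative (nonzero-coefficient) features; ignored
#'   when `beta` is given. Default `max(1, floor(p/3))`.
#' @param beta optional length-`p` true coefficient vector (zeros outside
#'   the informative set). When `NULL`, `k` informative positions are
#'   sampled and their coefficients drawn uniform on `[-10, 10]`.
#' @param sigma noise standard deviation (same units as the outcome).
#' @param rho equicorrelation of the features (`0` = identity covariance).
#' @param split `"equal"` (rows divided equally, remainder spread over the
#'   first sites) or `"counts"` (use `n_i`).
#' @param n_i per-site record counts for `split = "counts"`; must sum to `N`.
#' @param delta per-site feature mean shift: site `i`'s features are
#'   shifted by `(i-1) * delta` (0 keeps sites identically distributed).
#' @param intercept true intercept of the generating model.
#' @param seed optional RNG seed; the same seed reproduces the data
#'   exactly.
#' @return an object of class `sma_synth`: list with `sites` (list of
#'   [sma_site()]), and `truth` (true `beta`, `informative` indices,
#'   `intercept`, `sigma` and the generator settings).
#' @examples
#' syn <- generate_sites(N = 1000, p = 5, m = 4, beta = c(5, 0, 0, 4, 0),
#'                       sigma = 1, seed = 1)
#' length(syn$sites)           # 4 sites of 250 rows each
#' syn$truth$informative       # 1 4
#' @export
generate_sites <- function(N, p, m, k = max(1, floor(p / 3)), beta = NULL,
                           sigma = 1, rho = 0,
                           split = c("equal", "counts"), n_i = NULL,
                           delta = 0, intercept = 0, seed = NULL) {
  split <- match.arg(split)
  stopifnot(N >= 2 * m, p >= 1, m >= 1, sigma >= 0, rho >= 0, rho < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(beta)) {
    stopifnot(k >= 1, k <= p)
    informative <- sort(sample.int(p, k))
    beta <- numeric(p)
    beta[informative] <- stats::runif(k, -10, 10)
  } else {
    stopifnot(length(beta) == p)
    informative <- which(beta != 0)
  }
  counts <- if (split == "equal") {
    base_n <- as.integer(N %/% m)
    cnt <- rep(base_n, m)
    extra <- as.integer(N - as.numeric(base_n) * m)
    if (extra > 0) cnt[seq_len(extra)] <- cnt[seq_len(extra)] + 1L
    cnt
  } else {
    if (is.null(n_i) || length(n_i) != m || sum(n_i) != N)
      stop("n_i must be a length-m vector of counts summing to N")
    as.integer(n_i)
  }
  x <- matrix(stats::rnorm(N * p), N, p)
  if (rho > 0) {
    # equicorrelated(rho): shared factor + idiosyncratic part
    z <- stats::rnorm(N)
    x <- sqrt(rho) * z + sqrt(1 - rho) * x
  }
  colnames(x) <- paste0("x", seq_len(p))
  site_of <- rep(seq_len(m), counts)
  if (delta != 0) x <- x + (site_of - 1) * delta
  y <- intercept + drop(x %*% beta) + stats::rnorm(N, 0, sigma)
  sites <- lapply(seq_len(m), function(i) {
    idx <- which(site_of == i)
    sma_site(x[idx, , drop = FALSE], y[idx], site_id = paste0("site", i))
  })
  structure(list(sites = sites,
                 truth = list(beta = beta, informative = informative,
                              intercept = intercept, sigma = sigma,
                              rho = rho, delta = delta, N = N, p = p, m = m,
                              n_i = counts, seed = seed)),
            class = "sma_synth")
}

#' @export
print.sma_synth <- function(x, ...) {
  cat("synthetic partitioned regression data: N =", x$truth$N,
      ", p =", x$truth$p, ", m =", x$truth$m, "\n")
  cat("per-site n:", x$truth$n_i, "\n")
  cat("informative features:", x$truth$informative, "\n")
  invisible(x)
}

#' Partition an existing dataset into sites
#'
#' Splits one dataset's rows into `m` disjoint sites, either by explicit
#' per-site counts (rows assigned in order: the first `n_1` rows to site
#' 1, and so on, preserving row order within sites) or by a site-id
#' column/vector.
#'
#' @param site an [sma_site()] (or anything [sma_site()] accepts via
#'   `x`/`y`).
#' @param counts integer per-site row counts summing to `nrow`.
#' @param site_id_by vector of per-row site labels (alternative to
#'   `counts`).
#' @return list of [sma_site()] objects.
#' @examples
#' # the two-school split of a 649-record dataset
#' syn <- generate_sites(N = 649, p = 3, m = 1, sigma = 1, seed = 1)
#' parts <- split_existing(syn$sites[[1]], counts = c(423, 226))
#' vapply(parts, function(s) nrow(s$x), integer(1))   # 423 226
#' @export
split_existing <- function(site, counts = NULL, site_id_by = NULL) {
  stopifnot(inherits(site, "sma_site"))
  n <- nrow(site$x)
  if (!is.null(counts)) {
    counts <- as.integer(counts)
    if (any(counts < 1) || sum(counts) != n)
      stop("counts must be positive and sum to the number of rows (", n, ")")
    site_of <- rep(seq_along(counts), counts)
    labels <- paste0("site", seq_along(counts))
  } else if (!is.null(site_id_by)) {
    stopifnot(length(site_id_by) == n)
    labels <- unique(as.character(site_id_by))
    site_of <- match(as.character(site_id_by), labels)
  } else {
    stop("supply either counts or site_id_by")
  }
  lapply(seq_along(labels), function(i) {
    idx <- which(site_of == i)
    sma_site(site$x[idx, , drop = FALSE], site$y[idx],
             feature_names = site$feature_names, site_id = labels[i])
  })
}

#' Write per-site CSV files plus a truth record
#'
#' Materializes a generated dataset as one headered CSV per site
#' (`site<i>.csv`, outcome column `y`) and `truth.json` echoing the true
#' coefficients, informative set and generator settings.
#'
#' @param synth an [generate_sites()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_sites <- function(synth, dir) {
  stopifnot(inherits(synth, "sma_synth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(synth$sites, function(s) {
    path <- file.path(dir, paste0(s$site_id, ".csv"))
    utils::write.csv(data.frame(y = s$y, s$x, check.names = FALSE),
                     path, row.names = FALSE)
    path
  }, character(1))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(synth$truth, truth_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, truth_path))
}
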