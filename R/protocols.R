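#' Role assignment for a secure aggregation run
#'
#' The protocols use a star topology with three roles: `m` data parties
#' encrypt their inputs and send ciphertexts to a single aggregator; the
#' aggregator combines them homomorphically and forwards one aggregate
#' ciphertext per component to a single key authority, which holds the
#' private key, decrypts only the aggregate and publishes the result.
#' The key authority never sees an individual party's ciphertext, and the
#' aggregator never holds the private key, so under a semi-honest
#' (honest-but-curious, non-colluding) adversary model no party learns
#' another party's input beyond the published aggregate.
#'
#' The aggregator may be one of the data parties or a separate third
#' party; that is configuration, not code.
#'
#' @param m number of data parties (>= 2).
#' @param party_ids optional character ids for the data parties.
#' @param aggregator id of the aggregator (default a separate third party).
#' @param key_authority id of the key authority.
#' @return an object of class `sma_roles`.
#' @export
protocol_roles <- function(m, party_ids = paste0("site", seq_len(m)),
                           aggregator = "aggregator",
                           key_authority = "key_authority") {
  stopifnot(m >= 2, length(party_ids) == m, !anyDuplicated(party_ids),
            length(aggregator) == 1L, length(key_authority) == 1L)
  if (aggregator == key_authority)
    stop("aggregator and key authority must be distinct parties")
  if (key_authority %in% party_ids)
    stop("the key authority must not be a data party (it holds the private key)")
  structure(list(data_parties = party_ids, aggregator = aggregator,
                 key_authority = key_authority, m = as.integer(m)),
            class = "sma_roles")
}

# ---- transcript plumbing ----------------------------------------------

.transcript_new <- function() {
  env <- new.env(parent = emptyenv())
  env$messages <- list()
  env
}

.transcript_log <- function(tr, from, to, type, payload_kind, payload) {
  tr$messages[[length(tr$messages) + 1L]] <- list(
    step = length(tr$messages) + 1L, from = from, to = to,
    type = type, payload_kind = payload_kind, payload = payload)
  invisible(tr)
}

.transcript_finish <- function(tr) {
  msgs <- tr$messages
  summary <- vapply(msgs, function(m) {
    paste(m$step, m$from, m$to, m$type, m$payload_kind,
          .payload_fingerprint(m$payload), sep = "|")
  }, character(1))
  list(messages = msgs,
       digest = as.character(openssl::sha256(paste(summary, collapse = "\n"))))
}

.payload_fingerprint <- function(p) {
  if (is.list(p) && length(p) && inherits(p[[1]], "paillier_ciphertext")) {
    txt <- paste(vapply(p, function(ct) as.character(ct$c), character(1)),
                 collapse = ",")
    substr(as.character(openssl::sha256(txt)), 1, 16)
  } else {
    substr(as.character(openssl::sha256(paste(format(unlist(p)), collapse = ","))),
           1, 16)
  }
}

# ---- shared protocol core ---------------------------------------------

.validate_party_vectors <- function(values, roles) {
  if (!is.list(values) || length(values) < 2)
    stop("need a list of vectors from at least 2 parties")
  m <- length(values)
  if (!is.null(roles) && roles$m != m)
    stop("role assignment declares ", roles$m, " data parties but ", m,
         " submitted values")
  dims <- vapply(values, length, integer(1))
  if (length(unique(dims)) != 1L) {
    ids <- if (!is.null(roles)) roles$data_parties else paste0("party", seq_len(m))
    stop("protocol abort, dimension mismatch: ",
         paste0(ids, "=", dims, collapse = ", "))
  }
  invisible(dims[1])
}

# One round of the star protocol: every party encrypts its vector and
# SUBMITs to the aggregator; the aggregator homomorphically sums and sends
# one AGGREGATE ciphertext per component to the key authority; the key
# authority decrypts and publishes RESULT after applying `finalize` to the
# decrypted totals.
.star_round <- function(values, roles, key, base, exponent, rng,
                        protocol, finalize) {
  m <- length(values)
  d <- length(values[[1]])
  tr <- .transcript_new()
  for (i in seq_len(m)) {
    .transcript_log(tr, roles$data_parties[i], roles$aggregator, "HELLO",
                    "plaintext", list(party = roles$data_parties[i], dim = d))
  }
  submissions <- vector("list", m)
  for (i in seq_len(m)) {
    cts <- lapply(values[[i]], encrypt_real, pub = key$pub,
                  base = base, exponent = exponent, rng = rng)
    submissions[[i]] <- cts
    .transcript_log(tr, roles$data_parties[i], roles$aggregator, "SUBMIT",
                    "ciphertext", cts)
  }
  aggregate <- lapply(seq_len(d), function(j) {
    Reduce(add_encrypted, lapply(submissions, `[[`, j))
  })
  .transcript_log(tr, roles$aggregator, roles$key_authority, "AGGREGATE",
                  "aggregate_ciphertext", aggregate)
  totals <- vapply(aggregate, decrypt_real, numeric(1), priv = key$priv)
  result <- finalize(totals, m)
  .transcript_log(tr, roles$key_authority, "all", "RESULT", "plaintext",
                  as.list(result))
  structure(list(protocol = protocol, result = result, m = m, dim = d,
                 transcript = .transcript_finish(tr)),
            class = "sma_aggregate_result")
}

#' @export
print.sma_aggregate_result <- function(x, ...) {
  cat(x$protocol, "over", x$m, "parties,", x$dim, "components\n")
  cat("result:", format(x$result, digits = 6), "\n")
  cat("transcript digest:", x$transcript$digest, "\n")
  invisible(x)
}

#' Secure elementwise sum of per-party vectors
#'
#' Each party's real vector is fixed-point encoded and Paillier encrypted;
#' the aggregator multiplies ciphertexts componentwise (homomorphic
#' addition) and only the encrypted totals reach the key authority for
#' decryption. The result equals the plaintext elementwise sum up to
#' fixed-point granularity (`m * base^exponent`; exact when the inputs
#' are encoded exactly, which is the default).
#'
#' @param values list of `m >= 2` numeric vectors of equal length.
#' @param key a Paillier keypair from [paillier_keygen()]; generated
#'   fresh (with `key_bits`) when `NULL`.
#' @param key_bits key size when generating a fresh keypair.
#' @param roles an [protocol_roles()] object; defaults to `m` sites plus a
#'   third-party aggregator and key authority.
#' @param base,exponent fixed-point encoding parameters ([fp_encode()]).
#' @param rng randomness source for encryption, see [encrypt_real()].
#' @return an `sma_aggregate_result`: `result` (numeric vector), `m`, and
#'   a `transcript` (ordered message log plus SHA-256 digest) for audit.
#' @examples
#' key <- paillier_keygen(512)
#' secure_sum(list(c(1, 2), c(3, 4)), key = key)$result   # 4 6
#' @export
secure_sum <- function(values, key = NULL, key_bits = 2048, roles = NULL,
                       base = 16L, exponent = NULL, rng = c("system", "r")) {
  .validate_party_vectors(values, roles)
  if (is.null(roles)) roles <- protocol_roles(length(values))
  if (is.null(key)) key <- paillier_keygen(key_bits)
  .star_round(values, roles, key, base, exponent, match.arg(rng),
              "secure_sum", function(totals, m) totals)
}

#' Secure elementwise average of per-party vectors
#'
#' Runs the same round as [secure_sum()]; the key authority divides the
#' decrypted totals by `m` in the clear before publishing, so
#' `secure_average(v1..vm) == secure_sum(v1..vm) / m` componentwise.
#'
#' @inheritParams secure_sum
#' @return an `sma_aggregate_result` whose `result` is the elementwise mean.
#' @export
secure_average <- function(values, key = NULL, key_bits = 2048, roles = NULL,
                           base = 16L, exponent = NULL,
                           rng = c("system", "r")) {
  .validate_party_vectors(values, roles)
  if (is.null(roles)) roles <- protocol_roles(length(values))
  if (is.null(key)) key <- paillier_keygen(key_bits)
  .star_round(values, roles, key, base, exponent, match.arg(rng),
              "secure_average", function(totals, m) totals / m)
}

#' Secure majority vote (median) over binary selection vectors
#'
#' Realizes the median probability model over encrypted votes: each party
#' submits a binary vector (1 = feature selected locally); votes are
#' encrypted as integers and summed homomorphically, and the key authority
#' decrypts only the per-component counts, marking a component 1 iff
#' strictly more than `m/2` parties voted for it (the componentwise median
#' of 0/1 votes exceeds 1/2). With even `m` an exact `m/2` tie is excluded
#' — the median sits at 1/2 and the threshold is strict.
#'
#' Documented leakage: the key authority learns the per-component vote
#' counts (not which party cast which vote). This is recorded in the
#' result as `leakage_note` so protocol runs are auditable.
#'
#' @param selections list of `m >= 2` binary vectors (entries 0/1) of
#'   equal length.
#' @inheritParams secure_sum
#' @return an `sma_aggregate_result` with binary `result`, the decrypted
#'   `counts`, and `leakage_note`.
#' @examples
#' key <- paillier_keygen(512)
#' secure_median_binary(list(c(1, 1), c(1, 0), c(0, 0)), key = key)$result  # 1 0
#' @export
secure_median_binary <- function(selections, key = NULL, key_bits = 2048,
                                 roles = NULL, base = 16L,
                                 rng = c("system", "r")) {
  .validate_party_vectors(selections, roles)
  ok <- vapply(selections, function(s) all(s %in% c(0, 1)), logical(1))
  if (!all(ok))
    stop("protocol abort: non-binary entry in selection vector(s) ",
         paste(which(!ok), collapse = ", "))
  if (is.null(roles)) roles <- protocol_roles(length(selections))
  if (is.null(key)) key <- paillier_keygen(key_bits)
  counts <- NULL
  res <- .star_round(selections, roles, key, base, exponent = 0L,
                     match.arg(rng), "secure_median_binary",
                     function(totals, m) {
                       counts <<- totals
                       as.integer(totals > m / 2)
                     })
  res$counts <- counts
  res$leakage_note <- paste(
    "key authority observes per-feature vote counts (aggregate only);",
    "individual votes remain encrypted end-to-end")
  res
}
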