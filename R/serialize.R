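#' Key and ciphertext serialization
#'
#' Stable structured-text forms so parties can exchange key material and
#' ciphertexts: public keys as JSON `{n, bits}` (decimal big-integer
#' strings), private keys as `{lambda, mu, n, bits}`, ciphertexts as
#' line-delimited JSON `{c, e, base}` records.
#'
#' @param key a `paillier_pubkey` or `paillier_privkey`.
#' @param path file path; when `NULL` the JSON string is returned.
#' @return the path (or JSON string), invisibly; readers return the
#'   restored object.
#' @name paillier-serialization
NULL

#' @rdname paillier-serialization
#' @export
write_pubkey <- function(key, path = NULL) {
  stopifnot(inherits(key, "paillier_pubkey"))
  rec <- list(type = "paillier_pubkey", n = as.character(key$n),
              bits = key$bits)
  .write_json_record(rec, path)
}

#' @rdname paillier-serialization
#' @export
write_privkey <- function(key, path = NULL) {
  stopifnot(inherits(key, "paillier_privkey"))
  rec <- list(type = "paillier_privkey", lambda = as.character(key$lambda),
              mu = as.character(key$mu), n = as.character(key$pub$n),
              bits = key$pub$bits)
  .write_json_record(rec, path)
}

#' @rdname paillier-serialization
#' @param input path or JSON string.
#' @export
read_pubkey <- function(input) {
  rec <- jsonlite::fromJSON(input)
  stopifnot(identical(rec$type, "paillier_pubkey"))
  n <- openssl::bignum(rec$n)
  structure(list(n = n, g = n + openssl::bignum("1"), n2 = n * n,
                 bits = as.integer(rec$bits)),
            class = "paillier_pubkey")
}

#' @rdname paillier-serialization
#' @export
read_privkey <- function(input) {
  rec <- jsonlite::fromJSON(input)
  stopifnot(identical(rec$type, "paillier_privkey"))
  n <- openssl::bignum(rec$n)
  pub <- structure(list(n = n, g = n + openssl::bignum("1"), n2 = n * n,
                        bits = as.integer(rec$bits)),
                   class = "paillier_pubkey")
  structure(list(lambda = openssl::bignum(rec$lambda),
                 mu = openssl::bignum(rec$mu), pub = pub),
            class = "paillier_privkey")
}

.write_json_record <- function(rec, path) {
  if (is.null(path)) {
    return(invisible(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))))
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname paillier-serialization
#' @param ct a `paillier_ciphertext`.
#' @export
ciphertext_to_wire <- function(ct) {
  stopifnot(inherits(ct, "paillier_ciphertext"))
  as.character(jsonlite::toJSON(list(c = as.character(ct$c),
                                     e = ct$exponent, base = ct$base),
                                auto_unbox = TRUE))
}

#' @rdname paillier-serialization
#' @param wire a wire-form JSON string from [ciphertext_to_wire()].
#' @param pub the `paillier_pubkey` the ciphertext belongs to.
#' @export
wire_to_ciphertext <- function(wire, pub) {
  rec <- jsonlite::fromJSON(wire)
  structure(list(c = openssl::bignum(rec$c), exponent = as.integer(rec$e),
                 base = as.integer(rec$base), pub = pub),
            class = "paillier_ciphertext")
}
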