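#' Paillier keypair generation
#'
#' Generates a Paillier keypair with modulus `n = p*q` (two distinct primes
#' of `key_bits/2` bits, obtained from OpenSSL's prime generator) and the
#' generator convention `g = n + 1`, under which encryption needs a single
#' modular exponentiation and the decryption multiplier is
#' `mu = lambda^-1 mod n` with `lambda = lcm(p-1, q-1)`.
#'
#' @param key_bits modulus size in bits. 2048 is the recommended production
#'   size; 512 is acceptable for tests and simulations. Anything below 256
#'   is rejected outright.
#' @return a list with elements `pub` (class `paillier_pubkey`: `n`, `g`,
#'   `n2`, `bits`) and `priv` (class `paillier_privkey`: `lambda`, `mu`
#'   plus the public half).
#' @examples
#' key <- paillier_keygen(512)
#' ct <- encrypt_real(42, key$pub)
#' decrypt_real(ct, key$priv)   # 42
#' @export
paillier_keygen <- function(key_bits = 2048) {
  stopifnot(is.numeric(key_bits), length(key_bits) == 1L)
  if (key_bits < 256) stop("key_bits below the hard floor of 256 bits")
  repeat {
    rsa <- as.list(openssl::rsa_keygen(bits = as.integer(key_bits)))$data
    p <- rsa$p
    q <- rsa$q
    if (!(p == q)) break
  }
  n <- p * q
  one <- openssl::bignum("1")
  pm1 <- p - one
  qm1 <- q - one
  lambda <- (pm1 * qm1) %/% .bignum_gcd(pm1, qm1)
  mu <- openssl::bignum_mod_inv(lambda %% n, n)
  pub <- structure(list(n = n, g = n + one, n2 = n * n,
                        bits = as.integer(key_bits)),
                   class = "paillier_pubkey")
  priv <- structure(list(lambda = lambda, mu = mu, pub = pub),
                    class = "paillier_privkey")
  list(pub = pub, priv = priv)
}

.bignum_gcd <- function(a, b) {
  zero <- openssl::bignum("0")
  while (!(b == zero)) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

#' @export
print.paillier_pubkey <- function(x, ...) {
  cat("Paillier public key:", x$bits, "bit modulus, g = n + 1\n")
  invisible(x)
}

#' @export
print.paillier_privkey <- function(x, ...) {
  cat("Paillier private key for a", x$pub$bits, "bit modulus\n")
  invisible(x)
}

# Uniform bignum in [1, n) coprime with n. source = "system" draws from the
# OS entropy pool; "r" draws from R's RNG so that set.seed() makes
# encryption reproducible (tests, audited replays).
.random_unit <- function(n, bits, source = c("system", "r")) {
  source <- match.arg(source)
  nbytes <- ceiling(bits / 8) + 8L
  repeat {
    raw <- if (source == "system") openssl::rand_bytes(nbytes)
           else as.raw(sample.int(256L, nbytes, replace = TRUE) - 1L)
    r <- openssl::bignum(raw) %% n
    if (r == openssl::bignum("0")) next
    # coprimality with n: r is a unit iff it has an inverse mod n
    inv <- tryCatch(openssl::bignum_mod_inv(r, n), error = function(e) NULL)
    if (!is.null(inv)) return(r)
  }
}

#' Encrypt a real value under a Paillier public key
#'
#' Encodes `x` as a signed fixed point ([fp_encode()]) and encrypts the
#' mantissa as `c = (1 + n*m) * r^n mod n^2`. Encryption is semantically
#' randomized: repeated encryptions of the same value yield different
#' ciphertexts that decrypt identically.
#'
#' @param x a single finite real.
#' @param pub a `paillier_pubkey`.
#' @param base,exponent fixed-point parameters, see [fp_encode()].
#' @param rng `"system"` (entropy pool, default) or `"r"` (R's seeded RNG).
#' @return an object of class `paillier_ciphertext` with fields `c`
#'   (bignum mod `n^2`), `exponent`, `base` and the public key.
#' @export
encrypt_real <- function(x, pub, base = 16L, exponent = NULL,
                         rng = c("system", "r")) {
  stopifnot(inherits(pub, "paillier_pubkey"))
  enc <- fp_encode(x, base = base, exponent = exponent, key = pub)
  m <- .mantissa_to_residue(enc$mantissa, pub)
  .encrypt_residue(m, pub, enc$exponent, enc$base, match.arg(rng))
}

.encrypt_residue <- function(m, pub, exponent, base, rng = "system") {
  r <- .random_unit(pub$n, pub$bits, rng)
  gm <- (openssl::bignum("1") + pub$n * m) %% pub$n2
  c <- (gm * openssl::bignum_mod_exp(r, pub$n, pub$n2)) %% pub$n2
  structure(list(c = c, exponent = as.integer(exponent),
                 base = as.integer(base), pub = pub),
            class = "paillier_ciphertext")
}

#' Decrypt a Paillier ciphertext to a real value
#'
#' Recovers the mantissa as `L(c^lambda mod n^2) * mu mod n` with
#' `L(u) = (u-1)/n`, maps it back to a signed value with the
#' reserved-thirds convention and rescales by `base^exponent`.
#'
#' @param ct a `paillier_ciphertext`.
#' @param priv the matching `paillier_privkey`.
#' @return the decrypted real value.
#' @export
decrypt_real <- function(ct, priv) {
  stopifnot(inherits(ct, "paillier_ciphertext"),
            inherits(priv, "paillier_privkey"))
  mantissa <- .decrypt_residue(ct, priv)
  mantissa * ct$base^ct$exponent
}

# signed mantissa (double) from a ciphertext
.decrypt_residue <- function(ct, priv) {
  pub <- priv$pub
  if (!(ct$pub$n == pub$n)) stop("ciphertext does not match this private key")
  u <- openssl::bignum_mod_exp(ct$c, priv$lambda, pub$n2)
  L <- (u - openssl::bignum("1")) %/% pub$n
  m <- (L * priv$mu) %% pub$n
  .residue_to_mantissa(m, pub)
}

#' @export
print.paillier_ciphertext <- function(x, ...) {
  cat("Paillier ciphertext (", x$pub$bits, " bit key, base ", x$base,
      ", exponent ", x$exponent, ")\n", sep = "")
  invisible(x)
}

#' Homomorphic addition of two ciphertexts
#'
#' The product of two Paillier ciphertexts decrypts to the sum of their
#' plaintexts. Fixed-point exponents are aligned first: the operand with
#' the larger exponent is scaled down the grid by homomorphically
#' multiplying its mantissa with `base^(e_hi - e_lo)`, so callers never
#' handle exponents themselves.
#'
#' @param a,b `paillier_ciphertext` objects under the same public key and
#'   base.
#' @return a `paillier_ciphertext` of the sum.
#' @export
add_encrypted <- function(a, b) {
  stopifnot(inherits(a, "paillier_ciphertext"),
            inherits(b, "paillier_ciphertext"))
  if (!(a$pub$n == b$pub$n)) stop("cannot add ciphertexts under different keys")
  if (a$base != b$base) stop("cannot add ciphertexts with different encoding bases")
  al <- .align_exponents(a, b)
  structure(list(c = (al$a$c * al$b$c) %% a$pub$n2,
                 exponent = al$a$exponent, base = a$base, pub = a$pub),
            class = "paillier_ciphertext")
}

.align_exponents <- function(a, b) {
  if (a$exponent == b$exponent) return(list(a = a, b = b))
  if (a$exponent > b$exponent) {
    a <- .rescale_down(a, a$exponent - b$exponent)
  } else {
    b <- .rescale_down(b, b$exponent - a$exponent)
  }
  list(a = a, b = b)
}

# multiply the mantissa by base^delta (homomorphically) and drop the
# exponent by delta; the represented value is unchanged
.rescale_down <- function(ct, delta) {
  k <- .bignum_pow(openssl::bignum(as.character(ct$base)), delta)
  structure(list(c = openssl::bignum_mod_exp(ct$c, k, ct$pub$n2),
                 exponent = ct$exponent - as.integer(delta),
                 base = ct$base, pub = ct$pub),
            class = "paillier_ciphertext")
}

.bignum_pow <- function(b, e) {
  out <- openssl::bignum("1")
  for (i in seq_len(e)) out <- out * b
  out
}

#' Homomorphic multiplication of a ciphertext by a plaintext integer
#'
#' `c^k mod n^2` decrypts to `k` times the plaintext. `k` must be a
#' non-negative integer (this is the primitive the adder uses for
#' exponent alignment; general plaintext scaling belongs in the clear).
#'
#' @param ct a `paillier_ciphertext`.
#' @param k a single non-negative integer-valued scalar.
#' @return a `paillier_ciphertext` of `k * plaintext`.
#' @export
scalar_multiply <- function(ct, k) {
  stopifnot(inherits(ct, "paillier_ciphertext"),
            is.numeric(k), length(k) == 1L, k >= 0, k == round(k))
  kb <- openssl::bignum(sprintf("%.0f", k))
  structure(list(c = openssl::bignum_mod_exp(ct$c, kb, ct$pub$n2),
                 exponent = ct$exponent, base = ct$base, pub = ct$pub),
            class = "paillier_ciphertext")
}
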