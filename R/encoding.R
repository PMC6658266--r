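#' Signed fixed-point encoding of reals for homomorphic arithmetic
#'
#' Paillier ciphertexts carry non-negative integers modulo `n`, so real
#' values are represented as `mantissa * base^exponent` with an integer
#' mantissa. Negative mantissas are mapped into the upper residue range
#' (`n - |mantissa|`) of the key modulus; the residue space is split into
#' thirds so that decoding can distinguish positive values (low third),
#' negative values (high third) and overflow (middle third, always an
#' error, never a silent wrap).
#'
#' With the default `exponent = NULL` the exponent is derived from the
#' binary exponent of `x` so that the encoding represents the incoming
#' double exactly (relative error 0, i.e. below 2^-53); an explicit
#' exponent instead rounds `x` onto the fixed grid `base^exponent`.
#'
#' @param x a single finite real value.
#' @param base integer radix of the encoding, default 16 (a power of two,
#'   so binary doubles encode exactly under the automatic exponent).
#' @param exponent integer fixed-point exponent, or `NULL` to derive the
#'   largest exponent that still represents `x` exactly.
#' @param key optional [paillier_pubkey]; when supplied the mantissa is
#'   checked against the key's overflow boundary (`|mantissa| < n/3`).
#' @return an object of class `fp_encoded`: list with integer-valued
#'   `mantissa` (signed, stored as a double `< 2^53` in magnitude),
#'   `exponent` and `base`.
#' @examples
#' e <- fp_encode(-1.5, base = 16, exponent = -8)
#' fp_decode(e)   # -1.5
#' @export
fp_encode <- function(x, base = 16L, exponent = NULL, key = NULL) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x), base >= 2)
  if (is.null(exponent)) {
    if (x == 0) {
      exponent <- 0L
      mantissa <- 0
    } else {
      # binary exponent e2 with |x| = f * 2^e2, f in [1, 2)
      e2 <- floor(log2(abs(x)))
      if (abs(x) >= 2^(e2 + 1)) e2 <- e2 + 1
      if (abs(x) < 2^e2) e2 <- e2 - 1
      exponent <- as.integer(floor((e2 - 52) / log2(base)))
      # power-of-two rescale of a double: exact by construction
      mantissa <- round(x * base^(-exponent))
    }
  } else {
    exponent <- as.integer(exponent)
    mantissa <- round(x / base^exponent)
    if (abs(mantissa) >= 2^53)
      stop("fixed-point mantissa for ", format(x),
           " exceeds exact double range; raise the exponent")
  }
  if (!is.null(key)) .check_overflow_mantissa(abs(mantissa), key)
  structure(list(mantissa = mantissa, exponent = exponent, base = as.integer(base)),
            class = "fp_encoded")
}

#' Decode a fixed-point encoding back to a real
#' @param enc an `fp_encoded` object from [fp_encode()].
#' @return the represented real value.
#' @export
fp_decode <- function(enc) {
  stopifnot(inherits(enc, "fp_encoded"))
  enc$mantissa * enc$base^enc$exponent
}

# mantissa (non-negative double or bignum) vs n/3 boundary
.check_overflow_mantissa <- function(mantissa_abs, key) {
  m <- if (inherits(mantissa_abs, "bignum")) mantissa_abs
       else openssl::bignum(sprintf("%.0f", mantissa_abs))
  if (!((m * openssl::bignum("3")) < key$n))
    stop("fixed-point overflow: |mantissa| >= n/3 for this key")
  invisible(TRUE)
}

# Map a signed integer-valued mantissa into [0, n).
.mantissa_to_residue <- function(mantissa, key) {
  if (mantissa >= 0) {
    openssl::bignum(sprintf("%.0f", mantissa))
  } else {
    key$n - openssl::bignum(sprintf("%.0f", -mantissa))
  }
}

# Inverse of .mantissa_to_residue with the reserved-thirds convention:
# low third -> positive, high third -> negative, middle third -> overflow.
# Returns a signed double (exact for |mantissa| < 2^53; correctly rounded
# beyond, e.g. after long homomorphic sums).
.residue_to_mantissa <- function(residue, key) {
  third <- key$n %/% openssl::bignum("3")
  if (residue <= third) {
    as.numeric(as.character(residue))
  } else if (residue >= key$n - third) {
    -as.numeric(as.character(key$n - residue))
  } else {
    stop("decoded mantissa lies in the overflow (middle) third of the modulus")
  }
}
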