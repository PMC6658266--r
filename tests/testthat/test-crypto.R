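test_that("encrypt/decrypt round-trips integers, zero and signed reals", {
  expect_equal(decrypt_real(encrypt_real(42, tkey$pub), tkey$priv), 42)
  expect_equal(decrypt_real(encrypt_real(0, tkey$pub), tkey$priv), 0)
  expect_equal(decrypt_real(encrypt_real(-1.5, tkey$pub), tkey$priv), -1.5)
  # mantissa boundary values +-1 on the integer grid
  expect_equal(decrypt_real(encrypt_real(1, tkey$pub, exponent = 0), tkey$priv), 1)
  expect_equal(decrypt_real(encrypt_real(-1, tkey$pub, exponent = 0), tkey$priv), -1)
})

test_that("round-trip is exact on the fixed-point grid for random signed reals", {
  set.seed(101)
  x <- runif(100, -1e6, 1e6)
  rt <- vapply(x, function(v) decrypt_real(encrypt_real(v, tkey$pub), tkey$priv),
               numeric(1))
  expect_identical(rt, x)   # automatic exponent encodes doubles exactly
  # explicit grid: error bounded by one grid step
  rt8 <- vapply(x, function(v) {
    decrypt_real(encrypt_real(v, tkey$pub, exponent = -8), tkey$priv)
  }, numeric(1))
  expect_lt(max(abs(rt8 - x)), 16^-8)
})

test_that("fixed-point encoding obeys the stated sign convention", {
  enc <- fp_encode(-1.5, base = 16, exponent = -8)
  expect_equal(enc$mantissa, -(1.5 * 16^8))
  expect_equal(fp_decode(enc), -1.5)
  expect_equal(fp_encode(0, base = 16, exponent = -4)$mantissa, 0)
  # residue form is n - |mantissa|
  residue <- smareg:::.mantissa_to_residue(enc$mantissa, tkey$pub)
  expect_true(residue == tkey$pub$n - openssl::bignum("6442450944"))
})

test_that("encoding overflow (middle third of the modulus) raises, never wraps", {
  fake <- structure(list(n = openssl::bignum("99")), class = "paillier_pubkey")
  expect_error(fp_encode(40, base = 16, exponent = 0, key = fake), "overflow")
  expect_error(smareg:::.residue_to_mantissa(openssl::bignum("50"), fake),
               "overflow")
  # low and high thirds decode with their signs
  expect_equal(smareg:::.residue_to_mantissa(openssl::bignum("30"), fake), 30)
  expect_equal(smareg:::.residue_to_mantissa(openssl::bignum("70"), fake), -29)
})

test_that("encryption is randomized yet reproducible under a seeded source", {
  a <- encrypt_real(7, tkey$pub)
  b <- encrypt_real(7, tkey$pub)
  expect_false(a$c == b$c)
  expect_equal(decrypt_real(a, tkey$priv), decrypt_real(b, tkey$priv))
  set.seed(99); c1 <- encrypt_real(5, tkey$pub, rng = "r")
  set.seed(99); c2 <- encrypt_real(5, tkey$pub, rng = "r")
  expect_true(c1$c == c2$c)
})

test_that("homomorphic addition matches plaintext sums, including alignment", {
  expect_equal(decrypt_real(add_encrypted(encrypt_real(3, tkey$pub),
                                          encrypt_real(4, tkey$pub)),
                            tkey$priv), 7)
  x <- 123.456
  expect_equal(decrypt_real(add_encrypted(encrypt_real(x, tkey$pub),
                                          encrypt_real(-x, tkey$pub)),
                            tkey$priv), 0)
  set.seed(5)
  for (i in 1:25) {
    a <- runif(1, -1e4, 1e4); b <- runif(1, -1e4, 1e4)
    s <- decrypt_real(add_encrypted(encrypt_real(a, tkey$pub),
                                    encrypt_real(b, tkey$pub)), tkey$priv)
    expect_equal(s, a + b, tolerance = 1e-12)
  }
  # chain of 20 with heterogeneous magnitudes (exercises exponent alignment)
  set.seed(6)
  vals <- runif(20, -1, 1) * 10^sample(-6:6, 20, replace = TRUE)
  total <- decrypt_real(Reduce(add_encrypted,
                               lapply(vals, encrypt_real, pub = tkey$pub)),
                        tkey$priv)
  expect_equal(total, sum(vals), tolerance = 1e-12)
})

test_that("scalar multiplication matches plaintext products", {
  e5 <- encrypt_real(5, tkey$pub)
  expect_equal(decrypt_real(scalar_multiply(e5, 1), tkey$priv), 5)
  expect_equal(decrypt_real(scalar_multiply(e5, 0), tkey$priv), 0)
  set.seed(7)
  for (i in 1:25) {
    x <- runif(1, -1e3, 1e3); k <- sample.int(1000, 1)
    expect_equal(decrypt_real(scalar_multiply(encrypt_real(x, tkey$pub), k),
                              tkey$priv),
                 k * x, tolerance = 1e-9)
  }
  expect_error(scalar_multiply(e5, -2))
  expect_error(scalar_multiply(e5, 1.5))
})

test_that("key generation enforces the hard floor and key separation", {
  expect_error(paillier_keygen(128), "hard floor")
  other <- paillier_keygen(512)
  expect_error(add_encrypted(encrypt_real(1, tkey$pub),
                             encrypt_real(1, other$pub)), "different keys")
  expect_error(decrypt_real(encrypt_real(1, other$pub), tkey$priv),
               "does not match")
})

test_that("keys and ciphertexts survive their serialized text forms", {
  pub2 <- read_pubkey(write_pubkey(tkey$pub))
  priv2 <- read_privkey(write_privkey(tkey$priv))
  expect_true(pub2$n == tkey$pub$n)
  ct <- encrypt_real(-273.15, pub2)
  expect_equal(decrypt_real(ct, priv2), -273.15)
  ct2 <- wire_to_ciphertext(ciphertext_to_wire(ct), tkey$pub)
  expect_equal(decrypt_real(ct2, tkey$priv), -273.15)
  # file round trip
  f <- withr::local_tempfile(fileext = ".json")
  write_pubkey(tkey$pub, f)
  expect_true(read_pubkey(f)$n == tkey$pub$n)
})
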