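# One 512-bit keypair shared across the suite: key generation is random
# every time, but nothing downstream depends on which primes are drawn.
tkey <- paillier_keygen(512)

# small i.i.d. regression site for unit tests
make_site <- function(n, beta, sigma = 1, seed = NULL, site_id = "s1") {
  if (!is.null(seed)) set.seed(seed)
  p <- length(beta)
  x <- matrix(rnorm(n * p), n, p)
  y <- drop(x %*% beta) + rnorm(n, 0, sigma)
  sma_site(x, y, site_id = site_id)
}
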