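---
title: "Secure multiparty linear regression: model, protocols and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secure multiparty linear regression: model, protocols and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smareg)
```

## The problem

Several institutions — hospitals, registries, study sites — hold disjoint
records of a common schema (horizontal partitioning) and want one linear
model for the union of their data, but cannot pool raw records. smareg
fits that model by *split and merge*: every site computes on its own rows
only, and the few numbers that must be combined are merged under
encryption, so that nothing besides the final model is ever disclosed —
not raw data, not per-site selections, not per-site coefficients.

Formally, site $i$ holds $(X^i, Y^i)$ with $n_i$ rows of $p$ features,
all sites' records assumed i.i.d. draws from one population model
$Y = X\beta + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$. A linear
fit has two components, and each is merged with the combiner that theory
recommends for it:

1. **Feature selection.** Each site runs the lasso on its own rows and
   votes a binary vector $s^i \in \{0,1\}^p$. The merged set is the
   *median probability model*: feature $j$ is kept iff strictly more
   than $m/2$ sites voted for it. The median is preferred over
   averaging here because averaging inflates the selected set, and the
   componentwise median of 0/1 votes is exactly the majority rule.
2. **Parameter estimation.** Each site then fits ordinary least squares
   on its rows restricted to the agreed set $S$ and submits
   $(\hat\alpha_i, \hat\beta_{S,i})$; the published model is the simple
   (unweighted) average of the $m$ local fits.

Distributed-averaging theory says this loses essentially nothing when
every site has many records relative to both $p$ and $m$: the averaged
and centralized estimators agree to first order, and for linear models
the loss is negligible when $p < \log N$ and $m \le Np/(\log N)^2$.
`check_dsc_conditions()` reports these requirements — `n_min > p`,
`n_min > m`, `m \le \sqrt N`, and the two linear-model bounds — as
advisory warnings, never as hard errors, because they are asymptotic
guidance rather than validity conditions. The logarithms are natural
logs.

## The secure aggregation layer

Both merge points are instances of one primitive: an elementwise sum of
per-party vectors that no individual party may see. smareg realizes it
with the Paillier cryptosystem, which is additively homomorphic — the
product of two ciphertexts decrypts to the sum of the plaintexts — in a
star topology with three roles:

* **data parties** encrypt their vectors and submit ciphertexts;
* one **aggregator** multiplies ciphertexts componentwise (it sees only
  ciphertexts and holds no key);
* one **key authority** holds the private key, receives exactly one
  aggregate ciphertext per component, decrypts and publishes.

The averaging merge divides the decrypted totals by $m$ in the clear;
the selection merge sums 0/1 votes and applies the strict `> m/2`
threshold after decryption. Every run records a full message transcript
(`HELLO`/`SUBMIT`/`AGGREGATE`/`RESULT`) with a SHA-256 digest, and the
test suite asserts the privacy contract directly on transcripts: the
aggregator receives only ciphertexts, the key authority only aggregate
ciphertexts, and the only plaintext payloads are the published result
and the dimension announcements.

Assumptions and known leakage, stated plainly:

* The adversary model is semi-honest (honest-but-curious) with no
  collusion between aggregator and key authority. Malicious security,
  threshold keys and side-channel hardening are out of scope.
* The vote-count construction of the selection merge lets the key
  authority see per-feature **vote counts** (never which party voted).
  This reconstruction choice is recorded in every protocol result as an
  explicit `leakage_note` so deployments can audit it.
* With even $m$, a feature with exactly $m/2$ votes is **excluded**: the
  median of the 0/1 votes sits at $1/2$ and the threshold is strictly
  greater, which is also the parsimonious choice.
* The agreed set $S$ is broadcast in the clear after phase 1 — it is
  part of the declared output.

The transports are message-faithful but in-process: all parties run in
one R process against an in-memory queue with the same message sequence
a socket deployment would use, and keys, ciphertexts and models all have
stable JSON text forms (`write_pubkey()`, `ciphertext_to_wire()`,
`write_global_model()`) so the messages themselves are serializable. A
hardened network transport (TLS, authentication, timeouts) is a
deployment concern deliberately left out of this package.

## Encrypted real arithmetic

Paillier operates on integers modulo $n$; statistics are reals. Values
are encoded as `mantissa * base^exponent` with base 16. By default the
exponent is derived per value from its binary exponent so the encoding
represents the incoming double *exactly* — round-trips through
encrypt/decrypt are then exact, not approximate, and the homomorphic
sum is exact at the mantissa level. An explicit exponent (e.g. `-8`)
instead rounds onto a fixed grid with error at most $16^{-8}$ per
value. The adder aligns differing exponents itself, homomorphically,
by multiplying the coarser mantissa by $16^{\Delta e}$ — callers never
see exponents.

Negative values occupy the upper residue range: $x < 0$ is stored as
$n - |{\rm mantissa}|$. The residue space is split into thirds — low
third positive, high third negative, middle third an explicit overflow
error. Overflow therefore raises; it never wraps silently. With a
512-bit modulus the boundary sits near $2^{510}$, far beyond any
mantissa the statistics produce, so the check is a guard rail rather
than a practical limit.

Key sizes: 2048 bits is the production default; the simulations and
tests use 512-bit keys, which exercise identical code paths at about a
quarter of the per-operation cost. Key generation builds on OpenSSL's
prime generator; encryption randomness comes from the system entropy
pool by default, or from R's seeded RNG (`rng = "r"`) when reproducible
ciphertexts are wanted for audits. Decrypted *results* are exact either
way, so end-to-end model reproducibility needs only the statistical
seed.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda_policy` | `"cv_min"` | per-site 5-fold CV, penalty minimizing CV MSE; `"cv_1se"` and `"fixed"` available |
| `nfolds` | 5 | CV folds for the penalty search |
| `nlambda` | 50 | length of the candidate penalty path |
| `key_bits` | 2048 | Paillier modulus size (512 in simulations) |
| `base` | 16 | fixed-point radix |
| `fraction` | 0.7 | per-site training fraction in evaluation |
| `repetitions` | 50 | repeated train/test splits per evaluation |
| `weights` | equal | averaging weights (unweighted by default) |

Choices worth a word:

* **Penalty policy.** Published practice for this pipeline says "lasso"
  without specifying how the penalty is chosen, so the policy is
  pluggable. CV-min is the default. Note that at a *single* site CV-min
  deliberately trades parsimony for prediction and often admits
  near-zero extras; the cross-site majority vote is precisely the
  mechanism that prunes them, and the noiseless-recovery tests show the
  voted set is exact even when individual sites overselect. The
  50-point penalty path resolves the CV optimum well below fold-to-fold
  noise at half the default path's cost.
* **Standardization.** Features are centered and scaled *within* each
  site (inside glmnet) and coefficients returned on the original scale
  before averaging. Pooled cross-site standardization would itself leak
  per-site moments; it could be done with one extra secure-sum round
  and is noted as an extension, not the default.
* **Unweighted averaging.** The published merge is the simple average,
  and with i.i.d. sites of comparable size weighting changes little. A
  weight option exists for the plaintext path; the secure protocol
  publishes the unweighted mean only.
* **Intercept.** Always fitted, never penalized, never voted on.
* **Empty selection.** If no feature wins a majority the published
  model is intercept-only (securely averaged site means), with a
  warning.
* **Rank deficiency.** If the design restricted to $S$ is rank
  deficient at a site, that site reports the minimum-norm solution via
  the Moore–Penrose pseudoinverse, with a warning — never a crash, and
  never a silently dropped column.

## The synthetic-data generator

`generate_sites()` draws the study conditions the theory assumes: i.i.d.
rows from one linear model, divided equally between the sites (a
remainder goes to the first sites; explicit per-site counts are also
accepted). Features are standard normal, optionally equicorrelated with
parameter $\rho$ via a shared-factor construction; the informative
coefficients default to uniform on $[-10, 10]$ over a random subset of
size `k` (default $\lfloor p/3\rfloor$), noise is Gaussian with
$\sigma = 1$ by default, and the truth record (true $\beta$,
informative set, all settings) always accompanies the sites. A
heterogeneity knob `delta` shifts site $i$'s feature means by
$(i-1)\delta$, deliberately breaking the i.i.d. assumption for
robustness experiments; it is off by default.

What the generator does *not* emulate: categorical features and their
encodings, missing data, heavy-tailed noise, and systematic cross-site
differences in the $X$–$Y$ relationship itself (only mean shifts are
provided). Passing tests on this generator therefore demonstrates
correctness of the protocols and the estimator under the stated
assumptions — not robustness to the messiness of real clinical data,
where the i.i.d. assumption is the known weak point.

## Evaluation design

`repeated_experiment()` mirrors the standard protocol: split each
site's rows 0.7/0.3 (the split is per-site because rows cannot leave a
site), fit the centralized baseline on the pooled training rows and the
secure multiparty fit on the per-site training rows, score both on the
pooled test rows, repeat 50 times with fresh seeded splits, and report
mean MSE, mean $R^2$ and the ratio
${\rm MSE}_{\rm central}/{\rm MSE}_{\rm multiparty}$. A ratio near 1
means the secure distributed procedure costs no accuracy. The
centralized baseline uses the *same* selection-then-refit recipe on
pooled data, so the comparison isolates the effect of distribution and
encryption rather than of modeling choices.

Problem sizes used by the shipped acceptance checks, chosen to sit well
inside the `n > p`, `n > m` regime the estimator is designed for:
$N = 10^5$ records, $p \in \{10, 50\}$, $m \in \{2, 10, 20\}$, 50
repetitions, with 512-bit keys and full encryption; the
secure-vs-plaintext agreement check runs at $N = 10^4, p = 10, m = 4$;
noiseless exact recovery at $N = 2000, p = 10, m = 4$ with
$\beta_S = (5, 4, -3)$. On these conditions the measured MSE ratios sit
within a few parts per thousand of 1.

## Numerical and degenerate-input choices

* Fixed-point encoding is exact for doubles by default; sums of $m$
  encoded values are exact at the mantissa level, so secure and
  plaintext pipelines agree to floating-point rounding (observed
  $\sim 10^{-15}$), not merely to grid tolerance.
* Constant feature columns get a warning and a forced-zero vote; a
  constant outcome yields an empty selection with a warning.
* A zero-variance test outcome makes $R^2$ undefined; it is reported as
  `NA` rather than a division error.
* `m <= sqrt(N)` is checked as `m^2 <= N` in integer arithmetic so the
  boundary case is exact.
* Ciphertext randomness that is not coprime with the modulus is
  resampled internally (probability $\sim 2^{-250}$ at test key sizes).

## Limitations

* Semi-honest security only; collusion of aggregator and key authority
  would reveal per-party submissions.
* Vote counts are visible to the key authority (logged leakage).
* Linear models with $n > p$ per site only; no high-dimensional
  ($p > n$) regime, and ridge/logistic variants are future work.
* Horizontal partitioning only.
* The in-process transport is a faithful single-machine test bench, not
  a deployed network stack.
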