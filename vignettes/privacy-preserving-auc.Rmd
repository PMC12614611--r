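---
title: "Privacy-preserving AUC across data stations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving AUC across data stations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multi-site clinical studies often need to report how well a shared
classifier discriminates — the AUC — on evaluation data that is scattered
across hospitals and may not be pooled. The AUC is a *global* statistic:
it depends on the joint ranking of every score against every other, so
per-site AUCs cannot simply be averaged, and sharing scores or labels
leaks sensitive information (a label can itself be a diagnosis).

`ppauc` implements two protocols in which data stations and one
aggregation proxy jointly compute the global AUC while every score, label
and intermediate count stays encrypted or masked:

* **DPPE-AUC** — exact, tie-aware, cost linear in the number of samples;
* **DPPA-AUC** — approximate on a fixed grid of `K` decision points, with
  station-side encryption cost independent of the sample count.

Both run here as a single-process simulation (optionally file-by-file
through serialized train states), mirroring a sequential "train" that
visits stations and proxy in route order. Network transport, container
infrastructure, and classifier training are out of scope.

## The statistic

For descending unique thresholds `i = 1..S` of the pooled scores
(predict positive when score >= threshold), with cumulative counts
`TP[i]`, `FP[i]`, totals `T`, `N`, and sentinel `TP[0] = FP[0] = 0`:

```
AUC = 1/(2*T*N) * sum_i (TP[i] + TP[i-1]) * (FP[i] - FP[i-1])
```

This trapezoidal form counts tied positive–negative pairs half, so it
equals the pair-counting AUC (`pair_count_auc()` is the package's
independent O(T·N) oracle, `exact_auc()` the trapezoidal reference).
Re-expressing the statistic with a single final division is what lets the
numerator and denominator be assembled homomorphically from counts.

## Cryptographic building blocks

**Modified Paillier with split keys.** Public key `(n, g, h = g^x)` with
`n = z*y` a product of safe primes, `g = -a^(2n) mod n^2` (so the order
of `g` divides `(z-1)(y-1)/2`), secret `x` uniform in `[1, n^2/2]`.
Encryption of `m` in `Z_n` picks `r` in `[1, n/4]` and forms
`c1 = g^r`, `c2 = h^r (1 + m n) mod n^2`; decryption computes
`((c2 / c1^x mod n^2) - 1)/n`. Ciphertexts add by component-wise
multiplication and scale by exponentiation. The secret splits additively,
`x = x1 + x2` over the integers: the proxy holds `x1` and partially
decrypts `(c1, c2) -> (c1, c2 / c1^x1)`; stations hold `x2` and finish.
Neither share decrypts alone. Signed plaintexts use the upper-half
convention (residues above `n/2` are negative); every protocol magnitude
is bounded far below `n/2` and an explicit worst-case bound check rejects
keys that are too small for the blinder ranges.

**Score masking.** Scores are fixed-point encoded
(`round(score * 10^p)`, default `p = 12`) and masked as
`r1*s + (s mod r1)` with one shared base `r1` drawn uniformly from
`[2^32, 2^64)` by the first station and relayed to the others in RSA
envelopes. The map is strictly increasing for any `r1 >= 2` (consecutive
integers differ by at least 1 after masking) and deterministic, so the
proxy can sort pooled masked values and group *exactly* the tie classes
of the underlying scores without learning them. The deterministic
remainder term — rather than an independent random — is precisely what
makes equal scores at different stations collide.

**Dummy samples.** Each station appends a configurable fraction (default
0.2) of dummy records with label 0 and flag 0 whose scores are resampled
from its existing real values; real records carry flag 1. Dummies distort
the proxy's view of the score distribution but add no thresholds, and
because the proxy computes false positives as (flag sum) − (label sum),
every dummy cancels from every count. The pipeline output is provably
unchanged for any dummy fraction, which the tests assert bit-for-bit.

**Randomized encoding of products.** The proxy cannot multiply
ciphertexts, so each needed product `x1*x2` is published as the blinded
triple `(x1+r1, x2+r2, r2x1 + r1x2 + r1r2)`: combining the components as
`c1*c2 - c3` yields only the product. Per-threshold terms additionally
carry a zero-sum blinder vector `z` (the last entry is the negated sum of
the others), so individual numerator terms are hidden while the total is
preserved exactly.

**Envelopes.** Masked score tables travel under fresh 256-bit AES-GCM
session keys; an HMAC-SHA256 tag over nonce and ciphertext makes any bit
flip a hard failure. Session keys and the mask base are RSA-wrapped for
their single recipient with an 8-byte key-confirmation checksum inside
the envelope, so unwrapping with the wrong private key fails
deterministically rather than yielding pseudorandom bytes (modern RSA
decryption deliberately does not signal padding failures). Paillier key
shares are wrapped hybridly (RSA-wrapped session key + authenticated
symmetric body) since they exceed one RSA block.

## Protocol flow

1. **Initialization.** An initialization party generates the Paillier
   pair, splits `x`, wraps share 0 for the proxy and share 1 for each
   station, and discards `x`.
2. **Stations (exact protocol).** Each station injects dummies, masks its
   fixed-point scores, symmetric-encrypts the masked list, wraps the
   session key for the proxy, and Paillier-encrypts label and flag bits —
   2 encryptions per sample. The first station draws and relays `r1`.
3. **Proxy (exact).** Unwraps session keys, pools and sorts masked rows,
   accumulates encrypted running sums of labels and flags (one snapshot
   per tie class, `FP = flags - TP`), scales totals by random `a`, `b`,
   forms the randomized-encoding components of denominator
   (`D1, D2, D3`) and numerator (`N1[i], N2[i]`, aggregated `N3`), and
   partially decrypts everything with share 0.
4. **Stations (final).** Any station finishes decryption with share 1,
   decodes signs, and computes
   `(sum_i N1[i]*N2[i] - N3) / (2*(D1*D2 - D3))` — numerator and
   denominator as exact big integers, then one floating division. The
   scale factors `a*b` cancel in the exact quotient, so the result is
   bit-identical across all proxy randomness.

The approximate protocol replaces steps 2–3: stations send encrypted
cumulative TP/FP counts at `K` shared decision points (the package uses
`d_j = 1 - j/K`, `j = 0..K-1`, one admissible choice — only the count is
prescribed); the proxy sums them elementwise across stations and applies
the same adjacent-sum/difference blinding once. The printed aggregation
recurrence, read literally, would apply that transformation twice, which
is inconsistent with the trapezoidal statistic; this implementation
applies it once.

### Threshold accumulation in the approximate protocol

At interior decision points a station counts the samples scoring
*strictly above* the point; at the final point it folds in all remaining
samples, so the last counts always carry the station totals `(T, N)`.
This "finalize at the last point" reading of the per-station sweep was
chosen over a cursor-based patch (fold in the last sample the first time
the traversal reaches it) because it is the only variant that is
*additive across stations* — summed per-station counts equal pooled
counts at every decision point — which the proxy's elementwise
aggregation silently assumes, and it converges to the exact AUC as the
grid refines to the unique scores. The two protocols still differ in
threshold convention (strictly-above grid points vs score-at-threshold);
they are reconciled through the refinement-limit property rather than
forced to match pointwise.

## Numerical choices

* **Fixed-point precision** `p = 12` digits. Masking needs an exact
  integer domain; `p = 12` keeps `10^p` within exact-double range and
  makes the probability that two genuinely distinct scores collide into
  one bin negligible even for distributions piled up near 0 and 1, where
  a coarser grid (e.g. `p = 10`) would occasionally create ties the
  plaintext oracle does not see. All fixed-point and mask arithmetic runs
  on arbitrary-precision integers; masked values are carried as decimal
  strings and compared by zero-padded string order.
* **Blinder ranges.** `a, b` uniform in `[1, 2^32)`; additive blinders in
  `[1, 2^64)`; `z` entries signed 64-bit. A conservative worst-case bound
  (`S` thresholds, `m` samples) is checked against `n/2` before blinding;
  256-bit keys comfortably accommodate simulations of up to a million
  samples, 128-bit keys are rejected.
* **Exact final division.** The numerator and denominator of the AUC are
  assembled as exact signed big integers; the quotient is truncated at 96
  fractional bits and converted once to double. Because the integer
  quotient is invariant to the common factor `a*b`, the recovered AUC is
  bit-identical across proxy seeds; it differs from the plaintext oracle
  only through this one rounding, i.e. at most a few units in the last
  double-precision place (empirically 0 or ~1e-16).
* **Safe primes.** Candidates drawn from R's RNG (all protocol randomness
  is `set.seed()`-reproducible), forced to `3 (mod 4)`, trial-divided by
  primes below 1000, confirmed by Miller–Rabin (40 rounds; the cheaper
  `(p-1)/2` test runs first). Key material defaults to 3072-bit Paillier
  and 4096-bit RSA; simulations and tests use 256–512-bit Paillier and
  1024-bit RSA because every correctness property is size-independent and
  safe-prime search at production sizes takes minutes.
* **Key split.** `x1` uniform in `[1, x)`, `x2 = x - x1`, over the
  integers — exponent arithmetic composes additively, no modular
  reduction is involved. The secret range `[1, n^2/2]` is kept as stated
  even though exponents act modulo the order of `g`.
* **Degenerate inputs.** A single-class dataset makes `T*N = 0`; the
  denominator decodes to zero and every path raises an undefined-AUC
  error rather than returning a number. An all-ties dataset yields
  exactly 0.5. Empty stations and missing `r1` envelopes abort the route,
  mirroring the sequential train's behavior when a station drops out.

## What the synthetic generators emulate

`gen_experiment1()` reproduces a fixed-total design: 1500 subjects
(dummies included, 80/20 real/dummy by default — the split within the
total is not prescribed, so it is configurable) spread as evenly as
possible over 3–9 stations, scores drawn from an endpoint-biased mixture
(40% Beta(0.5, 8), 40% Beta(8, 0.5), 20% uniform — the shape mimics
well-separated classifier outputs; only "mass near 0 and 1" is
essential), Bernoulli(0.5) labels. `gen_experiment2()` fixes three
stations and draws uniform scores — the worst case for the exact
protocol, since almost every score is a distinct threshold.
`gen_fixture()` provides analytic endpoints: perfect separation (AUC
exactly 1), chance labels (AUC 0.5 in expectation), all-ties, and a
single-class error fixture.

What these generators do *not* emulate: real classifier score
distributions with heavy repeats, covariate shift between sites, class
imbalance beyond the configurable label rate, or missing/corrupt station
data. Passing tests therefore demonstrate protocol correctness — the
encrypted computation equals its plaintext counterpart — on any data of
this shape, not classifier quality on real cohorts; correctness is,
however, distribution-free by construction, since every step is exact
integer arithmetic on counts.

## Problem sizes used in the checks

The acceptance suite replays the synthetic designs at the protocol's
test key sizes: the fixed-total design at 512-bit keys (70 runs: 3–9
stations × 10 replicates of 1500 subjects), the growing-size design at
256-bit keys (500–2000 subjects, 10 replicates each), 50 chance-level
runs of 2000 pooled samples, and 100 randomized multi-station instances
checked against the plaintext oracles at 1e-12. One key pair per design
is generated and reused across replicates — key generation does not
interact with any assertion, and fresh session keys, mask bases and
blinders are drawn every run.

## Known limitations

* Semi-honest model only; no protection if the proxy colludes with a
  station (the shares then reconstruct `x`). Threshold decryption or MPC
  replacements for the proxy are out of scope.
* The proxy learns the number of unique thresholds `S` and the masked
  order statistics; dummy injection blurs but does not formally bound
  what the order statistics reveal.
* Paillier ciphertexts here are not integrity-protected; a malicious
  (rather than curious) proxy could corrupt results undetected.
* The simulation executes all parties in one process; it demonstrates
  protocol correctness, not transport security.
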