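# ppauc — privacy-preserving computation of the global ROC AUC

`ppauc` evaluates a binary classifier whose prediction scores and true
labels are distributed across several *data stations* — hospitals, data
integration centers, study sites — that are not allowed to pool raw data.
It computes the global area under the ROC curve (AUC) without any party
learning another station's scores, labels, or even intermediate counts,
using two multi-party protocols run as a local simulation:

* **DPPE-AUC** (exact): computes the tie-aware trapezoidal AUC

  $$\mathcal{A} \;=\; \frac{1}{2\,T\,N}\sum_{i=1}^{S}
      \bigl(TP[i]+TP[i-1]\bigr)\,\bigl(FP[i]-FP[i-1]\bigr),$$

  over the $S$ unique thresholds of the pooled scores ($TP$, $FP$ the
  cumulative true/false positives, $T$, $N$ the class totals,
  $TP[0]=FP[0]=0$), *exactly* — the recovered value equals the plaintext
  AUC of the pooled data up to one final floating division.
* **DPPA-AUC** (approximate): evaluates the same trapezoid on a fixed grid
  of $K$ decision points (default $K = 100$), trading a small bias for
  station-side work independent of the sample count.

## How it works

Each station masks its fixed-point scores with a shared order- and
tie-preserving transform $s \mapsto r_1 s + (s \bmod r_1)$ and encrypts
its label and flag bits under a modified Paillier cryptosystem with public
key $(n, g, h = g^x)$, $n$ a product of two safe primes. Injected *dummy
samples* (label = 0, flag = 0, scores resampled from the station's own
values) hide each station's score distribution without affecting the
result. A semi-honest **proxy** sorts the pooled masked table, accumulates
encrypted cumulative counts per unique threshold, blinds the AUC's
numerator and denominator with randomized encodings of products
$(x_1+r_1,\, x_2+r_2,\, r_2x_1+r_1x_2+r_1r_2)$ plus a zero-sum additive
blinder, and *partially decrypts* the results with its additive key share
$x_{(0)}$. Any station finishes decryption with the complementary share
$x_{(1)}$ ($x = x_{(0)} + x_{(1)}$) and evaluates

$$\text{AUC} \;=\; \frac{\sum_i N_1[i]\,N_2[i] - N_3}{2\,(D_1 D_2 - D_3)},$$

in exact big-integer arithmetic; every blinding factor cancels
algebraically. No single party — station or proxy — can decrypt alone, and
the protocol assumes semi-honest parties with no proxy–station collusion.

## Worked example

```r
library(ppauc)
set.seed(1)

# three stations with 40 real samples each; labels independent of scores
data <- gen_fixture("random", n = 120, n_stations = 3)

# 256-bit Paillier / 1024-bit RSA keys: correctness is size-independent,
# production deployments would use the 3072/4096-bit defaults
cfg  <- ppauc_config(n_stations = 3, paillier_bits = 256, rsa_bits = 1024)
keys <- init_keys(cfg)

res <- run_simulation(data, "dppe", cfg, keys = keys)
res$auc
#> [1] 0.5106027
res$report$S          # unique thresholds the proxy aggregated over
#> [1] 120
res$report$m_total    # pooled rows including injected dummies
#> [1] 144

# the plaintext oracle on the pooled real samples agrees exactly
pooled <- do.call(rbind, data)
exact_auc(pooled$score, pooled$label)
#> [1] 0.5106027

# the approximate protocol on a 100-point threshold grid
run_simulation(data, "dppa", cfg, keys = keys)$auc
#> [1] 0.5107422
threshold_auc(pooled$score, pooled$label, decision_points(100))
#> [1] 0.5107422
```

`run_simulation()` executes the whole route in one process. The same
route can be driven file-by-file through serialized train states
(`init_keys()` → `station_step()` → `proxy_step()` →
`finalize_station()`, with `write_train_state()` / `read_train_state()`
between stages), or from the shell via the thin CLI in
`inst/scripts/ppauc.R`.

## Package layout

* `R/paillier.R` — modified Paillier: safe primes, keygen, encryption,
  additive key splitting, homomorphic add / scalar-multiply / subtract.
* `R/envelope.R` — AES-GCM + HMAC authenticated envelopes, RSA key
  wrapping with key confirmation.
* `R/randomized-encoding.R` — perfect randomized encoding of products.
* `R/masking.R` — fixed-point scores, the multiplicative mask, dummies.
* `R/auc-oracle.R` — plaintext exact, pair-counting, and fixed-threshold
  AUC references.
* `R/station.R`, `R/proxy.R` — the two protocol sides.
* `R/orchestrator.R`, `R/serialize.R` — route simulation, CSV input,
  train-state JSON.
* `R/synthetic.R` — scenario generators and edge-case fixtures.
* `vignettes/privacy-preserving-auc.Rmd` — the methods vignette.
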