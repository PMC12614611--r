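# Modified Paillier cryptosystem with additively split secret key.
#
# Public key (n, g, h = g^x mod n^2) with n = z*y a product of two safe
# primes; g = -a^(2n) mod n^2 has multiplicative order dividing
# (z-1)(y-1)/2. Encryption of m in Z_n with random r in [1, n/4]:
#   c1 = g^r mod n^2,  c2 = h^r * (1 + m*n) mod n^2.
# Decryption: m = ((c2 * (c1^x)^-1 mod n^2) - 1) / n. The secret exponent x
# splits additively, x = x1 + x2 over the integers, so a proxy holding x1 can
# partially decrypt (c1, c2) -> (c1, c2 / c1^x1) and any holder of x2 can
# finish, without either share decrypting alone.

# small primes for trial division before Miller-Rabin
.small_primes <- local({
  n <- 2:1000
  is_p <- rep(TRUE, length(n))
  for (i in seq_along(n)) {
    if (!is_p[i]) next
    v <- n[i]
    if (v * v > 1000) next
    is_p[n %% v == 0 & n != v] <- FALSE
  }
  n[is_p]
})

.get_small_primes_bn <- function() {
  if (is.null(.ppauc_env$small_primes_bn))
    .ppauc_env$small_primes_bn <- lapply(as.character(.small_primes), openssl::bignum)
  .ppauc_env$small_primes_bn
}

# TRUE if v has a small prime factor and is not itself that prime
.has_small_factor <- function(v) {
  for (spb in .get_small_primes_bn()) {
    if (bn_is_zero(v %% spb) && !(v == spb)) return(TRUE)
  }
  FALSE
}

# Miller-Rabin with random bases from R's RNG. Probabilistic; 40 rounds gives
# error probability <= 4^-40, standard practice for protocol key material.
mr_is_prime <- function(p, rounds = 40L) {
  p <- bn(p)
  two <- bn(2)
  if (p < two) return(FALSE)
  for (spb in .get_small_primes_bn()) {
    if (p == spb) return(TRUE)
    if (bn_is_zero(p %% spb)) return(FALSE)
  }
  pm1 <- p - bn_one()
  d <- pm1
  s <- 0L
  while (bn_is_zero(d %% two)) { d <- d %/% two; s <- s + 1L }
  for (i in seq_len(rounds)) {
    a <- bn_rand_below(pm1, min = 2)
    x <- openssl::bignum_mod_exp(a, d, p)
    if (x == bn_one() || x == pm1) next
    composite <- TRUE
    r <- 1L
    while (r < s) {
      x <- openssl::bignum_mod_exp(x, two, p)
      if (x == pm1) { composite <- FALSE; break }
      r <- r + 1L
    }
    if (composite) return(FALSE)
  }
  TRUE
}

#' Generate a safe prime
#'
#' Searches for a prime `p` of exactly `bits` bits such that `(p - 1) / 2` is
#' also prime. Candidates are drawn from R's RNG (so the search is
#' reproducible under [set.seed()]), forced to `p = 3 (mod 4)`, pre-filtered
#' by trial division, and confirmed with Miller-Rabin.
#'
#' @param bits bit length of the prime, at least 5.
#' @param max_attempts candidate budget before giving up; exhaustion signals
#'   that the bit budget is too small for the search.
#' @return an `openssl::bignum` safe prime.
#' @export
generate_safe_prime <- function(bits, max_attempts = 50000L) {
  stopifnot(bits >= 5)
  two <- bn(2)
  for (i in seq_len(max_attempts)) {
    p <- bn_rand_bits(bits)
    # force p odd and p = 3 (mod 4): a safe prime > 5 has q = (p-1)/2 odd
    p <- p - (p %% bn(4)) + bn(3)
    if (bn_bits(p) != bits) next
    q <- p %/% two
    if (.has_small_factor(p) || .has_small_factor(q)) next
    # cheap screen on q first (safe-prime condition fails most often there)
    if (mr_is_prime(q, rounds = 8L) && mr_is_prime(p) && mr_is_prime(q)) return(p)
  }
  stop("safe-prime search exhausted after ", max_attempts,
       " attempts; increase the bit budget or attempt bound")
}

#' Check the safe-prime property
#'
#' @param p candidate integer (number, decimal string or bignum).
#' @return `TRUE` iff both `p` and `(p-1)/2` are (probable) primes.
#' @export
is_safe_prime <- function(p) {
  p <- bn(p)
  mr_is_prime(p) && mr_is_prime((p - bn_one()) %/% bn(2))
}

new_paillier_pubkey <- function(n, g, h, bits) {
  # precompute the encryption-randomness sampler parameters for r in [1, n/4]
  # and the (1 + n) factor used when encrypting the plaintext bit 1
  r_bound <- n %/% openssl::bignum("4") + bn_one()
  r_bits <- bn_bits(r_bound)
  structure(list(n = n, g = g, h = h, n2 = n * n, bits = bits,
                 one_plus_n = bn_one() + n,
                 r_bound = r_bound,
                 r_nbytes = (r_bits + 7L) %/% 8L,
                 r_topmask = as.raw(bitwShiftL(1L, ((r_bits - 1L) %% 8L) + 1L) - 1L)),
            class = "paillier_pubkey")
}

# fresh encryption randomness r in [1, n/4], using the key's precomputed
# sampler parameters
.fresh_r <- function(pk) {
  repeat {
    r <- as.raw(sample.int(256L, pk$r_nbytes, replace = TRUE) - 1L)
    r[1] <- r[1] & pk$r_topmask
    v <- openssl::bignum(r)
    if (v < pk$r_bound && !bn_is_zero(v)) return(v)
  }
}

#' @export
print.paillier_pubkey <- function(x, ...) {
  cat(sprintf("<paillier_pubkey> %d-bit modulus n (n = z*y, safe primes)\n", x$bits))
  invisible(x)
}

#' @export
print.paillier_privkey <- function(x, ...) {
  cat("<paillier_privkey> secret exponent x in [1, n^2/2]\n")
  invisible(x)
}

#' @export
print.paillier_keyshare <- function(x, ...) {
  cat(sprintf("<paillier_keyshare> index %d (additive share of x)\n", x$index))
  invisible(x)
}

# internal: assemble a keypair from given safe primes (toy keys in tests)
paillier_key_from_primes <- function(z, y, x = NULL) {
  z <- bn(z); y <- bn(y)
  n <- z * y
  n2 <- n * n
  half_order <- ((z - bn_one()) * (y - bn_one())) %/% bn(2)
  repeat {
    a <- bn_rand_below(n2, min = 2)
    # a must be invertible mod n^2; g = -a^(2n) mod n^2
    ok <- tryCatch({ openssl::bignum_mod_inv(a, n2); TRUE },
                   error = function(e) FALSE)
    if (!ok) next
    g <- n2 - openssl::bignum_mod_exp(a, bn(2) * n, n2)
    if (bn_is_zero(g) || g == bn_one()) next
    if (openssl::bignum_mod_exp(g, half_order, n2) == bn_one()) break
  }
  if (is.null(x)) x <- bn_rand_below(n2 %/% bn(2) + bn_one(), min = 1)
  x <- bn(x)
  h <- openssl::bignum_mod_exp(g, x, n2)
  list(pk = new_paillier_pubkey(n, g, h, bn_bits(n)),
       sk = structure(list(x = x), class = "paillier_privkey"))
}

#' Generate a modified Paillier key pair
#'
#' Draws two distinct safe primes of `bits/2` bits each, forms `n = z*y`,
#' picks `g = -a^(2n) mod n^2` for a random invertible `a` (so the order of
#' `g` divides `(z-1)(y-1)/2`), draws the secret exponent `x` uniformly from
#' `[1, n^2/2]` and publishes `h = g^x mod n^2`. All randomness comes from
#' R's RNG, so key generation is reproducible under [set.seed()].
#'
#' @param bits bit length of the modulus `n`; the protocol default is 3072.
#'   Correctness of every operation is size-independent, so test and
#'   simulation code typically uses 128-512 bits.
#' @return a list with elements `pk` (`paillier_pubkey`) and `sk`
#'   (`paillier_privkey`).
#' @examples
#' set.seed(1)
#' keys <- paillier_keygen(bits = 64)
#' ct <- paillier_encrypt(keys$pk, 42)
#' paillier_decrypt(ct, keys$sk, keys$pk)
#' @export
paillier_keygen <- function(bits = 3072) {
  stopifnot(bits >= 16)
  half <- bits %/% 2L
  z <- generate_safe_prime(half)
  repeat {
    y <- generate_safe_prime(half)
    if (!(y == z)) break
  }
  paillier_key_from_primes(z, y)
}

#' Split a Paillier secret key into two additive shares
#'
#' Draws `x1` uniformly from `[1, x)` and sets `x2 = x - x1`, so that
#' `x = x1 + x2` over the integers. Share 0 goes to the proxy (partial
#' decryption), share 1 to the data stations (final decryption).
#'
#' @param sk a `paillier_privkey`.
#' @return list of two `paillier_keyshare` objects with indices 0 and 1.
#' @export
paillier_split_key <- function(sk) {
  x <- sk$x
  stopifnot(x > bn_one())
  x1 <- bn_rand_below(x, min = 1)
  x2 <- x - x1
  list(structure(list(index = 0L, value = x1), class = "paillier_keyshare"),
       structure(list(index = 1L, value = x2), class = "paillier_keyshare"))
}

new_ciphertext <- function(c1, c2, partial = FALSE) {
  out <- list(c1 = c1, c2 = c2, partial = partial)
  class(out) <- "paillier_ciphertext"
  out
}

#' @export
print.paillier_ciphertext <- function(x, ...) {
  cat(sprintf("<paillier_ciphertext>%s c1=%s... c2=%s...\n",
              if (x$partial) " (partially decrypted)" else "",
              substr(as.character(x$c1), 1, 12),
              substr(as.character(x$c2), 1, 12)))
  invisible(x)
}

# operation counters used for the complexity contract (see ppauc_op_counts);
# kept as separate scalars - updating a named vector would copy it on every
# homomorphic operation
.ppauc_env <- new.env(parent = emptyenv())
.op_names <- c("encrypt", "add", "scalar_mul", "partial_decrypt", "decrypt")
for (.op in .op_names) .ppauc_env[[.op]] <- 0
rm(.op)

.count_op <- function(what) {
  .ppauc_env[[what]] <- .ppauc_env[[what]] + 1
  invisible(NULL)
}

#' Homomorphic operation counters
#'
#' The package counts every Paillier encryption, homomorphic addition,
#' scalar multiplication and (partial) decryption it performs; the counts
#' back the complexity contract of the two protocols (station work linear in
#' samples for the exact protocol, sample-independent for the fixed-threshold
#' approximation).
#'
#' @param reset if `TRUE`, zero the counters after reading them.
#' @return named numeric vector of operation counts.
#' @export
ppauc_op_counts <- function(reset = FALSE) {
  out <- vapply(.op_names, function(nm) .ppauc_env[[nm]], numeric(1))
  if (reset) for (nm in .op_names) .ppauc_env[[nm]] <- 0
  out
}

#' Encrypt a message under a modified Paillier public key
#'
#' @param pk a `paillier_pubkey`.
#' @param m message; a non-negative residue in `[0, n)` (numbers, decimal
#'   strings or bignums). Use [encode_signed()] first for negative values.
#' @return a `paillier_ciphertext` with fresh randomness `r` in `[1, n/4]`.
#' @export
paillier_encrypt <- function(pk, m) {
  # bits dominate protocol traffic (labels, flags); fast-path them
  if (is.numeric(m) && length(m) == 1L && !is.na(m) && (m == 0 || m == 1)) {
    blind <- if (m == 1) pk$one_plus_n else NULL
  } else {
    m <- bn(m)
    if (!(m < pk$n)) stop("plaintext residue outside [0, n); encode upstream")
    blind <- if (bn_is_zero(m)) NULL else bn_one() + m * pk$n
  }
  r <- .fresh_r(pk)
  c1 <- openssl::bignum_mod_exp(pk$g, r, pk$n2)
  c2 <- openssl::bignum_mod_exp(pk$h, r, pk$n2)
  if (!is.null(blind)) c2 <- (c2 * blind) %% pk$n2
  .count_op("encrypt")
  new_ciphertext(c1, c2)
}

#' Decrypt a modified Paillier ciphertext
#'
#' With the full secret key this inverts [paillier_encrypt()]; with key
#' share 1 it finishes a ciphertext that the proxy has passed through
#' [paillier_partial_decrypt()].
#'
#' @param ct a `paillier_ciphertext`.
#' @param key a `paillier_privkey` (full `x`, for `partial = FALSE`
#'   ciphertexts) or the index-1 `paillier_keyshare` (for partially
#'   decrypted ones).
#' @param pk the matching public key.
#' @return the plaintext residue as an `openssl::bignum` in `[0, n)`.
#' @seealso [decode_signed()] to map residues back to signed integers.
#' @export
paillier_decrypt <- function(ct, key, pk) {
  x <- if (inherits(key, "paillier_privkey")) {
    if (ct$partial) stop("ciphertext is partially decrypted; use key share 1")
    key$x
  } else if (inherits(key, "paillier_keyshare")) {
    if (key$index != 1L) stop("final decryption requires key share index 1")
    if (!ct$partial) stop("ciphertext not partially decrypted; share 1 alone cannot decrypt")
    key$value
  } else bn(key)
  u <- openssl::bignum_mod_exp(ct$c1, x, pk$n2)
  t <- (ct$c2 * openssl::bignum_mod_inv(u, pk$n2)) %% pk$n2
  tm1 <- t - bn_one()
  if (!bn_is_zero(tm1 %% pk$n))
    stop("decryption failed: ciphertext corrupted or wrong key")
  .count_op("decrypt")
  tm1 %/% pk$n
}

#' Partially decrypt a ciphertext with key share 0 (proxy re-encryption)
#'
#' Computes `(c1, c2 / c1^x1 mod n^2)` and marks the result partial; the
#' plaintext then only becomes recoverable with share 1.
#'
#' @param ct a `paillier_ciphertext` with `partial = FALSE`.
#' @param share the index-0 `paillier_keyshare`.
#' @param pk the public key.
#' @return a `paillier_ciphertext` with `partial = TRUE`.
#' @export
paillier_partial_decrypt <- function(ct, share, pk) {
  if (ct$partial) stop("ciphertext already partially decrypted")
  if (!inherits(share, "paillier_keyshare") || share$index != 0L)
    stop("partial decryption requires key share index 0")
  x1 <- bn(share$value)
  c2 <- if (bn_is_zero(x1)) ct$c2 else {
    u <- openssl::bignum_mod_exp(ct$c1, x1, pk$n2)
    (ct$c2 * openssl::bignum_mod_inv(u, pk$n2)) %% pk$n2
  }
  .count_op("partial_decrypt")
  new_ciphertext(ct$c1, c2, partial = TRUE)
}

.check_pair <- function(a, b) {
  if (!identical(a$partial, b$partial))
    stop("cannot combine ciphertexts with different partial-decryption status")
}

#' Homomorphic addition of two ciphertexts
#'
#' Component-wise multiplication modulo `n^2`; decrypts to `m1 + m2 (mod n)`.
#'
#' @param pk public key; `a`, `b` ciphertexts under `pk` with the same
#'   partial status.
#' @return a `paillier_ciphertext`.
#' @export
ph_add <- function(pk, a, b) {
  .check_pair(a, b)
  .count_op("add")
  new_ciphertext((a$c1 * b$c1) %% pk$n2, (a$c2 * b$c2) %% pk$n2, a$partial)
}

#' Homomorphic addition of a plaintext constant
#'
#' Folds a known constant `k` into a ciphertext by multiplying `c2` with
#' `(1 + k*n)`; equivalent to adding an encryption of `k` with randomness 0.
#' `k` may be negative (reduced into the upper residue range).
#'
#' @param pk public key; `ct` a ciphertext; `k` integer-like or `sbig`.
#' @return a `paillier_ciphertext`.
#' @export
ph_add_plain <- function(pk, ct, k) {
  kr <- sbig_mod(sbig(k), pk$n)
  .count_op("add")
  new_ciphertext(ct$c1, (ct$c2 * (bn_one() + kr * pk$n)) %% pk$n2, ct$partial)
}

#' Homomorphic multiplication by a plaintext scalar
#'
#' Raises both components to the `k`-th power modulo `n^2`; decrypts to
#' `m*k (mod n)`. `k` may be any residue in `[0, n)` - in particular
#' `k = n - 1` negates the plaintext - or a negative integer, which is
#' applied through the ciphertext group inverse (same plaintext effect,
#' cheaper than a full-width exponent).
#'
#' @param pk public key; `ct` a ciphertext; `k` integer-like or `sbig`.
#' @return a `paillier_ciphertext`.
#' @export
ph_scalar_mul <- function(pk, ct, k) {
  k <- sbig(k)
  if (!(k$mag < pk$n)) stop("|k| outside [0, n)")
  .count_op("scalar_mul")
  c1 <- ct$c1; c2 <- ct$c2
  if (k$neg) {
    # group inverse then the small positive exponent: decrypts identically
    # to exponentiation by n - |k| but avoids a full-width exponent
    c1 <- openssl::bignum_mod_inv(c1, pk$n2)
    c2 <- openssl::bignum_mod_inv(c2, pk$n2)
  }
  if (bn_is_one(k$mag)) return(new_ciphertext(c1, c2, ct$partial))
  if (bn_is_zero(k$mag)) return(new_ciphertext(bn_one(), bn_one(), ct$partial))
  new_ciphertext(openssl::bignum_mod_exp(c1, k$mag, pk$n2),
                 openssl::bignum_mod_exp(c2, k$mag, pk$n2), ct$partial)
}

#' Homomorphic subtraction
#'
#' `a - b` as `add(a, scalar_mul(b, -1))`; decrypts to `m_a - m_b (mod n)`.
#'
#' @inheritParams ph_add
#' @return a `paillier_ciphertext`.
#' @export
ph_sub <- function(pk, a, b) ph_add(pk, a, ph_scalar_mul(pk, b, -1))

#' Signed plaintext encoding
#'
#' Maps a signed integer `v` with `|v| < n/2` to its residue mod `n`
#' (upper-half convention: negatives land in `(n/2, n)`); `decode_signed`
#' inverts the map.
#'
#' @param v signed integer-like or `sbig`.
#' @param n the Paillier modulus (bignum or number).
#' @return `encode_signed`: an `openssl::bignum` residue in `[0, n)`.
#' @export
encode_signed <- function(v, n) {
  n <- bn(n)
  v <- sbig(v)
  if (!((v$mag + v$mag) < n))
    stop("|v| >= n/2: signed encoding would wrap; modulus too small for this magnitude")
  sbig_mod(v, n)
}

#' @rdname encode_signed
#' @param residue a residue in `[0, n)`.
#' @return `decode_signed`: an `sbig` in `(-n/2, n/2]`.
#' @export
decode_signed <- function(residue, n) {
  n <- bn(n)
  residue <- bn(residue)
  if (residue > n %/% .bn_const$two) new_sbig(TRUE, n - residue)
  else new_sbig(FALSE, residue)
}
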