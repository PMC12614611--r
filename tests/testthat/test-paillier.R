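# Modified Paillier cryptosystem: safe primes, key structure, round trips,
# split-key proxy re-encryption, homomorphic arithmetic, signed encoding.

test_that("the only 5-bit safe prime is found and safe-primality is decided correctly", {
  # exhaustive ground truth: 5-bit primes are 17, 19, 23, 29, 31 and only
  # 23 has a prime (p-1)/2
  fivebit <- Filter(function(p) ppauc:::mr_is_prime(p), 16:31)
  truth <- Filter(function(p) ppauc:::mr_is_prime((p - 1) / 2), fivebit)
  expect_identical(truth, 23L)
  set.seed(1)
  expect_true(generate_safe_prime(5) == 23)
  expect_true(is_safe_prime(23))
  expect_false(is_safe_prime(13))  # (13-1)/2 = 6 is not prime
  set.seed(2)
  p <- generate_safe_prime(16)
  expect_identical(ppauc:::bn_bits(p), 16L)
  expect_true(is_safe_prime(p))
})

test_that("toy key over z = 11, y = 23 has the advertised structure", {
  k <- toy_keys()
  expect_true(k$pk$n == 253)
  # g has order dividing (z-1)(y-1)/2 = 110 modulo n^2
  expect_true(openssl::bignum_mod_exp(k$pk$g, bn(110), k$pk$n2) == 1)
  expect_true(openssl::bignum_mod_exp(k$pk$g, k$sk$x, k$pk$n2) == k$pk$h)
})

test_that("generated keys satisfy h = g^x and g's order divides (z-1)(y-1)/2", {
  set.seed(3)
  for (i in 1:2) {
    z <- generate_safe_prime(32)
    repeat { y <- generate_safe_prime(32); if (!(y == z)) break }
    k <- ppauc:::paillier_key_from_primes(z, y)
    half_order <- ((z - bn(1)) * (y - bn(1))) %/% bn(2)
    expect_true(openssl::bignum_mod_exp(k$pk$g, half_order, k$pk$n2) == 1)
    expect_true(openssl::bignum_mod_exp(k$pk$g, k$sk$x, k$pk$n2) == k$pk$h)
    expect_true(k$sk$x <= k$pk$n2 %/% bn(2))
  }
})

test_that("keygen is deterministic under a seed", {
  set.seed(77); k1 <- paillier_keygen(64)
  set.seed(77); k2 <- paillier_keygen(64)
  expect_true(k1$pk$n == k2$pk$n && k1$pk$g == k2$pk$g && k1$sk$x == k2$sk$x)
})

test_that("encryption round-trips exhaustively on the toy key", {
  k <- toy_keys()
  set.seed(4)
  for (m in 0:252)
    expect_true(paillier_decrypt(paillier_encrypt(k$pk, m), k$sk, k$pk) == m)
})

test_that("encryption is randomized and rejects out-of-range plaintexts", {
  k <- toy_keys()
  set.seed(5)
  a <- paillier_encrypt(k$pk, 42); b <- paillier_encrypt(k$pk, 42)
  expect_false(a$c1 == b$c1 && a$c2 == b$c2)
  expect_error(paillier_encrypt(k$pk, 253), "outside")
  # tampering c2 decrypts to garbage or fails; integrity is not provided
  ct <- paillier_encrypt(k$pk, 7)
  ct$c2 <- (ct$c2 * bn(2)) %% k$pk$n2
  got <- tryCatch(paillier_decrypt(ct, k$sk, k$pk), error = function(e) NULL)
  expect_false(isTRUE(got == 7))
})

test_that("additive key splits decrypt via partial-then-final equal to direct", {
  k <- toy_keys()
  set.seed(6)
  for (split in 1:10) {
    sh <- paillier_split_key(k$sk)
    expect_true(bn(sh[[1]]$value) + bn(sh[[2]]$value) == k$sk$x)
    for (m in sample(0:252, 10)) {
      ct <- paillier_encrypt(k$pk, m)
      pd <- paillier_partial_decrypt(ct, sh[[1]], k$pk)
      expect_true(pd$partial)
      expect_true(paillier_decrypt(pd, sh[[2]], k$pk) == m)
    }
  }
})

test_that("partial decryption misuse is rejected and a zero share is the identity", {
  k <- toy_keys()
  set.seed(7)
  ct <- paillier_encrypt(k$pk, 9)
  sh <- paillier_split_key(k$sk)
  pd <- paillier_partial_decrypt(ct, sh[[1]], k$pk)
  expect_error(paillier_partial_decrypt(pd, sh[[1]], k$pk), "already")
  expect_error(paillier_decrypt(ct, sh[[2]], k$pk), "not partially")
  expect_error(paillier_decrypt(pd, k$sk, k$pk), "share 1")
  zero_share <- structure(list(index = 0L, value = bn(0)),
                          class = "paillier_keyshare")
  pz <- paillier_partial_decrypt(ct, zero_share, k$pk)
  expect_true(pz$c1 == ct$c1 && pz$c2 == ct$c2 && pz$partial)
})

test_that("homomorphic add, scalar-multiply and subtract match plaintext arithmetic mod n", {
  k <- toy_keys()
  set.seed(8)
  for (i in 1:100) {
    m1 <- sample(0:252, 1); m2 <- sample(0:252, 1)
    s <- paillier_decrypt(ph_add(k$pk, paillier_encrypt(k$pk, m1),
                                 paillier_encrypt(k$pk, m2)), k$sk, k$pk)
    expect_true(s == (m1 + m2) %% 253)
  }
  for (i in 1:50) {
    m <- sample(0:252, 1); c <- sample(0:252, 1)
    p <- paillier_decrypt(ph_scalar_mul(k$pk, paillier_encrypt(k$pk, m), c),
                          k$sk, k$pk)
    expect_true(p == (m * c) %% 253)
    m2 <- sample(0:100, 1); m1 <- sample(0:100, 1)
    d <- paillier_decrypt(ph_sub(k$pk, paillier_encrypt(k$pk, m1),
                                 paillier_encrypt(k$pk, m2)), k$sk, k$pk)
    expect_identical(as.numeric(decode_signed(d, k$pk$n)), as.numeric(m1 - m2))
  }
  # identities
  ct <- paillier_encrypt(k$pk, 3)
  expect_true(paillier_decrypt(ph_scalar_mul(k$pk, ct, 4), k$sk, k$pk) == 12)
  expect_true(paillier_decrypt(ph_scalar_mul(k$pk, ct, 1), k$sk, k$pk) == 3)
  expect_identical(as.numeric(decode_signed(
    paillier_decrypt(ph_scalar_mul(k$pk, ct, 252), k$sk, k$pk), k$pk$n)), -3)
  expect_true(paillier_decrypt(ph_add(k$pk, ct, paillier_encrypt(k$pk, 0)),
                               k$sk, k$pk) == 3)
  expect_true(paillier_decrypt(ph_sub(k$pk, ct, ct), k$sk, k$pk) == 0)
  expect_identical(as.numeric(decode_signed(paillier_decrypt(
    ph_add_plain(k$pk, ct, -5), k$sk, k$pk), k$pk$n)), -2)
  pd <- paillier_partial_decrypt(ct, paillier_split_key(toy_keys()$sk)[[1]], k$pk)
  expect_error(ph_add(k$pk, ct, pd), "partial")
})

test_that("signed encoding maps the upper residue range to negatives", {
  n <- toy_keys()$pk$n
  expect_true(encode_signed(-1, n) == 252)
  expect_identical(as.numeric(decode_signed(bn(252), n)), -1)
  expect_true(encode_signed(0, n) == 0)
  for (v in as.numeric(-126:126))
    expect_identical(as.numeric(decode_signed(encode_signed(v, n), n)), v)
  expect_error(encode_signed(127, n), "n/2")
  expect_error(encode_signed(-127, n), "n/2")
})
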