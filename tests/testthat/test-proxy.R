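# Proxy aggregation: merge/sort, encrypted cumulative counts with dummy
# cancellation, randomized-encoding blinding, partial decryption, and the
# approximate-protocol aggregation path.

make_payloads <- function(data, k, proxy) {
  pls <- list()
  n <- length(data)
  pls[[1]] <- dppe_station_step(data[[1]], k$pk, proxy$pubkey, 1L,
                                downstream_pubkeys = if (n > 1)
                                  lapply(seq_len(n)[-1], function(i) test_rsa(i)$pubkey))
  if (n > 1) for (i in 2:n)
    pls[[i]] <- dppe_station_step(data[[i]], k$pk, proxy$pubkey, i,
                                  r1_envelope = pls[[1]]$r1_envelopes[[i - 1L]],
                                  rsa_privkey = test_rsa(i))
  pls
}

test_that("merged tables pool, sort descending, and carry only ciphertexts", {
  set.seed(60)
  k <- test_keys(256); proxy <- test_rsa(99L)
  data <- lapply(1:3, function(i)
    data.frame(score = round(runif(4), 2), label = rbinom(4, 1, 0.5), flag = 1L))
  data[[2]]$score[1] <- data[[1]]$score[1]  # force an inter-station tie
  tab <- merge_and_sort(make_payloads(data, k, proxy), proxy)
  expect_identical(tab$m, 12L)
  key <- ppauc:::.score_keys(tab$masked)
  expect_true(all(diff(order(key, decreasing = TRUE, method = "radix")) == 1))
  expect_identical(sum(duplicated(tab$masked)),
                   sum(duplicated(unlist(lapply(data, `[[`, "score")))))
  expect_true(all(vapply(tab$enc_labels, inherits, logical(1),
                         "paillier_ciphertext")))
  expect_true(all(vapply(tab$enc_flags, inherits, logical(1),
                         "paillier_ciphertext")))
})

test_that("a tampered payload is rejected naming the offending station", {
  set.seed(61)
  k <- test_keys(256); proxy <- test_rsa(99L)
  data <- lapply(1:2, function(i)
    data.frame(score = runif(3), label = rbinom(3, 1, 0.5), flag = 1L))
  pls <- make_payloads(data, k, proxy)
  pls[[2]]$enc_masked_scores[20] <- xor(pls[[2]]$enc_masked_scores[20], as.raw(1))
  expect_error(merge_and_sort(pls, proxy), "station 2")
})

test_that("decrypted cumulative counts equal the plaintext ROC of the real samples", {
  set.seed(62)
  k <- test_keys(256); proxy <- test_rsa(99L)
  for (rep in 1:5) {
    data <- lapply(1:2, function(i) {
      real <- data.frame(score = sample(seq(0.1, 0.9, 0.1), 30, replace = TRUE),
                         label = rbinom(30, 1, 0.5), flag = 1L)
      rbind(real, make_dummies(real, sample(0:20, 1)))
    })
    tab <- merge_and_sort(make_payloads(data, k, proxy), proxy)
    cc <- cumulative_counts(tab, k$pk)
    p <- pool_real(data)
    rc <- ppauc:::roc_counts(p$score, p$label)
    expect_identical(cc$S, rc$S)  # dummies add no thresholds
    TP <- vapply(cc$enc_TP, function(ct)
      as.numeric(paillier_decrypt(ct, k$sk, k$pk)), numeric(1))
    FP <- vapply(cc$enc_FP, function(ct)
      as.numeric(decode_signed(paillier_decrypt(ct, k$sk, k$pk), k$pk$n)),
      numeric(1))
    expect_identical(TP, as.numeric(rc$TP))
    expect_identical(FP, as.numeric(rc$FP))
  }
})

test_that("denominator blinding satisfies D1*D2 - D3 = a*b*T*N exactly", {
  set.seed(63)
  k <- test_keys(256)
  for (rep in 1:5) {
    T_ <- sample(1:500, 1); N_ <- sample(1:500, 1)
    pr <- proxy_randoms(3)
    den <- blind_denominator(k$pk, paillier_encrypt(k$pk, T_),
                             paillier_encrypt(k$pk, N_), pr)
    dec <- function(ct) decode_signed(paillier_decrypt(ct, k$sk, k$pk), k$pk$n)
    got <- dec(den$D1) * dec(den$D2) - dec(den$D3)
    want <- sbig(pr$a) * sbig(pr$b) * sbig(T_) * sbig(N_)
    expect_identical(as.character(got), as.character(want))
  }
})

test_that("numerator blinding cancels to a*b*sum(sTP*dFP) and z sums to zero", {
  set.seed(64)
  k <- test_keys(256)
  for (rep in 1:3) {
    S <- sample(3:8, 1)
    TPs <- sort(sample(0:50, S)); FPs <- sort(sample(0:50, S))
    pr <- proxy_randoms(S)
    expect_identical(as.character(Reduce(`+`, pr$z, sbig(0))), "0")
    num <- blind_numerator(k$pk,
                           lapply(TPs, function(v) paillier_encrypt(k$pk, v)),
                           lapply(FPs, function(v) paillier_encrypt(k$pk, v)),
                           pr, m = 100)
    dec <- function(ct) decode_signed(paillier_decrypt(ct, k$sk, k$pk), k$pk$n)
    acc <- sbig(0)
    for (i in seq_len(S)) acc <- acc + dec(num$N1[[i]]) * dec(num$N2[[i]])
    got <- acc - dec(num$N3)
    sTP <- TPs + c(0, TPs[-S]); dFP <- FPs - c(0, FPs[-S])
    want <- sbig(pr$a) * sbig(pr$b) * sbig(sum(sTP * dFP))
    expect_identical(as.character(got), as.character(want))
  }
})

test_that("the modulus overflow guard rejects undersized keys", {
  set.seed(65)
  k128 <- local({ set.seed(1280); paillier_keygen(128) })
  pr <- proxy_randoms(5)
  cts <- lapply(1:5, function(i) paillier_encrypt(k128$pk, i))
  expect_error(blind_numerator(k128$pk, cts, cts, pr), "too small")
})

test_that("partial decryption leaves plaintexts unrecoverable with share 0 alone", {
  set.seed(66)
  k <- test_keys(256)
  sh <- paillier_split_key(k$sk)
  pr <- proxy_randoms(2)
  cts <- lapply(c(3, 7), function(v) paillier_encrypt(k$pk, v))
  num <- blind_numerator(k$pk, cts, cts, pr, m = 10)
  den <- blind_denominator(k$pk, cts[[2]], cts[[2]], pr)
  bc <- partial_decrypt_components(num, den, sh[[1]], k$pk)
  expect_true(bc$N3$partial && bc$D1$partial)
  expect_error(partial_decrypt_components(
    list(N1 = bc$N1, N2 = bc$N2, N3 = bc$N3), bc[c("D1", "D2", "D3")],
    sh[[1]], k$pk), "already")
  # share 0 alone: the "decryption" formula with x1 does not return the
  # true plaintext (x2 is nonzero with overwhelming probability)
  ct <- paillier_encrypt(k$pk, 5)
  half <- paillier_partial_decrypt(ct, sh[[1]], k$pk)
  leaked <- (half$c2 - ppauc:::bn_one()) %% k$pk$n
  expect_false(isTRUE(leaked == 0 &&
                        (half$c2 - ppauc:::bn_one()) %/% k$pk$n == 5))
})

test_that("the approximate aggregation equals its plaintext twin end-to-end", {
  set.seed(67)
  k <- test_keys(256)
  sh <- paillier_split_key(k$sk)
  D <- decision_points(25)
  for (rep in 1:3) {
    data <- lapply(1:3, function(i)
      data.frame(score = runif(30), label = rbinom(30, 1, 0.5), flag = 1L))
    data[[1]]$label[1:2] <- c(1L, 0L)
    cts <- lapply(data, function(d) dppa_station_step(d, D, k$pk))
    agg <- dppa_aggregate(cts, sh[[1]], k$pk)
    auc <- finalize_auc(agg$components, sh[[2]], k$pk)
    p <- pool_real(data)
    expect_equal(auc, threshold_auc(p$score, p$label, D), tolerance = 1e-12)
  }
  # single station reduces to the single-site approximation
  one <- dppa_station_step(data[[1]], D, k$pk)
  agg1 <- dppa_aggregate(list(one), sh[[1]], k$pk)
  expect_equal(finalize_auc(agg1$components, sh[[2]], k$pk),
               threshold_auc(data[[1]]$score, data[[1]]$label, D),
               tolerance = 1e-12)
  # mismatched grids abort
  short <- dppa_station_step(data[[2]], decision_points(10), k$pk)
  expect_error(dppa_aggregate(list(one, short), sh[[1]], k$pk), "different")
})
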