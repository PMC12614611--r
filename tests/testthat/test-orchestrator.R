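# Key lifecycle, route progression, simulation determinism, CSV and
# train-state serialization, and the operation-count complexity contract.

test_that("initialized keys reconstruct the secret exponent and are correctly addressed", {
  set.seed(70)
  cfg <- ppauc_config(n_stations = 2, paillier_bits = 64, rsa_bits = 1024)
  st <- init_keys(cfg)
  s0 <- ppauc:::unwrap_share(st$share_envelopes$proxy, st$rsa$proxy)
  s1 <- ppauc:::unwrap_share(st$share_envelopes$stations[[1]],
                             st$rsa$stations[[1]])
  expect_identical(s0$index, 0L)
  expect_identical(s1$index, 1L)
  # x1 + x2 = x: verify via h = g^(x1+x2) without access to x itself
  x <- bn(s0$value) + bn(s1$value)
  expect_true(openssl::bignum_mod_exp(st$pk$g, x, st$pk$n2) == st$pk$h)
  # wrong recipient cannot open an envelope
  expect_error(ppauc:::unwrap_share(st$share_envelopes$proxy,
                                    st$rsa$stations[[1]]))
  expect_error(ppauc:::unwrap_share(st$share_envelopes$stations[[2]],
                                    st$rsa$stations[[1]]))
})

test_that("the route enforces order and aborts on a missing station", {
  set.seed(71)
  st <- make_train_state(2)
  d <- gen_fixture("random", 20, 2)
  expect_error(proxy_step(st), "missing station|stations to have contributed")
  st <- station_step(st, d[[1]], "dppe")
  expect_error(proxy_step(st), "stations to have contributed")
  expect_error(station_step(st, d[[2]], "dppa"), "cannot change")
  st <- station_step(st, d[[2]], "dppe")
  expect_error(station_step(st, d[[1]], "dppe"), "already")
  st <- proxy_step(st)
  expect_error(proxy_step(st), "stations to have contributed")
  a1 <- finalize_station(st, 1L); a2 <- finalize_station(st, 2L)
  expect_identical(a1, a2)
})

test_that("simulations are deterministic under a seed and match the oracles", {
  st <- make_train_state(3)
  d <- gen_fixture("random", 90, 3, seed = 72)
  p <- pool_real(d)
  r1 <- run_simulation(d, "dppe", st$config, keys = st, seed = 5)
  r2 <- run_simulation(d, "dppe", st$config, keys = st, seed = 5)
  expect_identical(r1$auc, r2$auc)
  expect_identical(r1$report$S, r2$report$S)
  expect_identical(r1$report$ops, r2$report$ops)
  expect_equal(r1$auc, exact_auc(p$score, p$label), tolerance = 1e-12)
  ra <- run_simulation(d, "dppa", st$config, keys = st, seed = 5)
  expect_equal(ra$auc,
               threshold_auc(p$score, p$label, decision_points(100)),
               tolerance = 1e-12)
  expect_identical(ra$report$K, 100L)
})

test_that("station-side encryption work scales with samples only for the exact protocol", {
  set.seed(73)
  k <- test_keys(256); proxy <- test_rsa(99L)
  D <- decision_points(40)
  count_ops <- function(expr) {
    ppauc_op_counts(reset = TRUE)
    force(expr)
    ppauc_op_counts(reset = TRUE)
  }
  mk <- function(m) data.frame(score = runif(m), label = rbinom(m, 1, 0.5),
                               flag = 1L)
  e1 <- count_ops(dppe_station_step(mk(50), k$pk, proxy$pubkey, 1L))
  e2 <- count_ops(dppe_station_step(mk(100), k$pk, proxy$pubkey, 1L))
  expect_identical(e1[["encrypt"]], 100)  # one label + one flag per sample
  expect_identical(e2[["encrypt"]], 200)
  a1 <- count_ops(dppa_station_step(mk(50), D, k$pk))
  a2 <- count_ops(dppa_station_step(mk(400), D, k$pk))
  expect_identical(a1[["encrypt"]], 80)   # 2K, independent of m
  expect_identical(a2[["encrypt"]], a1[["encrypt"]])
})

test_that("station CSV input validates rows and round-trips", {
  d <- data.frame(score = c(0.25, 0.5), label = c(1L, 0L), flag = 1L)
  f <- tempfile(fileext = ".csv")
  write_station_csv(d, f)
  got <- read_station_csv(f)
  expect_identical(got$score, d$score)
  expect_identical(got$label, d$label)
  writeLines(c("id,prediction,label", "1,0.5,1", "2,1.5,0"), f)
  expect_error(read_station_csv(f), "line 3")
  writeLines(c("id,prediction,label", "1,0.5,2"), f)
  expect_error(read_station_csv(f), "label.*line 2")
  writeLines(c("id,score,label", "1,0.5,1"), f)
  expect_error(read_station_csv(f), "header")
})

test_that("train states survive a JSON round trip mid-route", {
  set.seed(74)
  st <- make_train_state(2, config = ppauc_config(2, 256, 1024,
                                                  dummy_fraction = 0.25))
  d <- gen_fixture("random", 24, 2)
  st <- station_step(st, d[[1]], "dppe")
  f <- tempfile(fileext = ".json")
  write_train_state(st, f)
  st2 <- read_train_state(f)
  expect_identical(st2$stage, st$stage)
  expect_identical(st2$config, st$config)
  expect_identical(st2$payloads[[1]]$m, st$payloads[[1]]$m)
  expect_true(st2$payloads[[1]]$enc_labels[[1]]$c1 ==
                st$payloads[[1]]$enc_labels[[1]]$c1)
  expect_identical(st2$payloads[[1]]$enc_masked_scores,
                   st$payloads[[1]]$enc_masked_scores)
  # the reloaded train continues the route to the same result
  st  <- station_step(st,  d[[2]], "dppe")
  st2 <- station_step(st2, d[[2]], "dppe")
  auc  <- finalize_station(proxy_step(st))
  auc2 <- finalize_station(proxy_step(st2))
  expect_identical(auc, auc2)
  p <- pool_real(d)
  expect_equal(auc, exact_auc(p$score, p$label), tolerance = 1e-12)
})
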