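# Shared, lazily generated key material. Safe-prime generation dominates
# test runtime, so each size is generated once per test process and reused;
# every correctness property checked here is key-independent.

.key_cache <- new.env(parent = emptyenv())

# fixed toy key over the safe primes z = 11, y = 23 (n = 253): small enough
# for exhaustive plaintext sweeps
toy_keys <- function() {
  if (is.null(.key_cache$toy)) {
    set.seed(230253)
    .key_cache$toy <- ppauc:::paillier_key_from_primes(11, 23)
  }
  .key_cache$toy
}

test_keys <- function(bits = 256) {
  nm <- paste0("k", bits)
  if (is.null(.key_cache[[nm]])) {
    set.seed(bits + 7L)
    .key_cache[[nm]] <- paillier_keygen(bits)
  }
  .key_cache[[nm]]
}

test_rsa <- function(i = 1L) {
  nm <- paste0("rsa", i)
  if (is.null(.key_cache[[nm]]))
    .key_cache[[nm]] <- openssl::rsa_keygen(1024)
  .key_cache[[nm]]
}

# assemble a train_state around the cached Paillier key so pipeline tests
# skip repeated safe-prime searches; fresh key split and RSA envelopes
make_train_state <- function(n_stations, paillier_bits = 256,
                             config = ppauc_config(n_stations, paillier_bits,
                                                   1024)) {
  k <- test_keys(paillier_bits)
  shares <- paillier_split_key(k$sk)
  stations <- lapply(seq_len(n_stations), function(i) test_rsa(i))
  proxy <- test_rsa(99L)
  structure(list(
    config = config, protocol = NA_character_, stage = "init",
    route_position = 0L, pk = k$pk,
    rsa = list(stations = stations, proxy = proxy),
    share_envelopes = list(
      proxy = ppauc:::wrap_share(shares[[1]], proxy$pubkey),
      stations = lapply(stations, function(kk)
        ppauc:::wrap_share(shares[[2]], kk$pubkey))),
    payloads = list(), dppa_counts = list(), components = NULL,
    report = list()
  ), class = "train_state")
}

# pooled real samples of a station list
pool_real <- function(station_data) {
  p <- do.call(rbind, lapply(station_data, ppauc:::as_sample_frame))
  p[p$flag == 1L, ]
}

bn <- ppauc:::bn
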