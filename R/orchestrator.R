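# Train-route orchestration: key lifecycle, the sequential station -> proxy
# -> station simulation for both protocols, station CSV input, and lossless
# JSON serialization of the train state so the route can also be driven
# file-by-file (e.g. from the bundled command-line script).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Protocol configuration
#'
#' @param n_stations number of data stations.
#' @param paillier_bits Paillier modulus size; protocol default 3072.
#'   Simulations and tests use 256-512 since correctness is
#'   size-independent (128-bit keys are rejected by the overflow guard once
#'   blinders are in play).
#' @param rsa_bits RSA modulus size for the long-term station/proxy keys;
#'   protocol default 4096, simulations typically 1024.
#' @param precision fixed-point digits for score masking.
#' @param dummy_fraction dummies injected per station as a fraction of its
#'   real samples (exact protocol only).
#' @param k_thresholds number of decision points of the approximate
#'   protocol.
#' @return a `ppauc_config` list.
#' @export
ppauc_config <- function(n_stations = 3L, paillier_bits = 3072L,
                         rsa_bits = 4096L, precision = 12L,
                         dummy_fraction = 0.2, k_thresholds = 100L) {
  stopifnot(n_stations >= 1, paillier_bits >= 16, rsa_bits >= 1024,
            precision >= 0, dummy_fraction >= 0, dummy_fraction <= 1,
            k_thresholds >= 1)
  structure(list(n_stations = as.integer(n_stations),
                 paillier_bits = as.integer(paillier_bits),
                 rsa_bits = as.integer(rsa_bits),
                 precision = as.integer(precision),
                 dummy_fraction = dummy_fraction,
                 k_thresholds = as.integer(k_thresholds)),
            class = "ppauc_config")
}

# hybrid envelope for a Paillier key share (shares are far larger than one
# RSA block, so they travel under a wrapped session key)
wrap_share <- function(share, pubkey) {
  skey <- gen_sym_key()
  list(index = share$index,
       wrapped_key = wrap_key(skey, pubkey),
       body = enc_sym(as.raw(bn(share$value)), skey))
}

unwrap_share <- function(env, privkey) {
  skey <- unwrap_key(env$wrapped_key, privkey)
  structure(list(index = as.integer(env$index),
                 value = openssl::bignum(dec_sym(env$body, skey))),
            class = "paillier_keyshare")
}

#' Initialize keys and an empty train state
#'
#' Generates the Paillier key pair, splits the secret exponent into the
#' proxy share (index 0) and the stations' share (index 1), generates
#' long-term RSA key pairs for every data station and the proxy, and wraps
#' share 0 for the proxy and share 1 for each station under the respective
#' RSA public keys. The full secret exponent is discarded; from here on no
#' single party can decrypt alone.
#'
#' @param config a [ppauc_config()].
#' @return a `train_state` at stage `"init"`.
#' @export
init_keys <- function(config) {
  stopifnot(inherits(config, "ppauc_config"))
  keys <- paillier_keygen(config$paillier_bits)
  shares <- paillier_split_key(keys$sk)
  stations <- lapply(seq_len(config$n_stations),
                     function(i) gen_asym_keypair(config$rsa_bits))
  proxy <- gen_asym_keypair(config$rsa_bits)
  structure(list(
    config = config,
    protocol = NA_character_,
    stage = "init",
    route_position = 0L,
    pk = keys$pk,
    rsa = list(stations = stations, proxy = proxy),
    share_envelopes = list(
      proxy = wrap_share(shares[[1]], proxy$pubkey),
      stations = lapply(stations, function(k) wrap_share(shares[[2]], k$pubkey))),
    payloads = list(),
    dppa_counts = list(),
    components = NULL,
    report = list()
  ), class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf("<train_state> %d stations, stage '%s'%s, %d-bit Paillier key\n",
              x$config$n_stations, x$stage,
              if (!is.na(x$protocol)) paste0(" (", x$protocol, ")") else "",
              x$pk$bits))
  invisible(x)
}

# reset per-run fields so one expensive key setup can back many runs
reset_train_state <- function(state) {
  state$stage <- "init"
  state$route_position <- 0L
  state$protocol <- NA_character_
  state$payloads <- list()
  state$dppa_counts <- list()
  state$components <- NULL
  state$report <- list()
  state
}

#' Run one station's protocol step on the train
#'
#' Advances the route by one data station: injects dummy samples
#' (exact protocol; `dummy_fraction` of the station's real rows), executes
#' the station protocol, and appends the encrypted contribution to the
#' train state.
#'
#' @param state a `train_state`.
#' @param samples the station's real samples (`score`, `label`).
#' @param method `"dppe"` (exact) or `"dppa"` (approximate); fixed after
#'   the first station.
#' @return the updated `train_state`.
#' @export
station_step <- function(state, samples, method = c("dppe", "dppa")) {
  stopifnot(inherits(state, "train_state"))
  method <- match.arg(method)
  if (!state$stage %in% c("init", "stations"))
    stop("train already past the station stage")
  if (!is.na(state$protocol) && state$protocol != method)
    stop("protocol cannot change mid-route")
  pos <- state$route_position + 1L
  if (pos > state$config$n_stations) stop("all stations already visited")
  samples <- as_sample_frame(samples)
  if (method == "dppe") {
    n_real <- sum(samples$flag == 1L)
    n_dummy <- round(state$config$dummy_fraction * n_real)
    if (n_dummy > 0) samples <- rbind(samples, make_dummies(samples, n_dummy))
    payload <- dppe_station_step(
      samples, state$pk, state$rsa$proxy$pubkey, station_id = pos,
      first = pos == 1L,
      downstream_pubkeys = if (pos == 1L && state$config$n_stations > 1L)
        lapply(state$rsa$stations[-1], function(k) k$pubkey),
      r1_envelope = if (pos > 1L) state$payloads[[1]]$r1_envelopes[[pos - 1L]],
      rsa_privkey = state$rsa$stations[[pos]],
      precision = state$config$precision)
    state$payloads[[pos]] <- payload
  } else {
    state$dppa_counts[[pos]] <-
      dppa_station_step(samples, decision_points(state$config$k_thresholds),
                        state$pk)
  }
  state$protocol <- method
  state$route_position <- pos
  state$stage <- if (pos == state$config$n_stations) "stations_done" else "stations"
  state
}

#' Run the proxy aggregation step
#'
#' @param state a `train_state` with all stations visited.
#' @return the updated `train_state` carrying the partially decrypted
#'   blinded components.
#' @export
proxy_step <- function(state) {
  stopifnot(inherits(state, "train_state"))
  if (state$stage != "stations_done")
    stop("proxy step requires all ", state$config$n_stations,
         " stations to have contributed (a missing station aborts the run)")
  share0 <- unwrap_share(state$share_envelopes$proxy, state$rsa$proxy)
  if (state$protocol == "dppe") {
    agg <- dppe_proxy_aggregate(state$payloads, state$rsa$proxy, share0, state$pk)
    state$report$S <- agg$S
    state$report$m_total <- agg$m
  } else {
    agg <- dppa_aggregate(state$dppa_counts, share0, state$pk)
    state$report$K <- agg$K
  }
  state$components <- agg$components
  state$stage <- "proxy_done"
  state
}

#' Recover the AUC at a data station
#'
#' @param state a `train_state` after [proxy_step()].
#' @param station_id which station finalizes (any; the result is identical
#'   at every station).
#' @return the AUC.
#' @export
finalize_station <- function(state, station_id = 1L) {
  stopifnot(inherits(state, "train_state"))
  if (state$stage != "proxy_done") stop("finalize requires the proxy stage")
  share1 <- unwrap_share(state$share_envelopes$stations[[station_id]],
                         state$rsa$stations[[station_id]])
  finalize_auc(state$components, share1, state$pk)
}

#' Run the full multi-party simulation
#'
#' Executes the whole route in one process: key initialization (or reuse of
#' a prepared `train_state`), each station's step in route order, the proxy
#' aggregation, and the final AUC recovery. Homomorphic operation counts
#' are recorded per stage.
#'
#' @param station_data list of per-station data frames (`score`, `label`).
#' @param method `"dppe"` or `"dppa"`.
#' @param config a [ppauc_config()]; `n_stations` is taken from
#'   `station_data`.
#' @param keys optional `train_state` from [init_keys()] to reuse (avoids
#'   regenerating safe primes for every run); per-run fields are reset.
#' @param seed optional seed for all protocol randomness.
#' @param finalize_at `"first"` (one station recovers the AUC) or `"all"`
#'   (every station does; the run asserts the results are identical).
#' @return list with `auc` and a `report` (row counts, threshold count,
#'   per-stage homomorphic operation counts, per-station AUCs).
#' @examples
#' \donttest{
#' set.seed(1)
#' data <- gen_fixture("perfect", n = 24, n_stations = 3)
#' cfg <- ppauc_config(n_stations = 3, paillier_bits = 256, rsa_bits = 1024)
#' run_simulation(data, "dppe", cfg)$auc  # exactly 1
#' }
#' @export
run_simulation <- function(station_data, method = c("dppe", "dppa"),
                           config = ppauc_config(), keys = NULL, seed = NULL,
                           finalize_at = c("first", "all")) {
  method <- match.arg(method)
  finalize_at <- match.arg(finalize_at)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.list(station_data), length(station_data) >= 1)
  config$n_stations <- length(station_data)
  state <- if (is.null(keys)) init_keys(config) else {
    stopifnot(inherits(keys, "train_state"),
              keys$config$n_stations == config$n_stations)
    st <- reset_train_state(keys)
    st$config <- config
    st
  }
  ppauc_op_counts(reset = TRUE)
  t0 <- Sys.time()
  for (i in seq_along(station_data))
    state <- station_step(state, station_data[[i]], method)
  ops_station <- ppauc_op_counts(reset = TRUE)
  t1 <- Sys.time()
  state <- proxy_step(state)
  ops_proxy <- ppauc_op_counts(reset = TRUE)
  t2 <- Sys.time()
  stations <- if (finalize_at == "all") seq_len(config$n_stations) else 1L
  aucs <- vapply(stations, function(s) finalize_station(state, s), numeric(1))
  ops_final <- ppauc_op_counts(reset = TRUE)
  t3 <- Sys.time()
  if (length(aucs) > 1 && length(unique(aucs)) != 1L)
    stop("stations recovered different AUC values; protocol state corrupted")
  report <- state$report
  report$method <- method
  report$n_stations <- config$n_stations
  report$n_real <- sum(vapply(station_data, function(d)
    sum(as_sample_frame(d)$flag == 1L), numeric(1)))
  report$auc_by_station <- stats::setNames(aucs, paste0("station", stations))
  report$ops <- list(stations = ops_station, proxy = ops_proxy,
                     finalize = ops_final)
  report$seconds <- c(stations = as.numeric(t1 - t0, units = "secs"),
                      proxy = as.numeric(t2 - t1, units = "secs"),
                      finalize = as.numeric(t3 - t2, units = "secs"))
  list(auc = aucs[[1]], report = report)
}

#' Read a station input CSV
#'
#' Expects the header `id,prediction,label` with predictions in `[0, 1]`
#' and labels 0/1; malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return data frame with columns `id`, `score`, `label`, `flag = 1`.
#' @export
read_station_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(df), c("id", "prediction", "label")))
    stop("station CSV must have header 'id,prediction,label' (got: ",
         paste(names(df), collapse = ","), ")")
  pred <- suppressWarnings(as.numeric(df$prediction))
  bad <- which(is.na(pred) | pred < 0 | pred > 1)
  if (length(bad))
    stop("invalid prediction (must be a decimal in [0,1]) at line ",
         paste(bad + 1L, collapse = ", "))
  lab <- suppressWarnings(as.numeric(df$label))
  badl <- which(is.na(lab) | !lab %in% c(0, 1))
  if (length(badl))
    stop("invalid label (must be 0 or 1) at line ",
         paste(badl + 1L, collapse = ", "))
  data.frame(id = df$id, score = pred, label = as.integer(lab), flag = 1L)
}
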