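# Lossless JSON serialization of the train state: big integers as hex
# strings, masked-score lists as decimal strings, byte strings as base64,
# RSA keys as PEM. This is the on-disk handoff format used when the route
# is driven file-by-file instead of in one process.

.b64 <- function(r) if (is.null(r)) NULL else openssl::base64_encode(r)
.unb64 <- function(s) if (is.null(s)) NULL else openssl::base64_decode(s)

ser_ct <- function(ct) list(c1 = bn_to_hex(ct$c1), c2 = bn_to_hex(ct$c2),
                            partial = ct$partial)
deser_ct <- function(x) new_ciphertext(bn_from_hex(x$c1), bn_from_hex(x$c2),
                                       isTRUE(x$partial))

ser_share_env <- function(e) list(index = e$index,
                                  wrapped_key = .b64(e$wrapped_key),
                                  body = .b64(e$body))
deser_share_env <- function(x) list(index = as.integer(x$index),
                                    wrapped_key = .unb64(x$wrapped_key),
                                    body = .unb64(x$body))

ser_payload <- function(p) list(
  station_id = p$station_id, m = p$m,
  enc_masked_scores = .b64(p$enc_masked_scores),
  enc_labels = lapply(p$enc_labels, ser_ct),
  enc_flags = lapply(p$enc_flags, ser_ct),
  wrapped_session_key = .b64(p$wrapped_session_key),
  r1_envelopes = if (!is.null(p$r1_envelopes)) lapply(p$r1_envelopes, .b64))

deser_payload <- function(x) structure(list(
  station_id = as.integer(x$station_id), m = as.integer(x$m),
  enc_masked_scores = .unb64(x$enc_masked_scores),
  enc_labels = lapply(x$enc_labels, deser_ct),
  enc_flags = lapply(x$enc_flags, deser_ct),
  wrapped_session_key = .unb64(x$wrapped_session_key),
  r1_envelopes = if (!is.null(x$r1_envelopes)) lapply(x$r1_envelopes, .unb64)
), class = "station_payload")

ser_counts <- function(ct) list(K = ct$K,
                                enc_TP = lapply(ct$enc_TP, ser_ct),
                                enc_FP = lapply(ct$enc_FP, ser_ct))
deser_counts <- function(x) structure(list(
  K = as.integer(x$K),
  enc_TP = lapply(x$enc_TP, deser_ct),
  enc_FP = lapply(x$enc_FP, deser_ct)), class = "dppa_station_counts")

ser_components <- function(cp) list(
  N1 = lapply(cp$N1, ser_ct), N2 = lapply(cp$N2, ser_ct), N3 = ser_ct(cp$N3),
  D1 = ser_ct(cp$D1), D2 = ser_ct(cp$D2), D3 = ser_ct(cp$D3))
deser_components <- function(x) structure(list(
  N1 = lapply(x$N1, deser_ct), N2 = lapply(x$N2, deser_ct),
  N3 = deser_ct(x$N3), D1 = deser_ct(x$D1), D2 = deser_ct(x$D2),
  D3 = deser_ct(x$D3)), class = "blinded_components")

#' Serialize a train state to JSON
#'
#' @param state a `train_state`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_train_state <- function(state, path) {
  stopifnot(inherits(state, "train_state"))
  obj <- list(
    format = "ppauc-train-state-1",
    config = unclass(state$config),
    protocol = if (!is.na(state$protocol)) state$protocol,
    stage = state$stage,
    route_position = state$route_position,
    pk = list(n = bn_to_hex(state$pk$n), g = bn_to_hex(state$pk$g),
              h = bn_to_hex(state$pk$h), bits = state$pk$bits),
    rsa = list(
      stations = lapply(state$rsa$stations, openssl::write_pem),
      proxy = openssl::write_pem(state$rsa$proxy)),
    share_envelopes = list(
      proxy = ser_share_env(state$share_envelopes$proxy),
      stations = lapply(state$share_envelopes$stations, ser_share_env)),
    payloads = lapply(state$payloads, ser_payload),
    dppa_counts = lapply(state$dppa_counts, ser_counts),
    components = if (!is.null(state$components)) ser_components(state$components),
    report = state$report)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null"),
             path)
  invisible(path)
}

#' @rdname write_train_state
#' @export
read_train_state <- function(path) {
  x <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                          simplifyVector = FALSE)
  if (!identical(x$format, "ppauc-train-state-1"))
    stop("not a ppauc train-state file: ", path)
  n <- bn_from_hex(x$pk$n)
  cfg <- do.call(ppauc_config, x$config)
  structure(list(
    config = cfg,
    protocol = if (is.null(x$protocol)) NA_character_ else x$protocol,
    stage = x$stage,
    route_position = as.integer(x$route_position),
    pk = new_paillier_pubkey(n, bn_from_hex(x$pk$g), bn_from_hex(x$pk$h),
                             as.integer(x$pk$bits)),
    rsa = list(
      stations = lapply(x$rsa$stations, openssl::read_key),
      proxy = openssl::read_key(x$rsa$proxy)),
    share_envelopes = list(
      proxy = deser_share_env(x$share_envelopes$proxy),
      stations = lapply(x$share_envelopes$stations, deser_share_env)),
    payloads = lapply(x$payloads, deser_payload),
    dppa_counts = lapply(x$dppa_counts, deser_counts),
    components = if (!is.null(x$components)) deser_components(x$components),
    report = x$report
  ), class = "train_state")
}
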