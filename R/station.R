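# Data-station side of the two protocols: the exact protocol's Step I
# (mask scores, encrypt labels and flags, wrap the session key), the
# approximate protocol's local threshold counting, and the final AUC
# recovery from the proxy's partially decrypted blinded components, which
# both protocols share.

#' Station step of the exact protocol
#'
#' Masks the station's fixed-point scores with the shared base `r1`,
#' encrypts the masked list under a fresh session key (wrapped for the
#' proxy), and Paillier-encrypts the label and flag bits element-wise.
#' The first station on the route draws `r1` and wraps it for every
#' downstream data station; later stations unwrap their envelope with their
#' RSA private key. Samples are expected to already include any injected
#' dummies (see [make_dummies()]).
#'
#' @param samples data frame with columns `score`, `label`, `flag`.
#' @param pk Paillier public key.
#' @param proxy_pubkey the proxy's RSA public key.
#' @param station_id integer id of this station (1-based route position).
#' @param first is this the first data station on the route?
#' @param downstream_pubkeys named list of RSA public keys of stations
#'   `2..n` (first station only).
#' @param r1_envelope raw RSA envelope containing `r1` (non-first stations).
#' @param rsa_privkey this station's RSA private key (non-first stations).
#' @param precision fixed-point digits for [to_fixed()].
#' @return a `station_payload`.
#' @export
dppe_station_step <- function(samples, pk, proxy_pubkey, station_id,
                              first = station_id == 1L,
                              downstream_pubkeys = NULL,
                              r1_envelope = NULL, rsa_privkey = NULL,
                              precision = 12L) {
  samples <- as_sample_frame(samples)
  if (nrow(samples) == 0) stop("station ", station_id, " has no samples")
  r1_envelopes <- NULL
  if (first) {
    r1 <- draw_mask_base()
    if (length(downstream_pubkeys))
      r1_envelopes <- lapply(downstream_pubkeys, function(pub) wrap_int(r1, pub))
  } else {
    if (is.null(r1_envelope))
      stop("station ", station_id, ": missing r1 envelope from the first station")
    if (is.null(rsa_privkey))
      stop("station ", station_id, ": RSA private key required to unwrap r1")
    r1 <- unwrap_int(r1_envelope, rsa_privkey)
  }
  masked <- mask_value(to_fixed(samples$score, precision), r1)
  skey <- gen_sym_key(station_id)
  enc_scores <- enc_sym(charToRaw(jsonlite::toJSON(masked)), skey)
  structure(list(
    station_id = station_id,
    m = nrow(samples),
    enc_masked_scores = enc_scores,
    enc_labels = lapply(samples$label, function(b) paillier_encrypt(pk, b)),
    enc_flags = lapply(samples$flag, function(b) paillier_encrypt(pk, b)),
    wrapped_session_key = wrap_key(skey, proxy_pubkey),
    r1_envelopes = r1_envelopes
  ), class = "station_payload")
}

#' @export
print.station_payload <- function(x, ...) {
  cat(sprintf("<station_payload> station %d, %d samples (scores sym-encrypted, labels/flags Paillier-encrypted)\n",
              x$station_id, x$m))
  invisible(x)
}

#' Station step of the approximate protocol
#'
#' Computes the station's cumulative TP/FP counts at the shared decision
#' points (see [threshold_counts()]) on its real samples and encrypts each
#' count with the Paillier public key. Scores never leave the station in
#' any form; the per-station cost is independent of the sample count up to
#' the local (plaintext) sweep.
#'
#' @param samples data frame with columns `score`, `label` (and optionally
#'   `flag`; only `flag == 1` rows are counted).
#' @param D strictly decreasing decision points.
#' @param pk Paillier public key.
#' @return a `dppa_station_counts` with ciphertext lists `enc_TP`, `enc_FP`.
#' @export
dppa_station_step <- function(samples, D, pk) {
  samples <- as_sample_frame(samples)
  samples <- samples[samples$flag == 1L, ]
  if (nrow(samples) == 0) stop("station has no real samples")
  tc <- threshold_counts(samples$score, samples$label, D)
  structure(list(
    K = length(D),
    enc_TP = lapply(tc$TP, function(v) paillier_encrypt(pk, v)),
    enc_FP = lapply(tc$FP, function(v) paillier_encrypt(pk, v))
  ), class = "dppa_station_counts")
}

#' @export
print.dppa_station_counts <- function(x, ...) {
  cat(sprintf("<dppa_station_counts> encrypted cumulative counts at %d decision points\n", x$K))
  invisible(x)
}

# exact quotient num/den rounded toward zero at 2^96 fractional bits, then
# one floating conversion; the blinding factors a*b cancel exactly in the
# integer quotient, so the result is invariant to all proxy randomness
.big_ratio <- function(num, den) {
  stopifnot(is_sbig(num), is_sbig(den))
  sgn <- if (xor(num$neg, den$neg)) -1 else 1
  q <- (num$mag * .bn_const$scale96) %/% den$mag
  sgn * bn_to_num(q) / 2^96
}

#' Recover the AUC from the proxy's blinded components
#'
#' Finishes decryption of every component with key share 1, decodes signs,
#' and evaluates `(sum_i N1[i]*N2[i] - N3) / (2 * (D1*D2 - D3))` with exact
#' big-integer arithmetic for the numerator and denominator followed by a
#' single floating division. All blinding randomness cancels algebraically,
#' so every station recovers the identical value.
#'
#' @param components a `blinded_components` object (partially decrypted by
#'   the proxy).
#' @param share1 the stations' key share (index 1).
#' @param pk Paillier public key.
#' @return the AUC in `[0, 1]`.
#' @export
finalize_auc <- function(components, share1, pk) {
  stopifnot(inherits(components, "blinded_components"))
  dec <- function(ct) decode_signed(paillier_decrypt(ct, share1, pk), pk$n)
  N1 <- lapply(components$N1, dec)
  N2 <- lapply(components$N2, dec)
  N3 <- dec(components$N3)
  D1 <- dec(components$D1); D2 <- dec(components$D2); D3 <- dec(components$D3)
  den <- D1 * D2 - D3
  if (den == sbig(0))
    stop("AUC undefined: no positive or no negative samples (zero denominator)")
  num <- sbig_zero()
  for (i in seq_along(N1)) num <- num + N1[[i]] * N2[[i]]
  num <- num - N3
  .big_ratio(num, sbig(2) * den)
}
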