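# Hybrid envelope layer: per-session symmetric authenticated encryption of
# masked score tables, and RSA wrapping of session keys and shared protocol
# integers. AES-GCM provides confidentiality; an HMAC-SHA256 tag over
# nonce||ciphertext (keyed with a hash-derived MAC key) provides the
# tamper-evidence contract, so any bit flip fails authentication.

#' Generate a 256-bit session key
#'
#' Fresh 32-byte symmetric key for one station and one protocol run, drawn
#' from R's RNG so runs are reproducible under [set.seed()].
#'
#' @param station_id optional identifier attached to the key.
#' @return raw vector of 32 bytes, class `ppauc_session_key`.
#' @export
gen_sym_key <- function(station_id = NULL) {
  k <- rng_bytes(32L)
  attr(k, "station_id") <- station_id
  class(k) <- "ppauc_session_key"
  k
}

.mac_key <- function(key) openssl::sha256(c(unclass(key), as.raw(1L)))

#' Authenticated symmetric encryption
#'
#' Encrypts with AES-256-GCM under a fresh 12-byte nonce and appends an
#' HMAC-SHA256 tag computed over nonce and ciphertext. The wire format is
#' `nonce(12) || ciphertext || tag(32)`.
#'
#' @param plaintext raw vector.
#' @param key 32-byte session key from [gen_sym_key()].
#' @return raw vector.
#' @export
enc_sym <- function(plaintext, key) {
  stopifnot(is.raw(plaintext), length(unclass(key)) == 32L)
  nonce <- rng_bytes(12L)
  ct <- openssl::aes_gcm_encrypt(plaintext, unclass(key), iv = nonce)
  attributes(ct) <- NULL
  tag <- openssl::sha256(c(nonce, ct), key = .mac_key(key))
  c(nonce, ct, unclass(tag))
}

#' @rdname enc_sym
#' @param ciphertext raw vector produced by `enc_sym`.
#' @return `dec_sym`: the decrypted raw plaintext; authentication failure
#'   (tampering or wrong key) raises an error.
#' @export
dec_sym <- function(ciphertext, key) {
  stopifnot(is.raw(ciphertext))
  if (length(ciphertext) < 44L)
    stop("symmetric ciphertext too short to contain nonce and tag")
  nonce <- ciphertext[1:12]
  tag <- ciphertext[(length(ciphertext) - 31L):length(ciphertext)]
  body <- ciphertext[seq.int(13L, length.out = length(ciphertext) - 44L)]
  expect <- unclass(openssl::sha256(c(nonce, body), key = .mac_key(key)))
  if (!identical(as.raw(expect), as.raw(tag)))
    stop("symmetric authentication failed: ciphertext tampered or wrong key")
  out <- openssl::aes_gcm_decrypt(body, unclass(key), iv = nonce)
  attributes(out) <- NULL
  out
}

#' Generate a long-term RSA key pair
#'
#' @param bits modulus size; the protocol default is 4096. Simulations use
#'   smaller sizes (1024+) since envelope correctness is size-independent.
#' @return an `openssl` RSA key object (private; `$pubkey` gives the public
#'   part).
#' @export
gen_asym_keypair <- function(bits = 4096) openssl::rsa_keygen(bits = bits)

# 8-byte key-confirmation checksum carried inside every RSA envelope;
# modern RSA decryption (implicit rejection) returns pseudorandom bytes
# rather than an error under a wrong key, so recipient binding is checked
# explicitly
.confirm_tag <- function(payload) unclass(openssl::sha256(c(payload, as.raw(0x4b))))[1:8]

.rsa_seal <- function(payload, pubkey)
  openssl::rsa_encrypt(c(payload, .confirm_tag(payload)), pubkey)

.rsa_open <- function(wrapped, privkey) {
  pt <- tryCatch(openssl::rsa_decrypt(wrapped, privkey), error = function(e)
    stop("envelope decryption failed: wrong private key or corrupted ciphertext",
         call. = FALSE))
  if (length(pt) < 9L)
    stop("envelope decryption failed: wrong private key or corrupted ciphertext")
  payload <- pt[seq_len(length(pt) - 8L)]
  tag <- pt[(length(pt) - 7L):length(pt)]
  if (!identical(as.raw(tag), as.raw(.confirm_tag(payload))))
    stop("envelope decryption failed: wrong private key or corrupted ciphertext")
  payload
}

#' Wrap and unwrap a session key for a recipient's RSA key
#'
#' The session key travels RSA-encrypted together with a short
#' key-confirmation checksum, so unwrapping with any key other than the
#' recipient's fails deterministically.
#'
#' @param key 32-byte session key.
#' @param pubkey recipient's RSA public key.
#' @return `wrap_key`: raw RSA ciphertext decryptable only with the
#'   recipient's private key.
#' @export
wrap_key <- function(key, pubkey) .rsa_seal(unclass(key), pubkey)

#' @rdname wrap_key
#' @param wrapped raw ciphertext from `wrap_key`.
#' @param privkey recipient's RSA private key.
#' @export
unwrap_key <- function(wrapped, privkey) {
  k <- .rsa_open(wrapped, privkey)
  class(k) <- "ppauc_session_key"
  k
}

# RSA envelope for a shared big integer (the mask base r1): big-endian bytes
wrap_int <- function(value, pubkey) .rsa_seal(as.raw(bn(value)), pubkey)

unwrap_int <- function(wrapped, privkey) openssl::bignum(.rsa_open(wrapped, privkey))
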