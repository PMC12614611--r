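# Proxy side: pooling and sorting of masked scores, cumulative encrypted
# TP/FP counts over unique thresholds, randomized-encoding blinding of the
# AUC numerator and denominator, zero-sum additive blinders, partial
# decryption, and the aggregation path of the approximate protocol. The
# proxy never sees a label, flag, count or raw score in plaintext.

#' Pool and sort the stations' masked tables
#'
#' Unwraps each station's session key with the proxy's RSA private key,
#' decrypts the symmetric layer of the masked score list, and pools all rows
#' into one table sorted by masked score, descending and stable. The
#' Paillier-encrypted labels and flags are carried alongside untouched; ties
#' in masked values correspond exactly to ties in raw scores because the
#' mask is deterministic and strictly increasing.
#'
#' @param payloads list of `station_payload` objects.
#' @param proxy_privkey the proxy's RSA private key.
#' @return a `merged_table`.
#' @export
merge_and_sort <- function(payloads, proxy_privkey) {
  masked <- character(0); labels <- list(); flags <- list(); station <- integer(0)
  for (p in payloads) {
    stopifnot(inherits(p, "station_payload"))
    row <- tryCatch({
      skey <- unwrap_key(p$wrapped_session_key, proxy_privkey)
      jsonlite::fromJSON(rawToChar(dec_sym(p$enc_masked_scores, skey)))
    }, error = function(e)
      stop("corrupted payload from station ", p$station_id, ": ",
           conditionMessage(e), call. = FALSE))
    if (length(row) != length(p$enc_labels) || length(row) != length(p$enc_flags))
      stop("corrupted payload from station ", p$station_id,
           ": masked score, label and flag lengths differ")
    masked <- c(masked, row)
    labels <- c(labels, p$enc_labels)
    flags <- c(flags, p$enc_flags)
    station <- c(station, rep(p$station_id, length(row)))
  }
  ord <- order(.score_keys(masked), decreasing = TRUE, method = "radix")
  structure(list(masked = masked[ord], enc_labels = labels[ord],
                 enc_flags = flags[ord], station = station[ord],
                 m = length(masked)),
            class = "merged_table")
}

#' @export
print.merged_table <- function(x, ...) {
  cat(sprintf("<merged_table> %d rows from %d stations, sorted by masked score\n",
              x$m, length(unique(x$station))))
  invisible(x)
}

#' Encrypted cumulative TP/FP counts per unique threshold
#'
#' Walks the sorted table once, maintaining a homomorphic running sum of
#' labels (true positives) and of flags; at the end of each tie class of
#' identical masked values it snapshots the running sums and sets
#' `FP[i] = flagsum[i] - TP[i]`, which cancels every dummy sample (label
#' and flag both zero) out of the false-positive count. O(m) homomorphic
#' additions plus one subtraction per unique threshold.
#'
#' @param table a `merged_table`.
#' @param pk Paillier public key.
#' @return list with ciphertext lists `enc_TP`, `enc_FP` and the unique
#'   threshold count `S`.
#' @export
cumulative_counts <- function(table, pk) {
  stopifnot(inherits(table, "merged_table"))
  m <- table$m
  run_tp <- paillier_encrypt(pk, 0)
  run_fl <- paillier_encrypt(pk, 0)
  last_of_class <- if (m > 1)
    c(table$masked[-1] != table$masked[-m], TRUE) else TRUE
  enc_TP <- list(); enc_FP <- list()
  for (i in seq_len(m)) {
    run_tp <- ph_add(pk, run_tp, table$enc_labels[[i]])
    run_fl <- ph_add(pk, run_fl, table$enc_flags[[i]])
    if (last_of_class[i]) {
      enc_TP[[length(enc_TP) + 1L]] <- run_tp
      enc_FP[[length(enc_FP) + 1L]] <- ph_sub(pk, run_fl, run_tp)
    }
  }
  list(enc_TP = enc_TP, enc_FP = enc_FP, S = length(enc_TP))
}

#' Draw the proxy's blinding randomness
#'
#' Multiplicative blinders `a`, `b` uniform in `[1, 2^32)`; additive
#' blinders `rA1`, `rA2` and per-threshold `ri1`, `ri2` uniform in
#' `[1, 2^64)`; and a zero-sum vector `z` of `S` signed 64-bit values
#' (`S-1` uniform draws, the last the negated sum). The ranges keep every
#' blinded plaintext magnitude far below `n/2` for protocol-size keys while
#' still swamping the count magnitudes they hide.
#'
#' @param S number of thresholds.
#' @return a `proxy_randoms` object.
#' @export
proxy_randoms <- function(S) {
  stopifnot(S >= 1)
  two64 <- bn(2)^bn(64)
  z <- vector("list", S)
  if (S > 1) {
    acc <- sbig_zero()
    for (i in seq_len(S - 1L)) {
      z[[i]] <- sbig_rand_signed_bits(64L)
      acc <- acc + z[[i]]
    }
    z[[S]] <- -acc
  } else z[[1]] <- sbig_zero()
  structure(list(
    a = bn_rand_below(bn(2)^bn(32), min = 1),
    b = bn_rand_below(bn(2)^bn(32), min = 1),
    rA1 = bn_rand_below(two64, min = 1),
    rA2 = bn_rand_below(two64, min = 1),
    ri1 = lapply(seq_len(S), function(i) bn_rand_below(two64, min = 1)),
    ri2 = lapply(seq_len(S), function(i) bn_rand_below(two64, min = 1)),
    z = z
  ), class = "proxy_randoms")
}

#' @export
print.proxy_randoms <- function(x, ...) {
  cat(sprintf("<proxy_randoms> blinders for %d thresholds (zero-sum z)\n",
              length(x$z)))
  invisible(x)
}

# conservative worst-case bound on any blinded plaintext magnitude; all
# protocol plaintexts must stay below n/2 or the signed encoding wraps
.check_blinding_bounds <- function(pk, S, m) {
  r_max <- bn(2)^bn(64); ab_max <- bn(2)^bn(32); mb <- bn(max(m, 1))
  # worst single term: sTP*ri2 + dFP*ri1 + ri1*ri2 + |z|, summed over S for N3
  term <- ab_max * (bn(2) * mb) * r_max + ab_max * mb * r_max +
    r_max * r_max + r_max
  bound <- bn(S) * term
  if (!(bound < pk$n %/% bn(2)))
    stop("Paillier modulus too small: worst-case blinded magnitude ",
         "exceeds n/2 for ", S, " thresholds and ", m,
         " samples; use a larger key")
  invisible(TRUE)
}

#' Blind the AUC denominator
#'
#' Scales the total encrypted counts by `a` and `b` and forms the
#' randomized-encoding triple `D1 = a*TP + rA1`, `D2 = b*FP + rA2`,
#' `D3 = a*TP*rA2 + b*FP*rA1 + rA1*rA2`, homomorphically, so that
#' `D1*D2 - D3 = a*b*T*N` exactly.
#'
#' @param pk Paillier public key.
#' @param enc_TP_last,enc_FP_last encrypted totals at the last threshold.
#' @param pr a `proxy_randoms`.
#' @return list of ciphertexts `D1`, `D2`, `D3`.
#' @export
blind_denominator <- function(pk, enc_TP_last, enc_FP_last, pr) {
  TPA <- ph_scalar_mul(pk, enc_TP_last, pr$a)
  FPA <- ph_scalar_mul(pk, enc_FP_last, pr$b)
  D1 <- ph_add_plain(pk, TPA, pr$rA1)
  D2 <- ph_add_plain(pk, FPA, pr$rA2)
  D3 <- ph_add_plain(pk,
                     ph_add(pk, ph_scalar_mul(pk, TPA, pr$rA2),
                            ph_scalar_mul(pk, FPA, pr$rA1)),
                     pr$rA1 * pr$rA2)
  list(D1 = D1, D2 = D2, D3 = D3)
}

#' Blind the AUC numerator
#'
#' For each threshold `i` (with zero sentinel at `i = 0`) forms the scaled
#' adjacent sums and differences `sTP[i] = a*(TP[i]+TP[i-1])`,
#' `dFP[i] = b*(FP[i]-FP[i-1])` and their randomized-encoding components
#' `N1[i] = sTP[i]+ri1`, `N2[i] = dFP[i]+ri2`,
#' `N3 = sum_i(sTP[i]*ri2 + dFP[i]*ri1 + ri1*ri2 + z[i])`, all
#' homomorphically. Because the `z[i]` sum to zero,
#' `sum_i N1[i]*N2[i] - N3 = a*b*sum_i sTP[i]*dFP[i]` exactly.
#'
#' @param pk Paillier public key.
#' @param enc_TP,enc_FP ciphertext lists of cumulative counts per threshold.
#' @param pr a `proxy_randoms` drawn for the same number of thresholds.
#' @param m bound on the underlying counts (total pooled samples) used for
#'   the overflow guard; callers that know the exact pooled size pass it.
#' @return list with ciphertext lists `N1`, `N2` and ciphertext `N3`.
#' @export
blind_numerator <- function(pk, enc_TP, enc_FP, pr, m = 2^20) {
  S <- length(enc_TP)
  stopifnot(S == length(enc_FP), S == length(pr$z))
  .check_blinding_bounds(pk, S, m)
  enc_zero <- paillier_encrypt(pk, 0)
  N1 <- vector("list", S); N2 <- vector("list", S)
  N3 <- paillier_encrypt(pk, 0)
  prev_tp <- enc_zero; prev_fp <- enc_zero
  for (i in seq_len(S)) {
    sTP <- ph_scalar_mul(pk, ph_add(pk, enc_TP[[i]], prev_tp), pr$a)
    dFP <- ph_scalar_mul(pk, ph_sub(pk, enc_FP[[i]], prev_fp), pr$b)
    N1[[i]] <- ph_add_plain(pk, sTP, pr$ri1[[i]])
    N2[[i]] <- ph_add_plain(pk, dFP, pr$ri2[[i]])
    Ni3 <- ph_add_plain(pk,
                        ph_add(pk, ph_scalar_mul(pk, sTP, pr$ri2[[i]]),
                               ph_scalar_mul(pk, dFP, pr$ri1[[i]])),
                        sbig(pr$ri1[[i]] * pr$ri2[[i]]) + pr$z[[i]])
    N3 <- ph_add(pk, N3, Ni3)
    prev_tp <- enc_TP[[i]]; prev_fp <- enc_FP[[i]]
  }
  list(N1 = N1, N2 = N2, N3 = N3)
}

#' Partially decrypt all blinded components with the proxy's key share
#'
#' Applies [paillier_partial_decrypt()] to every component; the plaintexts
#' remain unrecoverable without share 1.
#'
#' @param num list from [blind_numerator()] (`N1`, `N2`, `N3`).
#' @param den list from [blind_denominator()] (`D1`, `D2`, `D3`).
#' @param share0 the proxy's key share (index 0).
#' @param pk Paillier public key.
#' @return a `blinded_components` object, all components `partial = TRUE`.
#' @export
partial_decrypt_components <- function(num, den, share0, pk) {
  pd <- function(ct) paillier_partial_decrypt(ct, share0, pk)
  structure(list(
    N1 = lapply(num$N1, pd), N2 = lapply(num$N2, pd), N3 = pd(num$N3),
    D1 = pd(den$D1), D2 = pd(den$D2), D3 = pd(den$D3)
  ), class = "blinded_components")
}

#' @export
print.blinded_components <- function(x, ...) {
  cat(sprintf("<blinded_components> %d thresholds, partially decrypted: %s\n",
              length(x$N1), x$N1[[1]]$partial))
  invisible(x)
}

#' Full proxy stage of the exact protocol
#'
#' Convenience composition: [merge_and_sort()], [cumulative_counts()],
#' [proxy_randoms()], numerator and denominator blinding, and partial
#' decryption.
#'
#' @param payloads list of `station_payload`s.
#' @param proxy_privkey proxy RSA private key.
#' @param share0 proxy Paillier key share (index 0).
#' @param pk Paillier public key.
#' @return list with `components` (a `blinded_components`), `S` and `m`.
#' @export
dppe_proxy_aggregate <- function(payloads, proxy_privkey, share0, pk) {
  tab <- merge_and_sort(payloads, proxy_privkey)
  cc <- cumulative_counts(tab, pk)
  pr <- proxy_randoms(cc$S)
  den <- blind_denominator(pk, cc$enc_TP[[cc$S]], cc$enc_FP[[cc$S]], pr)
  num <- blind_numerator(pk, cc$enc_TP, cc$enc_FP, pr, m = tab$m)
  list(components = partial_decrypt_components(num, den, share0, pk),
       S = cc$S, m = tab$m)
}

#' Proxy stage of the approximate protocol
#'
#' Homomorphically sums the stations' encrypted cumulative counts at each
#' decision point, then applies the same adjacent-sum/difference blinding
#' and partial decryption as the exact protocol, with the last decision
#' point's totals as the denominator.
#'
#' @param counts_list list of `dppa_station_counts`, one per station, all
#'   over the same decision points.
#' @param share0 proxy Paillier key share (index 0).
#' @param pk Paillier public key.
#' @param pr optional `proxy_randoms` (drawn internally if `NULL`).
#' @return list with `components` and `K`.
#' @export
dppa_aggregate <- function(counts_list, share0, pk, pr = NULL) {
  stopifnot(length(counts_list) >= 1)
  K <- counts_list[[1]]$K
  for (ct in counts_list) {
    stopifnot(inherits(ct, "dppa_station_counts"))
    if (ct$K != K) stop("stations used different decision-point counts")
  }
  TPg <- counts_list[[1]]$enc_TP
  FPg <- counts_list[[1]]$enc_FP
  for (s in seq_along(counts_list)[-1]) {
    for (j in seq_len(K)) {
      TPg[[j]] <- ph_add(pk, TPg[[j]], counts_list[[s]]$enc_TP[[j]])
      FPg[[j]] <- ph_add(pk, FPg[[j]], counts_list[[s]]$enc_FP[[j]])
    }
  }
  if (is.null(pr)) pr <- proxy_randoms(K)
  den <- blind_denominator(pk, TPg[[K]], FPg[[K]], pr)
  num <- blind_numerator(pk, TPg, FPg, pr)
  list(components = partial_decrypt_components(num, den, share0, pk), K = K)
}
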