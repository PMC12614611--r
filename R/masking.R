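# Score masking: fixed-point encoding of prediction scores, the order- and
# tie-preserving multiplicative mask r1*s + (s mod r1), and dummy ("flag")
# sample injection. The mask lets the proxy sort pooled scores and group
# exact ties without learning the raw values; dummies obscure each station's
# score distribution and, because they carry label = 0 and flag = 0, cancel
# out of every count downstream.

#' Fixed-point encoding of a prediction score
#'
#' Maps a score in `[0, 1]` to the integer `round(score * 10^p)`. Equal
#' scores map to equal integers and order is preserved up to a resolution of
#' `10^-p`, which is what makes inter-station ties collide exactly in the
#' masked domain.
#'
#' @param score numeric vector in `[0, 1]`.
#' @param p decimal digits of precision (default 12).
#' @return numeric vector of non-negative integers (exact below 2^53).
#' @export
to_fixed <- function(score, p = 12L) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1))
    stop("scores must lie in [0, 1]")
  stopifnot(p >= 0, p <= 14)
  round(score * 10^p)
}

#' Order- and tie-preserving score mask
#'
#' Masks a fixed-point score `s` as `r1*s + (s mod r1)`. The map is strictly
#' increasing in `s` for any `r1 >= 2` (consecutive integers differ by at
#' least `r1 - (r1-1) + ... >= 1`), and deterministic, so stations sharing
#' the same `r1` produce identical masked values for identical scores.
#'
#' @param s numeric vector of non-negative integers (fixed-point scores).
#' @param r1 shared positive mask base (number, decimal string or bignum),
#'   at least 2.
#' @return character vector of decimal integer strings (values may exceed
#'   double precision).
#' @export
mask_value <- function(s, r1) {
  r1 <- bn(r1)
  if (r1 < bn(2)) stop("mask base r1 must be at least 2")
  if (any(s < 0) || any(s != round(s))) stop("masked inputs must be non-negative integers")
  vapply(s, function(si) {
    sb <- bn(si)
    as.character(r1 * sb + (sb %% r1))
  }, character(1))
}

#' Draw a mask base
#'
#' Uniform draw of the shared mask base `r1` from `[2^32, 2^64)`; the wide
#' range keeps masked magnitudes unpredictable while monotonicity holds for
#' any value at least 2.
#'
#' @return an `openssl::bignum`.
#' @export
draw_mask_base <- function() bn_rand_below(bn(2)^bn(64), min = bn(2)^bn(32))

#' Inject dummy ("flag") samples
#'
#' Creates `count` dummy records whose scores are drawn with replacement
#' from the station's existing real score values - never new values, so the
#' set of thresholds (and hence the AUC) is unchanged - with `label = 0` and
#' `flag = 0`. Real samples carry `flag = 1`; the proxy later subtracts true
#' positives from the flag sum, which cancels every dummy out of the
#' false-positive counts.
#'
#' @param real data frame of real samples with columns `score`, `label`
#'   (dummies present are ignored as a source of scores only if flagged 0).
#' @param count number of dummy records.
#' @return data frame with columns `score`, `label`, `flag`.
#' @export
make_dummies <- function(real, count) {
  stopifnot(is.data.frame(real), nrow(real) > 0)
  src <- if ("flag" %in% names(real)) real$score[real$flag == 1L] else real$score
  if (length(src) == 0) stop("no real samples to draw dummy scores from")
  if (count == 0)
    return(data.frame(score = numeric(0), label = integer(0), flag = integer(0)))
  data.frame(score = sample(src, count, replace = TRUE),
             label = 0L, flag = 0L)
}

# normalize a station sample table: ensure flag column, integer labels
as_sample_frame <- function(df) {
  stopifnot(is.data.frame(df), all(c("score", "label") %in% names(df)))
  if (!"flag" %in% names(df)) df$flag <- 1L
  if (any(!df$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (any(!df$flag %in% c(0L, 1L))) stop("flags must be 0 or 1")
  if (any(df$flag == 0L & df$label != 0L)) stop("dummy samples must have label 0")
  df$label <- as.integer(df$label)
  df$flag <- as.integer(df$flag)
  df[, c("score", "label", "flag")]
}
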