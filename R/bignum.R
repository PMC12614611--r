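# Internal big-integer plumbing on top of openssl's OpenSSL-backed bignum.
# openssl::bignum is unsigned; `sbig` adds a sign-magnitude layer so that
# randomized-encoding arithmetic and signed plaintext decoding stay exact.

bn <- function(x) {
  if (inherits(x, "bignum")) return(x)
  if (inherits(x, "sbig")) {
    if (x$neg) stop("cannot convert negative sbig to unsigned bignum")
    return(x$mag)
  }
  if (is.character(x) && length(x) == 1L && startsWith(x, "-"))
    stop("cannot convert negative value to unsigned bignum")
  if (is.numeric(x)) {
    if (x < 0) stop("cannot convert negative value to unsigned bignum")
    if (x != round(x) || x > 2^53)
      stop("numeric not exactly convertible; pass a decimal string")
    if (x == 0) return(.bn_const$zero)
    if (x == 1) return(.bn_const$one)
    if (x == 2) return(.bn_const$two)
    # never hand numerics to openssl::bignum(): it renders them with ~6
    # significant digits (e.g. 999958 collapses to 1000000); go through an
    # exact decimal rendering instead
    return(openssl::bignum(sprintf("%.0f", x)))
  }
  openssl::bignum(x)
}

# cached constants: constructing a bignum is comparatively expensive and the
# zero/one comparisons sit on hot paths
bn_zero <- function() .bn_const$zero
bn_one  <- function() .bn_const$one

# bignum objects are classed raw vectors, so these are safe to build at
# package install time
.bn_const <- local({
  e <- new.env(parent = emptyenv())
  e$zero <- openssl::bignum("0")
  e$one <- openssl::bignum("1")
  e$two <- openssl::bignum("2")
  e$scale96 <- openssl::bignum("79228162514264337593543950336")  # 2^96
  e
})

bn_is_zero <- function(b) length(as.raw(b)) == 0L || b == .bn_const$zero

bn_is_one <- function(b) {
  r <- as.raw(b)
  length(r) == 1L && r == as.raw(1L)
}

# big-endian hex serialization (leading zeros stripped); inverse of bn_from_hex
bn_to_hex <- function(b) {
  r <- as.raw(b)
  if (length(r) == 0L) return("00")
  paste(sprintf("%02x", as.integer(r)), collapse = "")
}

bn_from_hex <- function(h) {
  h <- tolower(h)
  if (nchar(h) %% 2 == 1L) h <- paste0("0", h)
  openssl::bignum(as.raw(strtoi(substring(h, seq(1, nchar(h), 2),
                                          seq(2, nchar(h), 2)), 16L)))
}

# number of bits in b (0 for zero)
bn_bits <- function(b) {
  r <- as.raw(b)
  if (length(r) == 0L) return(0L)
  top <- as.integer(r[1])
  nb <- 0L
  while (top > 0L) { nb <- nb + 1L; top <- top %/% 2L }
  nb + 8L * (length(r) - 1L)
}

# Raw bytes from R's RNG so that every protocol random is reproducible under
# set.seed(); openssl::rand_bytes would bypass the seed.
rng_bytes <- function(k) as.raw(sample.int(256L, k, replace = TRUE) - 1L)

# uniform bignum in [min, bound) by rejection sampling on the bit width
bn_rand_below <- function(bound, min = 1) {
  bound <- bn(bound); minb <- bn(min)
  if (!(minb < bound)) stop("empty sampling range")
  bits <- bn_bits(bound)
  nbytes <- (bits + 7L) %/% 8L
  topmask <- as.raw(bitwShiftL(1L, ((bits - 1L) %% 8L) + 1L) - 1L)
  repeat {
    r <- sample.int(256L, nbytes, replace = TRUE)
    r <- as.raw(r - 1L)
    r[1] <- r[1] & topmask
    v <- openssl::bignum(r)
    if (v < bound && !(v < minb)) return(v)
  }
}

# uniform bignum with exactly `bits` bits (top bit set)
bn_rand_bits <- function(bits) {
  nbytes <- (bits + 7L) %/% 8L
  r <- rng_bytes(nbytes)
  shift <- (bits - 1L) %% 8L
  r[1] <- (r[1] & as.raw(bitwShiftL(1L, shift + 1L) - 1L)) | as.raw(bitwShiftL(1L, shift))
  openssl::bignum(r)
}

# exact decimal rendering then R's correctly-rounded string-to-double parse;
# as.double.bignum itself is not reliably rounded
bn_to_num <- function(b) as.numeric(as.character(b))

## ---- signed big integers ---------------------------------------------------

new_sbig <- function(neg, mag) {
  if (bn_is_zero(mag)) neg <- FALSE
  structure(list(neg = neg, mag = mag), class = "sbig")
}

#' Exact signed big integer
#'
#' A minimal sign-magnitude arbitrary-precision integer used wherever the
#' protocol needs exact signed arithmetic outside a modulus: randomized
#' encoding of products, zero-sum blinders, and the final numerator and
#' denominator of the AUC. Supports `+`, `-`, `*`, unary minus, comparisons,
#' `as.numeric()` and `as.character()` (decimal, with sign).
#'
#' @param x a number, a decimal string (optionally signed), an
#'   `openssl::bignum`, or an `sbig`.
#' @return an object of class `sbig`.
#' @examples
#' sbig(-3) * sbig("100000000000000000000") + sbig(1)
#' @export
sbig <- function(x) {
  if (inherits(x, "sbig")) return(x)
  if (inherits(x, "bignum")) return(new_sbig(FALSE, x))
  if (is.numeric(x)) {
    stopifnot(length(x) == 1L, is.finite(x), x == round(x))
    if (abs(x) > 2^53) stop("numeric too large for exact conversion; pass a string")
    return(new_sbig(x < 0, bn(abs(x))))
  }
  if (is.character(x)) {
    neg <- startsWith(x, "-")
    return(new_sbig(neg, openssl::bignum(sub("^[+-]", "", x))))
  }
  stop("cannot convert to sbig: ", class(x)[1])
}

is_sbig <- function(x) inherits(x, "sbig")

sbig_zero <- function() new_sbig(FALSE, bn_zero())

#' @export
as.character.sbig <- function(x, ...) {
  paste0(if (x$neg) "-" else "", as.character(x$mag))
}

#' @export
as.numeric.sbig <- function(x, ...) (if (x$neg) -1 else 1) * bn_to_num(x$mag)

#' @export
as.double.sbig <- function(x, ...) as.numeric.sbig(x)

#' @export
print.sbig <- function(x, ...) {
  cat("<sbig>", as.character(x), "\n")
  invisible(x)
}

sbig_neg <- function(x) new_sbig(!x$neg, x$mag)

sbig_add <- function(a, b) {
  if (a$neg == b$neg) return(new_sbig(a$neg, a$mag + b$mag))
  # opposite signs: subtract smaller magnitude from larger
  if (a$mag == b$mag) return(sbig_zero())
  if (a$mag > b$mag) new_sbig(a$neg, a$mag - b$mag)
  else               new_sbig(b$neg, b$mag - a$mag)
}

sbig_mul <- function(a, b) new_sbig(xor(a$neg, b$neg), a$mag * b$mag)

# -1, 0, 1 for a <, ==, > b
sbig_cmp <- function(a, b) {
  d <- sbig_add(a, sbig_neg(b))
  if (bn_is_zero(d$mag)) 0L else if (d$neg) -1L else 1L
}

#' @export
Ops.sbig <- function(e1, e2) {
  if (missing(e2)) {  # unary
    e1 <- sbig(e1)
    return(switch(.Generic,
      "-" = sbig_neg(e1),
      "+" = e1,
      stop("unsupported unary operator for sbig: ", .Generic)))
  }
  a <- sbig(e1); b <- sbig(e2)
  switch(.Generic,
    "+" = sbig_add(a, b),
    "-" = sbig_add(a, sbig_neg(b)),
    "*" = sbig_mul(a, b),
    "==" = sbig_cmp(a, b) == 0L,
    "!=" = sbig_cmp(a, b) != 0L,
    "<"  = sbig_cmp(a, b) < 0L,
    ">"  = sbig_cmp(a, b) > 0L,
    "<=" = sbig_cmp(a, b) <= 0L,
    ">=" = sbig_cmp(a, b) >= 0L,
    stop("unsupported operator for sbig: ", .Generic))
}

# non-negative residue of v modulo n (n an unsigned bignum), in [0, n)
sbig_mod <- function(v, n) {
  v <- sbig(v)
  r <- v$mag %% n
  if (v$neg && !bn_is_zero(r)) r <- n - r
  r
}

# signed 64-bit-ish uniform draw in [-(2^b-1), 2^b-1] excluding huge bias issues
sbig_rand_signed_bits <- function(bits) {
  mag <- bn_rand_below(bn(2)^bn(bits), min = 0)
  neg <- sample.int(2L, 1L) == 1L
  new_sbig(neg, mag)
}
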