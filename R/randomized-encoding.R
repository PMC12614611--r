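# Randomized encoding of a product: x1*x2 is represented by the triple
# (x1 + r1, x2 + r2, r2*x1 + r1*x2 + r1*r2), from which only c1*c2 - c3 =
# x1*x2 can be recovered; each component alone is blinded by the uniform
# randoms. The proxy mirrors this encoding homomorphically on encrypted
# TP/FP counts; this plaintext form is the reference used in tests.

#' Randomized encoding of a product
#'
#' Encodes `x1 * x2` as the triple `(x1 + r1, x2 + r2,
#' r2*x1 + r1*x2 + r1*r2)`. The encoding is perfect: [decode_product()]
#' recovers the product exactly for any choice of the blinding randoms,
#' including negative inputs.
#'
#' @param x1,x2 factors (numbers, decimal strings or [sbig()]).
#' @param r1,r2 blinding randoms (same types).
#' @return an object of class `re_encoding` with `sbig` fields `c1`, `c2`,
#'   `c3`.
#' @examples
#' e <- encode_product(3, 5, r1 = 2, r2 = 7)
#' as.numeric(decode_product(e))  # 15
#' @export
encode_product <- function(x1, x2, r1, r2) {
  x1 <- sbig(x1); x2 <- sbig(x2); r1 <- sbig(r1); r2 <- sbig(r2)
  structure(list(c1 = x1 + r1,
                 c2 = x2 + r2,
                 c3 = r2 * x1 + r1 * x2 + r1 * r2),
            class = "re_encoding")
}

#' @rdname encode_product
#' @param e an `re_encoding`.
#' @return `decode_product`: the product `x1 * x2` as an [sbig()].
#' @export
decode_product <- function(e) {
  stopifnot(inherits(e, "re_encoding"))
  e$c1 * e$c2 - e$c3
}

#' @export
print.re_encoding <- function(x, ...) {
  cat("<re_encoding> c1 =", as.character(x$c1),
      " c2 =", as.character(x$c2),
      " c3 =", as.character(x$c3), "\n")
  invisible(x)
}
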