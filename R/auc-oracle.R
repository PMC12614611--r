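# Plaintext reference computations: tie-aware trapezoidal AUC over unique
# descending thresholds, a brute-force pair-counting AUC, and the plaintext
# twin of the fixed-threshold approximation. These are the oracles against
# which the encrypted protocols are verified.

# sortable representation: numeric scores stay numeric; decimal-string
# scores (masked values beyond double precision) are zero-padded so that
# lexicographic order equals numeric order
.score_keys <- function(scores) {
  if (is.numeric(scores)) return(scores)
  if (is.character(scores)) {
    nc <- nchar(scores)
    w <- max(nc)
    pad <- strrep("0", w - nc)
    return(paste0(pad, scores))
  }
  stop("scores must be numeric or decimal strings")
}

# cumulative TP/FP at each unique descending threshold ("positive iff
# score >= threshold"); no sentinel row
roc_counts <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (any(!labels %in% c(0, 1))) stop("labels must be 0 or 1")
  keys <- .score_keys(scores)
  ord <- order(keys, decreasing = TRUE, method = "radix")
  k <- keys[ord]
  l <- labels[ord]
  last_of_class <- c(k[-1] != k[-length(k)], TRUE)
  TP <- cumsum(l)[last_of_class]
  FP <- cumsum(1 - l)[last_of_class]
  list(TP = TP, FP = FP,
       T = sum(l), N = sum(1 - l), S = sum(last_of_class))
}

#' Exact tie-aware AUC
#'
#' Trapezoidal AUC over the unique descending thresholds of the score
#' vector, `A = 1/(2*T*N) * sum_i (TP[i]+TP[i-1]) * (FP[i]-FP[i-1])` with
#' the sentinel `TP[0] = FP[0] = 0`. Ties contribute half, so the result
#' equals the pair-counting AUC (probability that a random positive scores
#' above a random negative, ties counted 1/2).
#'
#' @param scores numeric scores, or decimal-string integers (e.g. masked
#'   scores); only order and ties matter.
#' @param labels 0/1 vector, at least one of each class.
#' @return AUC in `[0, 1]`.
#' @examples
#' exact_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0))  # 1
#' exact_auc(c(0.5, 0.5), c(1, 0))                  # 0.5
#' @export
exact_auc <- function(scores, labels) {
  rc <- roc_counts(scores, labels)
  if (rc$T == 0 || rc$N == 0)
    stop("AUC undefined: need at least one positive and one negative label")
  TP <- c(0, rc$TP); FP <- c(0, rc$FP)
  i <- seq_len(rc$S) + 1L
  sum((TP[i] + TP[i - 1L]) * (FP[i] - FP[i - 1L])) / (2 * rc$T * rc$N)
}

#' Brute-force pair-counting AUC
#'
#' Independent O(T*N) oracle: `(concordant + 0.5*tied) / (T*N)` over all
#' positive-negative pairs.
#'
#' @inheritParams exact_auc
#' @return AUC in `[0, 1]`.
#' @export
pair_count_auc <- function(scores, labels) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0)
    stop("AUC undefined: need at least one positive and one negative label")
  d <- outer(pos, neg, "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / (length(pos) * length(neg))
}

# cumulative TP/FP per decision point: at each interior decision point,
# count the samples scoring strictly above it; at the final decision point,
# fold in every remaining sample so the last counts carry the full totals
# (T, N). This per-point rule is additive across stations - summing
# per-station counts gives exactly the pooled counts - which is what lets
# the proxy aggregate encrypted per-station counts by plain addition.
threshold_counts <- function(scores, labels, D) {
  stopifnot(is.numeric(scores), length(scores) == length(labels))
  if (length(D) == 0) stop("decision-point set must be non-empty")
  if (length(D) > 1 && any(diff(D) >= 0)) stop("decision points must be strictly decreasing")
  if (any(!labels %in% c(0, 1))) stop("labels must be 0 or 1")
  m <- length(scores)
  ord <- order(scores, decreasing = TRUE, method = "radix")
  lab <- labels[ord]
  cum_tp <- cumsum(lab)            # positives among the top-k scores
  cum_fp <- cumsum(1 - lab)
  sa <- scores[ord][m:1]           # ascending
  K <- length(D)
  # number of samples strictly above each decision point
  k <- m - findInterval(D, sa)
  k[K] <- m                        # final point finalizes the totals
  TP <- ifelse(k > 0, cum_tp[pmax(k, 1L)], 0)
  FP <- ifelse(k > 0, cum_fp[pmax(k, 1L)], 0)
  list(TP = as.numeric(TP), FP = as.numeric(FP))
}

#' Fixed-threshold approximate AUC (plaintext twin)
#'
#' Accumulates cumulative TP/FP at a predefined descending set of decision
#' points (counting samples strictly above each point; the final point folds
#' in all remaining samples) and applies the trapezoidal formula over those
#' K points, using the last point's counts as the positive/negative totals. This is the plaintext reference for the
#' approximate protocol; as the decision points refine to the unique score
#' values the result converges to [exact_auc()].
#'
#' @inheritParams exact_auc
#' @param D strictly decreasing numeric vector of decision points.
#' @return approximate AUC.
#' @export
threshold_auc <- function(scores, labels, D) {
  tc <- threshold_counts(scores, labels, D)
  K <- length(D)
  T_ <- tc$TP[K]; N_ <- tc$FP[K]
  if (T_ == 0 || N_ == 0)
    stop("AUC undefined: need at least one positive and one negative count")
  TP <- c(0, tc$TP); FP <- c(0, tc$FP)
  i <- seq_len(K) + 1L
  sum((TP[i] + TP[i - 1L]) * (FP[i] - FP[i - 1L])) / (2 * T_ * N_)
}

#' Default decision points
#'
#' `K` equally spaced points `1 - j/K` for `j = 0..K-1`, descending from 1
#' to `1/K`.
#'
#' @param k number of decision points (default 100).
#' @return numeric vector of length `k`.
#' @export
decision_points <- function(k = 100L) {
  stopifnot(k >= 1)
  1 - (seq_len(k) - 1) / k
}
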