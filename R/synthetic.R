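# Generators for the synthetic evaluation scenarios and edge-case fixtures:
# endpoint-biased and uniform score distributions, Bernoulli labels, dummy
# injection from existing score values, and degenerate fixtures exercising
# the perfect-separation, chance-level, all-ties and undefined-AUC paths.

# scores piled up near 0 and 1: 40% Beta(0.5, 8), 40% Beta(8, 0.5),
# 20% Uniform. Exactness of the protocol does not depend on the shape;
# the mixture mimics well-separated classifier outputs.
.endpoint_biased_scores <- function(n) {
  comp <- sample.int(3L, n, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  s <- numeric(n)
  s[comp == 1L] <- stats::rbeta(sum(comp == 1L), 0.5, 8)
  s[comp == 2L] <- stats::rbeta(sum(comp == 2L), 8, 0.5)
  s[comp == 3L] <- stats::runif(sum(comp == 3L))
  s
}

.bernoulli_labels <- function(n, rate) {
  l <- stats::rbinom(n, 1L, rate)
  # degenerate single-class draws make the AUC undefined; nudge one sample
  if (n >= 2) {
    if (sum(l) == 0L) l[1] <- 1L
    if (sum(l) == n) l[1] <- 0L
  }
  l
}

.one_station <- function(n_total, score_fun, label_rate, dummy_fraction) {
  n_real <- n_total - round(n_total * dummy_fraction)
  stopifnot(n_real >= 1)
  real <- data.frame(score = score_fun(n_real),
                     label = .bernoulli_labels(n_real, label_rate),
                     flag = 1L)
  rbind(real, make_dummies(real, n_total - n_real))
}

#' Synthetic scenario: fixed total size, varying station count
#'
#' Emulates the first evaluation scenario: a fixed total of `total`
#' subjects (real plus dummy) split as evenly as possible across
#' `n_stations` stations, endpoint-biased scores (mass near 0 and 1),
#' Bernoulli labels, and dummy records drawn from each station's real score
#' values.
#'
#' @param n_stations number of data stations (3-9 in the scenario).
#' @param total total subjects across stations, dummies included.
#' @param label_rate positive-label probability.
#' @param dummy_fraction fraction of each station's records that are
#'   dummies.
#' @param seed optional seed forwarded to [set.seed()].
#' @return list of per-station data frames (`score`, `label`, `flag`).
#' @export
gen_experiment1 <- function(n_stations = 3L, total = 1500L, label_rate = 0.5,
                            dummy_fraction = 0.2, seed = NULL) {
  stopifnot(n_stations >= 1, total >= n_stations)
  if (!is.null(seed)) set.seed(seed)
  base <- total %/% n_stations
  sizes <- rep(base, n_stations) + c(rep(1L, total - base * n_stations),
                                     rep(0L, n_stations - (total - base * n_stations)))
  lapply(sizes, .one_station, score_fun = .endpoint_biased_scores,
         label_rate = label_rate, dummy_fraction = dummy_fraction)
}

#' Synthetic scenario: three stations, varying sample size
#'
#' Emulates the second evaluation scenario: `n_samples` subjects (dummies
#' included) split over three stations with uniformly distributed scores -
#' the worst case for the exact protocol, since almost every score is a
#' distinct threshold.
#'
#' @param n_samples total subjects (the scenario ranges up to 23,000).
#' @inheritParams gen_experiment1
#' @return list of three per-station data frames.
#' @export
gen_experiment2 <- function(n_samples, label_rate = 0.5, dummy_fraction = 0.2,
                            seed = NULL) {
  stopifnot(n_samples >= 3)
  if (!is.null(seed)) set.seed(seed)
  base <- n_samples %/% 3L
  sizes <- rep(base, 3L) + c(rep(1L, n_samples - base * 3L),
                             rep(0L, 3L - (n_samples - base * 3L)))
  lapply(sizes, .one_station, score_fun = stats::runif,
         label_rate = label_rate, dummy_fraction = dummy_fraction)
}

#' Edge-case fixtures
#'
#' * `perfect` - every positive (scores in `[0.6, 1]`) outscores every
#'   negative (scores in `[0, 0.4]`); AUC exactly 1.
#' * `random` - uniform scores, labels independent of scores; AUC near 0.5.
#' * `all_ties` - a single unique score; AUC exactly 0.5.
#' * `single_class` - positives only; every AUC path must signal an
#'   undefined AUC.
#'
#' @param kind fixture type.
#' @param n total number of real samples across stations.
#' @param n_stations how many stations to split over.
#' @param seed optional seed.
#' @return list of per-station data frames (`score`, `label`, `flag = 1`).
#' @export
gen_fixture <- function(kind = c("perfect", "random", "all_ties", "single_class"),
                        n = 60L, n_stations = 1L, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n >= 2, n_stations >= 1, n >= n_stations)
  if (!is.null(seed)) set.seed(seed)
  df <- switch(kind,
    perfect = {
      npos <- n %/% 2L
      data.frame(
        score = c(stats::runif(npos, 0.6, 1.0), stats::runif(n - npos, 0.0, 0.4)),
        label = c(rep(1L, npos), rep(0L, n - npos)), flag = 1L)
    },
    random = data.frame(score = stats::runif(n),
                        label = .bernoulli_labels(n, 0.5), flag = 1L),
    all_ties = data.frame(score = rep(0.5, n),
                          label = .bernoulli_labels(n, 0.5), flag = 1L),
    single_class = data.frame(score = stats::runif(n), label = 1L, flag = 1L))
  rows <- sample(rep(seq_len(n_stations), length.out = n))
  lapply(seq_len(n_stations), function(s) {
    out <- df[rows == s, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write a station's samples as protocol-format CSV
#'
#' Columns `id`, `prediction`, `label`; the `flag` column is not written
#' (dummies are injected at protocol time, not shipped in input files).
#'
#' @param df data frame with `score` and `label` (real samples).
#' @param path output file.
#' @param ids optional sample identifiers.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(df, path, ids = NULL) {
  df <- as_sample_frame(df)
  df <- df[df$flag == 1L, ]
  out <- data.frame(id = if (is.null(ids)) seq_len(nrow(df)) else ids,
                    prediction = df$score, label = df$label)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
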