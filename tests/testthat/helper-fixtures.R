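# Shared fixtures and independent oracles for the test suite.

# The published 32-model anchored catalog, transcribed row for row.
anchored32_reference <- function() {
  tibble::tribble(
    ~model_id, ~pattern,
    0L, "m",
    1L, "mm",
    2L, "mkm",
    3L, "mmm",
    4L, "mkkm",
    5L, "mkmm",
    6L, "mmkm",
    7L, "mmmm",
    8L, "mkkkm",
    9L, "mkkmm",
    10L, "mkmkm",
    11L, "mkmmm",
    12L, "mmkkm",
    13L, "mmkmm",
    14L, "mmmkm",
    15L, "mmmmm",
    16L, "mkkkkm",
    17L, "mkkkmm",
    18L, "mkkmkm",
    19L, "mkkmmm",
    20L, "mkmkkm",
    21L, "mkmkmm",
    22L, "mkmmkm",
    23L, "mkmmmm",
    24L, "mmkkkm",
    25L, "mmkkmm",
    26L, "mmkmkm",
    27L, "mmkmmm",
    28L, "mmmkkm",
    29L, "mmmkmm",
    30L, "mmmmkm",
    31L, "mmmmmm"
  )
}

# Independent brute-force oracle for the exact score distribution: explicit
# loop over every width-w window, scoring and weighting it one letter at a
# time, then aggregating tails by descending score.
brute_force_score_dist <- function(pwm, background) {
  width <- ncol(pwm)
  combos <- expand.grid(rep(list(1:4), width))
  scores <- numeric(nrow(combos))
  probs <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    s <- 0; p <- 1
    for (j in seq_len(width)) {
      b <- combos[r, width - j + 1L]
      s <- s + pwm[b, j]
      p <- p * background[b]
    }
    scores[r] <- s
    probs[r] <- p
  }
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  tails <- cumsum(probs[ord])
  keep <- !duplicated(scores, fromLast = TRUE)
  data.frame(score = scores[keep], p_value = tails[keep])
}

random_pwm <- function(width = 6) {
  counts <- matrix(stats::rexp(4 * width), nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  prob <- sweep(counts, 2, colSums(counts), "/")
  to_log_odds(prob, background_freqs())
}

random_sites <- function(n, width = 6) {
  apply(matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
               nrow = n), 1, paste, collapse = "")
}
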