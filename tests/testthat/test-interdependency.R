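test_that("position probability matrices are pseudocount-free frequencies", {
  ppm <- position_probability_matrix(rep("TCAGTT", 4))
  expect_equal(ppm["T", 1], 1)
  expect_equal(sum(ppm[c("A", "C", "G"), 1]), 0)
  ppm2 <- position_probability_matrix(c("AAAAAA", "CCCCCC"))
  expect_true(all(ppm2["A", ] == 0.5 & ppm2["C", ] == 0.5))
  set.seed(4)
  ppm3 <- position_probability_matrix(random_sites(33))
  expect_true(all(abs(colSums(ppm3) - 1) < 1e-9))
})

test_that("hypothesis enumeration covers all position and nucleotide pairs", {
  h6 <- enumerate_pair_hypotheses(6)
  expect_equal(nrow(h6), 240L)
  expect_equal(nrow(unique(h6[, c("pos_i", "pos_j")])), 15L)
  expect_true(all(h6$pos_i < h6$pos_j))
  expect_equal(nrow(enumerate_pair_hypotheses(2)), 16L)
  expect_equal(nrow(unique(enumerate_pair_hypotheses(3)[, c("pos_i", "pos_j")])), 3L)
})

test_that("null counts follow the product binomial law", {
  # deterministic ppm: every site is AAAAAA, so the (A, A) count is set_size
  det <- matrix(c(1, 0, 0, 0), 4, 6, dimnames = list(c("A", "C", "G", "T"), 1:6))
  cnt <- simulate_null_counts(det, n_sets = 5, set_size = 11)
  hyp <- attr(cnt, "hypotheses")
  aa <- hyp$nt_i == "A" & hyp$nt_j == "A"
  expect_true(all(cnt[aa, ] == 11L))
  expect_true(all(cnt[!aa, ] == 0L))

  # moments match Binomial(set_size, p_i(a) p_j(b)) within 3 standard errors
  set.seed(55)
  ppm <- inr_ppm()
  n_sets <- 4000
  set_size <- 50
  cnt2 <- simulate_null_counts(ppm, n_sets = n_sets, set_size = set_size)
  hyp2 <- attr(cnt2, "hypotheses")
  idx <- which(hyp2$pos_i == 2 & hyp2$pos_j == 5)
  for (k in idx[c(1, 6, 12)]) {
    q <- ppm[hyp2$nt_i[k], 2] * ppm[hyp2$nt_j[k], 5]
    mu <- set_size * q
    sdv <- sqrt(set_size * q * (1 - q))
    expect_lt(abs(mean(cnt2[k, ]) - mu), 3 * sdv / sqrt(n_sets) + 1e-9)
    # upper-tail agreement with the exact binomial tail
    obs <- ceiling(mu + sdv)
    mc_tail <- mean(cnt2[k, ] >= obs)
    exact_tail <- stats::pbinom(obs - 1, set_size, q, lower.tail = FALSE)
    expect_lt(abs(mc_tail - exact_tail),
              3 * sqrt(exact_tail * (1 - exact_tail) / n_sets) + 1e-3)
  }
})

test_that("Monte Carlo p-values use the add-one rule and are order-invariant", {
  set.seed(61)
  sites <- sample_sites(inr_ppm(), 40)
  set.seed(7)
  res <- pair_dependence_test(sites, n_sets = 1000)
  expect_s3_class(res, "interdep_test")
  expect_equal(nrow(res), 240L)
  expect_true(all(res$p_upper > 0 & res$p_lower > 0))
  expect_true(all(res$p_upper >= 1 / 1001))
  expect_true(all(res$p_two_tailed <= 1))
  # each pair's observed counts total the number of sites
  tot <- res |>
    dplyr::group_by(pos_i, pos_j) |>
    dplyr::summarise(n = sum(observed), .groups = "drop")
  expect_true(all(tot$n == 40L))
  # expected = n * p_i(a) * p_j(b) from the plug-in ppm
  ppm <- position_probability_matrix(sites)
  r1 <- res[res$pos_i == 1 & res$pos_j == 2 & res$nt_i == "T" & res$nt_j == "C", ]
  expect_equal(r1$expected, 40 * ppm["T", 1] * ppm["C", 2])
  # permuting the sites changes nothing (same RNG state for the null draws)
  set.seed(7)
  res_shuffled <- pair_dependence_test(rev(sites), n_sets = 1000)
  expect_equal(res$p_upper, res_shuffled$p_upper)
  expect_equal(res$observed, res_shuffled$observed)
  expect_warning(pair_dependence_test(sites, n_sets = 500), "1000")
})

test_that("a planted coupling is detected as one-tailed over-enrichment", {
  set.seed(71)
  sites <- sample_sites_coupled(inr_ppm(), 205, c(2, 5), c("A", "G"),
                                coupling = 0.3)
  res <- pair_dependence_test(sites, n_sets = 2000)
  target <- res[res$pos_i == 2 & res$pos_j == 5 &
                  res$nt_i == "A" & res$nt_j == "G", ]
  expect_lt(target$p_upper, 0.001)
  expect_true(target$sig_0.001)
  expect_gt(target$observed, target$expected)
})

test_that("type-I error never exceeds the nominal level under a known null", {
  # sites drawn from a known ppm, test run against that same ppm: the
  # add-one doubled-tail procedure is valid (conservative)
  set.seed(83)
  ppm <- background_ppm()
  n_rep <- 30
  frac <- replicate(n_rep, {
    sites <- sample_sites(ppm, 60)
    res <- suppressWarnings(pair_dependence_test(sites, n_sets = 600, ppm = ppm))
    mean(res$p_two_tailed <= 0.05)
  })
  overall <- mean(frac)
  se <- sqrt(0.05 * 0.95 / (n_rep * 240))
  expect_lt(overall, 0.05 + 3 * se)
})

test_that("tidiers summarize the dependence table", {
  set.seed(91)
  sites <- sample_sites(inr_ppm(), 30)
  res <- pair_dependence_test(sites, n_sets = 1000)
  td <- generics::tidy(res)
  expect_false(inherits(td, "interdep_test"))
  g <- generics::glance(res)
  expect_equal(g$n_hypotheses, 240L)
  expect_equal(g$n_sets, 1000)
})
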