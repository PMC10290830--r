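test_that("exact score distribution equals brute-force enumeration", {
  bg <- background_freqs()
  set.seed(101)
  for (i in 1:10) {
    pwm <- random_pwm()
    d <- exact_score_distribution(pwm, bg)
    oracle <- brute_force_score_dist(pwm, bg)
    expect_identical(d$score, oracle$score)
    expect_identical(d$p_value, oracle$p_value)
    # tail probabilities non-increasing in score; 1 at the minimum
    expect_true(all(diff(d$p_value) >= 0))
    expect_equal(d$p_value[nrow(d)], 1)
  }
})

test_that("degenerate and extreme PWMs have the forced distributions", {
  bg <- background_freqs()
  zero <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "T"), 1:6))
  d0 <- exact_score_distribution(zero, bg)
  expect_equal(nrow(d0), 1L)
  expect_equal(d0$score, 0)
  expect_equal(d0$p_value, 1)
  # unique maximum window: tail at the max equals its background probability
  set.seed(5)
  pwm <- random_pwm()
  d <- exact_score_distribution(pwm, bg)
  best <- apply(pwm, 2, which.max)
  expect_equal(d$p_value[1], prod(bg[best]))
})

test_that("scanning respects the p-value threshold and positions", {
  bg <- background_freqs()
  set.seed(13)
  prob <- to_probability(build_count_matrix(sample_sites(inr_ppm(), 40)))
  pwm <- gapped_pwm(prob, "mmmmmm", bg)
  seq100 <- sample_promoters(1, site = "TCAGTT")$sequence
  hits_all <- scan_promoter(seq100, pwm, bg, p_max = 1)
  expect_equal(nrow(hits_all), 95L)  # length - width + 1 windows
  expect_true(all(diff(hits_all$start) > 0))
  # a stringent threshold isolates the planted consensus site
  hits <- scan_promoter(seq100, pwm, bg, p_max = 0.001)
  expect_true(47 %in% hits$start)
  # p_max below the smallest achievable tail: no hits
  d <- exact_score_distribution(pwm, bg)
  none <- scan_promoter(seq100, pwm, bg, p_max = min(d$p_value) / 2)
  expect_equal(nrow(none), 0L)
  expect_error(scan_promoter("ACGT", pwm, bg), "shorter")
  expect_error(scan_promoter(seq100, pwm, bg, p_max = 0), "0, 1")
})

test_that("hit counts grow with the p-value threshold", {
  bg <- background_freqs()
  set.seed(17)
  pwm <- random_pwm()
  s <- sample_promoters(1)$sequence
  d <- exact_score_distribution(pwm, bg)
  counts <- vapply(c(0.001, 0.01, 0.1, 0.5, 1),
                   function(p) nrow(scan_promoter(s, pwm, bg, p_max = p, dist = d)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("PPV and true-hit-ratio arithmetic match the formulas", {
  expect_equal(ppv(8, 2), 0.8)
  expect_equal(ppv(0, 5), 0)
  expect_equal(ppv(5, 0), 1)
  expect_error(ppv(0, 0), "undefined")
  expect_equal(true_hit_ratio(3, 5, 1), 0.75)
  expect_equal(true_hit_ratio(4, 4, 0), 1)
  expect_true(is.na(true_hit_ratio(2, 3, 3)))
  expect_error(true_hit_ratio(5, 3, 0), "exceed")
})

test_that("true positives need at least one base of overlap", {
  expect_true(is_true_positive(10, 15, 21))
  expect_false(is_true_positive(10, 16, 22))
  expect_true(is_true_positive(15, 15, 21))
  expect_false(is_true_positive(21, 15, 21))
  expect_true(is_true_positive(20, 15, 21))
})

test_that("the PPV-maximizing p-value isolates a clean planted site", {
  bg <- background_freqs()
  set.seed(23)
  sites <- sample_sites(inr_ppm(), 60)
  prob <- to_probability(build_count_matrix(sites))
  pwm <- gapped_pwm(prob, "mmmmmm", bg)
  records <- sample_promoters(6, site = "TCAGTT")
  p_star <- select_p_threshold(records, pwm, bg)
  expect_true(p_star > 0 && p_star <= 1)
  # at the selected threshold, pooled PPV is at least as high as at p = 1
  eval_at <- function(p) {
    ev <- evaluate_model(records, pwm, bg, p_value = p, n_scrambles = 1)
    ev$ppv
  }
  expect_gte(eval_at(p_star), eval_at(1))
  expect_equal(eval_at(p_star), 1)
  # two candidates between the same pair of achievable tail values admit the
  # same hit set, hence equal PPV: the smaller one is returned
  d <- exact_score_distribution(pwm, bg)
  k <- which.min(abs(d$p_value - 0.1))
  c1 <- d$p_value[k]
  c2 <- (d$p_value[k] + d$p_value[k + 1]) / 2
  expect_equal(select_p_threshold(records, pwm, bg, candidates = c(c1, c2)), c1)
})

test_that("an uninformative PWM yields geometric overlap and undefined ratios", {
  bg <- background_freqs()
  zero <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "T"), 1:6))
  records <- tibble::tibble(id = "r1",
                            sequence = strrep("ACGT", 25),
                            truth_start = 47, truth_end = 53)
  ev <- evaluate_model(records, zero, bg, p_value = 1, n_scrambles = 2)
  # every window hits; true positives are exactly the 11 windows overlapping
  # a 6-base interior interval; real and scrambled counts cancel
  expect_equal(ev$per_record$all_hits, 95L)
  expect_equal(ev$per_record$true_positive_hits, 11L)
  expect_true(is.na(ev$per_record$true_hit_ratio))
  expect_equal(ev$n_undefined, 1L)
})

test_that("an informative PWM recovers planted sites with high ratios", {
  bg <- background_freqs()
  set.seed(29)
  sites <- sample_sites(inr_ppm(), 60)
  prob <- to_probability(build_count_matrix(sites))
  pwm <- gapped_pwm(prob, "mmmmmm", bg)
  records <- sample_promoters(12, site = inr_ppm())
  ev <- evaluate_model(records, pwm, bg, p_value = 0.006, n_scrambles = 20)
  expect_s3_class(ev, "scan_eval")
  expect_gt(ev$mean_true_hit_ratio, 0.5)
  expect_true(all(ev$per_record$true_positive_hits <= ev$per_record$all_hits))
  g <- generics::glance(ev)
  expect_equal(g$n_records, 12L)
})

test_that("leave-parts-out trials are shaped and seed-reproducible", {
  set.seed(37)
  records <- sample_promoters(24, site = inr_ppm())
  run <- function(seed) {
    set.seed(seed)
    leave_parts_out(records, catalog = "full64", n_trials = 2, train_size = 12,
                    p_value = 0.006, n_scrambles = 3)
  }
  res <- run(99)
  expect_s3_class(res, "lpo_result")
  expect_equal(nrow(res$trials), 2L * 64L)
  expect_equal(length(res$top_models[[1]]), 3L)  # 5% of 64
  expect_true(all(is.na(res$trials$mean_true_hit_ratio[res$trials$model_id == 0])))
  # training and test ids partition the records
  sp <- res$splits[[1]]
  expect_equal(sort(c(sp$train, sp$test)), 1:24)
  res2 <- run(99)
  expect_identical(res$trials, res2$trials)
})

test_that("trial-set correlations behave like Pearson correlations", {
  set.seed(41)
  ratios <- runif(64)
  fake <- tibble::tibble(
    trial = rep(1:20, each = 64),
    model_id = rep(0:63, 20),
    pattern = "x",
    mean_true_hit_ratio = rep(ratios, 20)  # identical sets
  )
  corr <- trial_set_correlations(fake, trials_per_set = 10)
  expect_equal(dim(corr), c(2L, 2L))
  expect_equal(unname(corr[1, 2]), 1)
  # a set against its own negation
  fake2 <- fake
  fake2$mean_true_hit_ratio[fake2$trial > 10] <-
    -fake2$mean_true_hit_ratio[fake2$trial > 10]
  corr2 <- trial_set_correlations(fake2, trials_per_set = 10)
  expect_equal(unname(corr2[1, 2]), -1)
  expect_error(trial_set_correlations(fake[fake$trial <= 10, ]), "two complete")
})

test_that("the shared-window evaluator agrees exactly with evaluate_model", {
  bg <- background_freqs()
  set.seed(47)
  records <- sample_promoters(8, site = inr_ppm())
  prob <- to_probability(build_count_matrix(sample_sites(inr_ppm(), 25)))
  scrambles <- lapply(records$sequence, function(s) {
    vapply(1:3, function(i) scramble_sequence(s), character(1))
  })
  patterns <- c("mmmmmm", "mmkkmm", "mkmkmk", "kmmkkm")
  fast <- gapmotif:::evaluate_models_shared(records, prob, patterns, bg,
                                            0.006, scrambles)
  slow <- vapply(patterns, function(p) {
    pwm <- gapped_pwm(prob, p, bg)
    evaluate_model(records, pwm, bg, p_value = 0.006,
                   scrambles = scrambles)$mean_true_hit_ratio
  }, numeric(1), USE.NAMES = FALSE)
  expect_identical(fast, slow)
})
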