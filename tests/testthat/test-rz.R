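test_that("scrambling preserves composition and is seed-reproducible", {
  expect_identical(scramble_sequence("AAAA"), "AAAA")
  set.seed(9)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
    scr <- scramble_sequence(s)
    expect_equal(nchar(scr), nchar(s))
    expect_equal(sort(strsplit(scr, "")[[1]]), sort(strsplit(s, "")[[1]]))
  }
  set.seed(123)
  a <- scramble_sequence("ACGTACGTAC")
  set.seed(123)
  b <- scramble_sequence("ACGTACGTAC")
  expect_identical(a, b)
})

test_that("training-site scores match an independent hand computation", {
  sites <- c("AACGTT", "ACGTAC")
  bg <- background_freqs()
  tab <- gapped_tuple_table(sites, "mm", pseudocount = 1)
  scores <- score_training_sites(sites, tab, bg)
  # oracle: direct counting and log-odds arithmetic, written independently
  oracle_score <- function(site) {
    total <- 0
    for (f in 0:4) {
      pair_of <- function(s) substr(s, f + 1, f + 2)
      all_pairs <- as.vector(outer(c("A", "C", "G", "T"),
                                   c("A", "C", "G", "T"), paste0))
      freqs <- table(factor(sapply(sites, pair_of), levels = all_pairs))
      freq <- (freqs + 1) / (length(sites) + 16)
      tup <- pair_of(site)
      bp <- bg[substr(tup, 1, 1)] * bg[substr(tup, 2, 2)]
      total <- total + log2(freq[[tup]] / unname(bp))
    }
    total
  }
  expect_equal(scores[1], oracle_score("AACGTT"))
  expect_equal(scores[2], oracle_score("ACGTAC"))
  # identical sites score identically
  same <- score_training_sites(rep("TCAGTT", 5),
                               gapped_tuple_table(rep("TCAGTT", 5), "mkm"), bg)
  expect_true(all(same == same[1]))
})

test_that("percentile thresholds resolve by the lower nearest-rank rule", {
  expect_equal(resolve_threshold(c(1, 2, 3, 4), 0), 1)
  expect_equal(resolve_threshold(c(1, 2, 3, 4), 1), 4)
  expect_equal(resolve_threshold(c(1, 2, 3, 4), 0.75), 4)
  expect_equal(resolve_threshold(c(1, 2, 3, 4), 0.5), 3)
  expect_equal(resolve_threshold(c(4, 2, 1, 3), 0), 1)  # order-free
  expect_error(resolve_threshold(numeric(0), 0.5), "non-empty")
  expect_error(resolve_threshold(1:4, 1.5), "0, 1")
  # detection-set semantics: every site at or above the resolved percentile
  # scores >= the threshold
  set.seed(2)
  s <- rnorm(17)
  for (p in c(0, 0.25, 0.5, 0.75, 1)) {
    thr <- resolve_threshold(s, p)
    expect_gte(sum(s >= thr), max(1, length(s) - floor(p * length(s))))
  }
})

test_that("RZ scores hit the printed anchors and stay in [0, 1]", {
  expect_equal(rz_score(10, 0), 1)
  expect_equal(rz_score(0, 7), 0)
  expect_equal(rz_score(5, 5), 0.5)
  expect_true(is.na(rz_score(0, 0)))
  # monotone in real hits, antitone in scrambled hits
  expect_true(rz_score(6, 3) > rz_score(5, 3))
  expect_true(rz_score(5, 4) < rz_score(5, 3))
  expect_true(all(rz_score(0:10, 5) >= 0 & rz_score(0:10, 5) <= 1))
})

test_that("the RZ screen covers the catalog and is monotone in selectivity", {
  set.seed(31)
  sites <- sample_sites(inr_ppm(), 30)
  proms <- sample_promoters(8, site = inr_ppm())$sequence
  rz <- run_rz_screen(sites, proms, "anchored32")
  expect_s3_class(rz, "rz_screen")
  expect_equal(nrow(rz), 32L * 5L)
  expect_true(all(rz$rz >= 0 & rz$rz <= 1, na.rm = TRUE))
  # raising the threshold position never increases hit counts
  by_model <- split(rz, rz$model_id)
  for (d in by_model) {
    d <- d[order(d$threshold_position), ]
    expect_true(all(diff(d$real_hits) <= 0))
    expect_true(all(diff(d$scrambled_hits) <= 0))
    expect_true(all(diff(d$threshold_value) >= 0))
  }
})

test_that("planted promoters score higher RZ than site-free promoters", {
  set.seed(77)
  sites <- sample_sites(inr_ppm(), 40)
  planted <- sample_promoters(12, length = 60, site = "TCAGTT",
                              offset = 27)$sequence
  empty <- sample_promoters(12, length = 60)$sequence
  rz_planted <- run_rz_screen(sites, planted, "anchored32",
                              threshold_positions = 0.75,
                              scrambles_per_promoter = 5)
  rz_empty <- run_rz_screen(sites, empty, "anchored32",
                            threshold_positions = 0.75,
                            scrambles_per_promoter = 5)
  full_planted <- rz_planted$rz[rz_planted$model_id == 31]
  full_empty <- rz_empty$rz[rz_empty$model_id == 31]
  expect_gt(full_planted, full_empty)
  expect_gt(full_planted, 0.7)
  # at permissive thresholds, site-free promoters cannot be told from their
  # scrambles on average
  rz_null <- run_rz_screen(sites, empty, "anchored32",
                           threshold_positions = c(0, 0.25, 0.5),
                           scrambles_per_promoter = 3)
  expect_lt(abs(mean(rz_null$rz, na.rm = TRUE) - 0.5), 0.1)
})

test_that("good/poor classification follows order statistics with ties", {
  base <- tibble::tibble(
    threshold_position = 0,
    model_id = 1:7,
    pattern = paste0("p", 1:7),
    rz = c(0.9, 0.8, 0.7, 0.5, 0.3, 0.2, 0.1)
  )
  cls <- classify_models(base, target_count = 3)
  expect_setequal(cls$model_id[cls$class == "good"], 1:3)
  expect_setequal(cls$model_id[cls$class == "poor"], 5:7)
  # ties at the cutoff expand the set
  tied <- base
  tied$rz <- c(0.9, 0.8, 0.7, 0.7, 0.5, 0.2, 0.1)
  cls2 <- classify_models(tied, target_count = 3)
  expect_setequal(cls2$model_id[cls2$class == "good"], 1:4)
  expect_error(classify_models(base, target_count = 10), "target_count")
  flat <- base
  flat$rz <- rep(0.5, 7)
  expect_warning(out <- classify_models(flat), "separate")
  expect_equal(nrow(out), 0L)
})
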