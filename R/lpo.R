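# Leave-parts-out cross-validation of gapped-model PWMs.
#
# Repeated random train/test splits guard against overfitting the matrices
# to the search set: each trial builds the full model catalog's PWMs from
# the training records' annotated 6-mers, then evaluates every model on the
# held-out records (true hit ratios against scrambles), recording per-model
# mean ratios and the top/bottom 5% model sets.

# Shared-window evaluation of many models on one test set: extracts the
# window codes of the test sequences and their scrambles once, then scores
# them under each model's PWM. Agrees exactly with evaluate_model() (pinned
# by a test); exists because re-extracting windows per model dominates the
# runtime of a trial.
evaluate_models_shared <- function(records, prob, patterns, background,
                                   p_value, scrambles) {
  width <- ncol(prob)
  n_rec <- nrow(records)
  n_scr <- length(scrambles[[1]])
  win_real <- sequence_windows(records$sequence, width)
  win_scr <- sequence_windows(unlist(scrambles), width)
  scr_record <- rep(seq_len(n_rec), each = n_scr)
  score_codes <- function(codes, pwm) {
    s <- numeric(nrow(codes))
    for (j in seq_len(width)) s <- s + pwm[codes[, j], j]
    unname(s)
  }
  vapply(patterns, function(pattern) {
    pwm <- gapped_pwm(prob, pattern, background)
    dist <- exact_score_distribution(pwm, background)
    hit_real <- lookup_p_value(dist, score_codes(win_real$codes, pwm)) <= p_value
    hit_scr <- lookup_p_value(dist, score_codes(win_scr$codes, pwm)) <= p_value
    all_hits <- tabulate(win_real$seq[hit_real], nbins = n_rec)
    overlaps <- is_true_positive(win_real$start,
                                 records$truth_start[win_real$seq],
                                 records$truth_end[win_real$seq], width = width)
    tp <- tabulate(win_real$seq[hit_real & overlaps], nbins = n_rec)
    avg_scr <- tabulate(scr_record[win_scr$seq[hit_scr]], nbins = n_rec) / n_scr
    ratios <- true_hit_ratio(tp, all_hits, avg_scr)
    if (all(is.na(ratios))) NA_real_ else mean(ratios, na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Leave-parts-out trials over a model catalog
#'
#' Per trial: a uniformly random subset of `train_size` records builds the
#' catalog's gapped PWMs from the truth-interval 6-mers; every model is then
#' evaluated on the remaining records at the fixed p-value threshold, with
#' `n_scrambles` composition-preserving scrambles per test promoter shared
#' across models. Models without considered positions (full64 id 0) get an
#' `NA` mean ratio and are excluded from the rankings.
#'
#' @inheritParams select_p_threshold
#' @param catalog Model catalog (default `"full64"`).
#' @param n_trials Number of random splits (default 50).
#' @param train_size Number of training records per trial (default 102).
#' @param p_value Scanner p-value threshold for every trial (default 0.006,
#'   the median of the PPV-maximizing thresholds of the 16 length-6 anchored
#'   models).
#' @param n_scrambles Scrambles per test promoter (default 100).
#' @param pseudocount Pseudocount for the training count matrices.
#' @param top_fraction Fraction of models reported as top/bottom performers
#'   (default 0.05, i.e. 3 of 64).
#' @return Object of class `lpo_result`: list with `trials` (tibble: `trial`,
#'   `model_id`, `pattern`, `mean_true_hit_ratio`), `splits` (list of
#'   train/test index vectors), `top_models`/`bottom_models` (lists of model
#'   id vectors per trial) and the run parameters.
#' @export
leave_parts_out <- function(records, catalog = c("full64", "anchored32"),
                            n_trials = 50, train_size = 102,
                            p_value = 0.006, n_scrambles = 100,
                            pseudocount = 1,
                            background = background_freqs(),
                            top_fraction = 0.05) {
  records <- validate_records(records)
  catalog <- match_catalog(match.arg(catalog))
  n <- nrow(records)
  if (n < train_size + 1) abort("`records` must have at least train_size + 1 rows")
  site_length <- unique(records$truth_end - records$truth_start)
  if (length(site_length) != 1L) abort("all truth intervals must share one length")
  models <- enumerate_models(site_length, catalog)
  n_top <- max(1L, round(top_fraction * nrow(models)))

  trials <- vector("list", n_trials)
  splits <- vector("list", n_trials)
  tops <- vector("list", n_trials)
  bottoms <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    train_idx <- sort(sample.int(n, train_size))
    test_idx <- setdiff(seq_len(n), train_idx)
    train_sites <- substr(records$sequence[train_idx],
                          records$truth_start[train_idx] + 1L,
                          records$truth_end[train_idx])
    prob <- to_probability(build_count_matrix(train_sites, pseudocount))
    test_records <- records[test_idx, , drop = FALSE]
    scrambles <- lapply(test_records$sequence, function(s) {
      vapply(seq_len(n_scrambles), function(i) scramble_sequence(s), character(1))
    })
    ratios <- rep(NA_real_, nrow(models))
    # only full-length models map onto scanning PWMs; shorter patterns (and
    # the zero-position model) carry NA ratios and are excluded from ranking
    scoreable <- models$n_considered > 0L & models$length == site_length
    ratios[scoreable] <- evaluate_models_shared(
      test_records, prob, models$pattern[scoreable], background,
      p_value, scrambles)
    ranked <- order(ratios, decreasing = TRUE, na.last = NA)
    trials[[t]] <- tibble(trial = t, model_id = models$model_id,
                          pattern = models$pattern,
                          mean_true_hit_ratio = ratios)
    splits[[t]] <- list(train = train_idx, test = test_idx)
    tops[[t]] <- models$model_id[head(ranked, n_top)]
    bottoms[[t]] <- models$model_id[tail(ranked, n_top)]
  }
  structure(
    list(trials = list_rbind(trials), splits = splits,
         top_models = tops, bottom_models = bottoms,
         catalog = catalog, n_trials = n_trials, train_size = train_size,
         p_value = p_value, n_scrambles = n_scrambles, n_top = n_top),
    class = "lpo_result"
  )
}

#' @export
print.lpo_result <- function(x, ...) {
  avg <- x$trials |>
    group_by(.data$model_id, .data$pattern) |>
    summarise(avg = mean(.data$mean_true_hit_ratio, na.rm = TRUE),
              .groups = "drop") |>
    arrange(desc(.data$avg))
  cat(sprintf("Leave-parts-out: %d trials, %s catalog, train size %d, p <= %g\n",
              x$n_trials, x$catalog, x$train_size, x$p_value))
  cat("Top models by average mean true hit ratio:\n")
  print(head(avg, 5))
  invisible(x)
}

#' Pearson correlations between sets of leave-parts-out trials
#'
#' Groups consecutive trials into sets, averages each model's mean true hit
#' ratio within each set, and returns the Pearson correlation matrix
#' between the sets' per-model averages (unit diagonal). Zero-variance sets
#' yield `NA` entries with a warning.
#'
#' @param lpo `lpo_result` from [leave_parts_out()], or a tibble with
#'   columns `trial`, `model_id`, `mean_true_hit_ratio`.
#' @param trials_per_set Number of consecutive trials per set (default 10).
#' @return Symmetric correlation matrix, one row/column per set.
#' @export
trial_set_correlations <- function(lpo, trials_per_set = 10) {
  trials <- if (inherits(lpo, "lpo_result")) lpo$trials else lpo
  stopifnot(is.data.frame(trials))
  n_trials <- length(unique(trials$trial))
  n_sets <- n_trials %/% trials_per_set
  if (n_sets < 2) abort("need at least two complete trial sets")
  trials <- trials |>
    filter(!is.na(.data$mean_true_hit_ratio)) |>
    mutate(set = (match(.data$trial, sort(unique(trials$trial))) - 1L) %/%
             trials_per_set + 1L) |>
    filter(.data$set <= n_sets)
  wide <- trials |>
    group_by(.data$set, .data$model_id) |>
    summarise(avg = mean(.data$mean_true_hit_ratio), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "set", values_from = "avg",
                       names_prefix = "set_")
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (any(apply(m, 2L, stats::sd, na.rm = TRUE) == 0, na.rm = TRUE)) {
    warn("a trial set has zero variance across models; correlations undefined")
  }
  suppressWarnings(cor(m, use = "pairwise.complete.obs"))
}
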