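# PWM scanning with exact enumeration p-values.
#
# At motif width 6 there are only 4^6 = 4096 windows, so the null score
# distribution under the background model is enumerated exactly rather than
# approximated: every window gets the product of its letters' background
# probabilities, and the tail P(score >= s) is exact for every achievable
# score. Forward strand only (core promoter elements are orientation
# specific); the p-value threshold is either supplied or chosen to maximize
# positive predictive value over annotated truth intervals.

#' Exact score distribution of a PWM under the background model
#'
#' Enumerates all `4^width` windows, scores each with the PWM, assigns each
#' the product of its letters' background probabilities, and returns the
#' exact tail probability `P(score >= s)` for every achievable score.
#'
#' @param pwm 4 x width weight matrix (e.g. from [gapped_pwm()]).
#' @param background Background probabilities.
#' @return A tibble of class `score_dist` with columns `score` (decreasing)
#'   and `p_value` (increasing tail probability; 1 at the minimum score).
#' @export
exact_score_distribution <- function(pwm, background = background_freqs()) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4L)
  background <- validate_background(background)
  width <- ncol(pwm)
  codes <- expand_bits4(width) + 1L
  scores <- numeric(nrow(codes))
  probs <- rep(1, nrow(codes))
  for (j in seq_len(width)) {
    scores <- scores + pwm[codes[, j], j]
    probs <- probs * background[codes[, j]]
  }
  ord <- order(scores, decreasing = TRUE)
  scores <- unname(scores[ord])
  tail_p <- cumsum(probs[ord])
  # merge exactly-equal scores: tail at a score covers all its ties
  keep <- !duplicated(scores, fromLast = TRUE)
  out <- tibble(score = scores[keep], p_value = unname(tail_p[keep]))
  class(out) <- c("score_dist", class(out))
  out
}

# Tail p-value lookup for scores computed with the same arithmetic as the
# enumeration (scores match enumerated values exactly).
lookup_p_value <- function(dist, scores) {
  asc_scores <- rev(dist$score)
  asc_p <- rev(dist$p_value)
  idx <- findInterval(scores, asc_scores)
  idx[idx < 1L] <- 1L
  asc_p[idx]
}

#' Scan a sequence for PWM hits with exact p-values
#'
#' Scores every forward-strand window and reports those whose exact tail
#' p-value is at or below `p_max`, sorted by position.
#'
#' @param sequence Single A/C/G/T string at least as long as the PWM width.
#' @inheritParams exact_score_distribution
#' @param p_max Hit threshold on the exact tail p-value, in `(0, 1]`.
#' @param dist Optional precomputed [exact_score_distribution()].
#' @return Tibble with columns `start` (0-based window start), `score`,
#'   `p_value`.
#' @export
scan_promoter <- function(sequence, pwm, background = background_freqs(),
                          p_max = 1, dist = NULL) {
  if (p_max <= 0 || p_max > 1) abort("`p_max` must be in (0, 1]")
  if (length(sequence) != 1L) abort("`sequence` must be a single string")
  sequence <- toupper(sequence)
  if (nchar(sequence) < ncol(pwm)) abort("sequence is shorter than the PWM width")
  dist <- dist %||% exact_score_distribution(pwm, background)
  win <- sequence_windows(sequence, ncol(pwm))
  scores <- numeric(nrow(win$codes))
  for (j in seq_len(ncol(pwm))) scores <- scores + pwm[win$codes[, j], j]
  p <- lookup_p_value(dist, scores)
  keep <- p <= p_max
  tibble(start = win$start[keep], score = scores[keep], p_value = p[keep])
}

#' Positive predictive value
#'
#' `TP / (TP + FP)` over scanner hits judged against annotated truth.
#'
#' @param true_positives,false_positives Non-negative hit counts, not both
#'   zero.
#' @return Number in `[0, 1]`.
#' @examples
#' ppv(8, 2)
#' @export
ppv <- function(true_positives, false_positives) {
  if (true_positives < 0 || false_positives < 0) abort("counts must be >= 0")
  if (true_positives + false_positives == 0) {
    abort("PPV is undefined when there are no hits")
  }
  true_positives / (true_positives + false_positives)
}

#' Is a hit window a true positive?
#'
#' A hit is a true positive when its window overlaps the annotated truth
#' interval by at least one base. Intervals are 0-based half-open.
#'
#' @param hit_start 0-based start(s) of the hit window(s).
#' @param truth_start,truth_end 0-based half-open truth interval.
#' @param width Hit window width (default 6).
#' @return Logical vector.
#' @examples
#' is_true_positive(10, 15, 21)  # one-base overlap
#' is_true_positive(10, 16, 22)  # adjacent, no overlap
#' @export
is_true_positive <- function(hit_start, truth_start, truth_end, width = 6) {
  hit_start < truth_end & (hit_start + width) > truth_start
}

#' True hit ratio
#'
#' Per-promoter accuracy statistic: true positive hits on the real sequence
#' divided by (all hits on the real sequence minus the average number of
#' hits on its scrambles). Undefined (`NA`) when the denominator is not
#' positive.
#'
#' @param tp True positive hits on the real sequence.
#' @param all_hits All hits on the real sequence (`tp <= all_hits`).
#' @param avg_scrambled Average hit count over the scrambles.
#' @return Number, or `NA` when `all_hits - avg_scrambled <= 0`.
#' @examples
#' true_hit_ratio(3, 5, 1)
#' @export
true_hit_ratio <- function(tp, all_hits, avg_scrambled) {
  if (any(tp > all_hits)) abort("`tp` cannot exceed `all_hits`")
  if (any(avg_scrambled < 0)) abort("`avg_scrambled` must be >= 0")
  denom <- all_hits - avg_scrambled
  out <- tp / denom
  out[denom <= 0] <- NA_real_
  out
}

validate_records <- function(records, need_truth = TRUE) {
  stopifnot(is.data.frame(records))
  needed <- c("id", "sequence", if (need_truth) c("truth_start", "truth_end"))
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("`records` lacks column(s): %s%s",
                  paste(missing_cols, collapse = ", "),
                  if (any(c("truth_start", "truth_end") %in% missing_cols))
                    " (evaluation needs annotated truth intervals)" else ""))
  }
  if (need_truth) {
    bad <- records$truth_start < 0 | records$truth_end > nchar(records$sequence) |
      records$truth_start >= records$truth_end
    if (any(bad)) abort("truth intervals must lie within the sequence bounds")
  }
  records
}

#' Select the PPV-maximizing p-value threshold
#'
#' Candidate thresholds default to the achievable tail probabilities of the
#' PWM (plus 1.0), since PPV is piecewise constant between them. Returns the
#' candidate maximizing pooled PPV over all records' hits; ties break toward
#' the smallest (most selective) p-value.
#'
#' @param records Tibble with columns `id`, `sequence`, `truth_start`,
#'   `truth_end` (0-based half-open truth intervals).
#' @inheritParams scan_promoter
#' @param candidates Optional numeric vector of candidate p-values.
#' @return The selected p-value threshold.
#' @export
select_p_threshold <- function(records, pwm, background = background_freqs(),
                               candidates = NULL) {
  records <- validate_records(records)
  dist <- exact_score_distribution(pwm, background)
  candidates <- sort(unique(c(candidates %||% dist$p_value, 1)))
  hits <- lapply(seq_len(nrow(records)), function(i) {
    h <- scan_promoter(records$sequence[i], pwm, background, p_max = 1, dist = dist)
    h$tp <- is_true_positive(h$start, records$truth_start[i], records$truth_end[i],
                             width = ncol(pwm))
    h
  })
  hits <- list_rbind(hits)
  ppvs <- vapply(candidates, function(p) {
    sub <- hits[hits$p_value <= p, , drop = FALSE]
    if (nrow(sub) == 0L) return(NA_real_)
    ppv(sum(sub$tp), sum(!sub$tp))
  }, numeric(1))
  if (all(is.na(ppvs))) abort("no candidate p-value yields any hit")
  candidates[which.max(ppvs)]  # which.max: first (smallest p) among ties
}

#' Evaluate a model PWM on annotated promoters
#'
#' For each promoter record: counts hits on the real sequence at the given
#' p-value threshold, true positives (>= 1 base overlap with the truth
#' interval), and the mean hit count over composition-preserving scrambles;
#' computes per-record true hit ratios and their mean over records where
#' the ratio is defined.
#'
#' @inheritParams select_p_threshold
#' @param p_value Hit threshold on the exact tail p-value.
#' @param n_scrambles Scrambles per promoter (default 100).
#' @param scrambles Optional precomputed scrambles: list (one element per
#'   record) of character vectors; used to share scrambles across models.
#' @return Object of class `scan_eval`: list with `per_record` tibble (`id`,
#'   `all_hits`, `true_positive_hits`, `avg_scrambled_hits`,
#'   `true_hit_ratio`), `mean_true_hit_ratio`, `n_undefined`, `ppv` and
#'   `p_value`.
#' @export
evaluate_model <- function(records, pwm, background = background_freqs(),
                           p_value = 0.006, n_scrambles = 100,
                           scrambles = NULL) {
  records <- validate_records(records)
  if (is.null(scrambles)) {
    if (n_scrambles < 1) abort("`n_scrambles` must be >= 1")
    scrambles <- lapply(records$sequence, function(s) {
      vapply(seq_len(n_scrambles), function(i) scramble_sequence(s), character(1))
    })
  }
  dist <- exact_score_distribution(pwm, background)
  width <- ncol(pwm)
  per <- lapply(seq_len(nrow(records)), function(i) {
    h <- scan_promoter(records$sequence[i], pwm, background, p_max = p_value,
                       dist = dist)
    tp <- sum(is_true_positive(h$start, records$truth_start[i],
                               records$truth_end[i], width = width))
    scr_hits <- vapply(scrambles[[i]], function(s) {
      nrow(scan_promoter(s, pwm, background, p_max = p_value, dist = dist))
    }, numeric(1), USE.NAMES = FALSE)
    tibble(id = records$id[i], all_hits = nrow(h), true_positive_hits = tp,
           avg_scrambled_hits = mean(scr_hits))
  })
  per <- list_rbind(per)
  per$true_hit_ratio <- true_hit_ratio(per$true_positive_hits, per$all_hits,
                                       per$avg_scrambled_hits)
  total_hits <- sum(per$all_hits)
  structure(
    list(per_record = per,
         mean_true_hit_ratio = if (all(is.na(per$true_hit_ratio))) NA_real_
                               else mean(per$true_hit_ratio, na.rm = TRUE),
         n_undefined = sum(is.na(per$true_hit_ratio)),
         ppv = if (total_hits == 0) NA_real_
               else ppv(sum(per$true_positive_hits),
                        total_hits - sum(per$true_positive_hits)),
         p_value = p_value),
    class = "scan_eval"
  )
}

#' @export
print.scan_eval <- function(x, ...) {
  cat(sprintf(paste0("PWM scan evaluation over %d promoters (p <= %g)\n",
                     "  mean true hit ratio: %s (%d undefined)\n",
                     "  pooled PPV: %s\n"),
              nrow(x$per_record), x$p_value,
              format(x$mean_true_hit_ratio, digits = 4), x$n_undefined,
              format(x$ppv, digits = 4)))
  invisible(x)
}
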