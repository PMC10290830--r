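# Real-versus-scrambled (RZ) scoring of gapped models.
#
# A model's score for a 6 bp window is the sum over its sliding frames of
# the log-odds of the observed considered-tuple frequency (from the training
# tuple table) against the background product for that tuple. Training-site
# scores resolve percentile thresholds; promoter windows scoring at or above
# a threshold are counted as predicted binding sites, separately on the real
# promoters and on composition-preserving scrambles.

#' Scramble a nucleotide sequence
#'
#' Uniform random permutation of the sequence's characters: the per-letter
#' composition is conserved exactly, giving a matched null sequence.
#'
#' @param seq Single A/C/G/T string.
#' @return Scrambled string of the same composition.
#' @examples
#' set.seed(1)
#' scramble_sequence("TCAGTT")
#' @export
scramble_sequence <- function(seq) {
  if (length(seq) != 1L || !is.character(seq)) abort("`seq` must be a single string")
  seq <- toupper(seq)
  seq_to_codes(seq, "sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(sample(chars), collapse = "")
}

# Score every length-site_length window of a code matrix (n x site_length)
# under a tuple table: sum over frames of log2(tuple freq / background
# product of the tuple).
score_window_codes <- function(codes, table, background) {
  background <- validate_background(background)
  offs <- considered_offsets(table$pattern)
  bg <- tuple_background(table$arity, background)
  n_frames <- table$site_length - nchar(table$pattern) + 1L
  scores <- numeric(nrow(codes))
  for (f in seq_len(n_frames) - 1L) {
    freq <- if (table$pooled) table$frames[[1]] else table$frames[[f + 1L]]
    lo <- log2(unname(freq) / bg)
    idx <- tuple_codes(codes, offs + f + 1L)
    scores <- scores + lo[idx]
  }
  scores
}

#' Score training sites under a model's tuple table
#'
#' One score per aligned site: the sum over the model's sliding frames of
#' the log-odds of the observed considered-tuple frequency against the
#' background product for that tuple.
#'
#' @inheritParams build_count_matrix
#' @param table [gapped_tuple_table()] built from the same model.
#' @param background Background probabilities (see [background_freqs()]).
#' @return Numeric vector of site scores.
#' @export
score_training_sites <- function(sites, table, background = background_freqs()) {
  sites <- validate_sites(sites)
  if (!inherits(table, "tuple_table")) abort("`table` must be a tuple_table")
  codes <- seq_to_codes(sites, "site")
  if (ncol(codes) != table$site_length) {
    abort("site length does not match the table's site length")
  }
  score_window_codes(codes, table, background)
}

# All length-`width` windows of a set of sequences, as a code matrix plus
# the originating sequence index.
sequence_windows <- function(seqs, width) {
  lens <- nchar(seqs)
  if (any(lens < width)) abort("sequence shorter than the scanning width")
  codes <- lapply(seqs, function(s) seq_to_codes(s, "sequence")[1L, ])
  n_win <- lens - width + 1L
  out <- matrix(0L, nrow = sum(n_win), ncol = width)
  seq_idx <- integer(sum(n_win))
  start <- integer(sum(n_win))
  r <- 0L
  for (i in seq_along(seqs)) {
    cs <- codes[[i]]
    for (j in seq_len(width)) {
      out[(r + 1L):(r + n_win[i]), j] <- cs[j:(j + n_win[i] - 1L)]
    }
    seq_idx[(r + 1L):(r + n_win[i])] <- i
    start[(r + 1L):(r + n_win[i])] <- seq_len(n_win[i]) - 1L
    r <- r + n_win[i]
  }
  list(codes = out, seq = seq_idx, start = start)
}

#' Resolve a percentile threshold position into a score cutoff
#'
#' Threshold positions are percentiles (0..1) of the training-site score
#' distribution, resolved by the lower nearest-rank rule: the returned
#' cutoff is the score of the site whose lower empirical percentile first
#' reaches the position, so that site and everything above it are detected
#' under the rule `score >= threshold`. Position 0 returns the minimum
#' training score (every training site detected); position 1 the maximum
#' (only the top site detected).
#'
#' @param scores Non-empty numeric vector of training-site scores.
#' @param position Number in `[0, 1]`.
#' @return Score cutoff.
#' @examples
#' resolve_threshold(c(1, 2, 3, 4), 0.75)
#' @export
resolve_threshold <- function(scores, position) {
  if (length(scores) == 0L) abort("`scores` must be non-empty")
  if (position < 0 || position > 1) abort("`position` must be in [0, 1]")
  s <- sort(scores)
  k <- min(length(s), floor(position * length(s)) + 1L)
  s[k]
}

#' Real-versus-scrambled discrimination (RZ) score
#'
#' `real_hits / (real_hits + scrambled_hits)`: 1 when binding sites are
#' found only in the real sequences, 0 when only in the scrambled ones, 0.5
#' when the counts balance. Undefined (`NA`) when both counts are zero,
#' distinguishing "no signal" from "balanced signal".
#'
#' @param real_hits Number of predicted sites in the real sequences.
#' @param scrambled_hits Number (possibly a replicate average) of predicted
#'   sites in the scrambled sequences.
#' @return Number in `[0, 1]`, or `NA` when both counts are zero.
#' @examples
#' rz_score(10, 0)
#' rz_score(5, 5)
#' @export
rz_score <- function(real_hits, scrambled_hits) {
  if (any(real_hits < 0) || any(scrambled_hits < 0)) abort("hit counts must be >= 0")
  out <- real_hits / (real_hits + scrambled_hits)
  out[real_hits == 0 & scrambled_hits == 0] <- NA_real_
  out
}

#' Run the real-versus-scrambled screen over a model catalog
#'
#' For every model in the catalog and every threshold position: build the
#' model's tuple table from the aligned training sites, resolve the
#' threshold from the training-site scores, scan every 6 bp window of every
#' promoter (and of composition-preserving scrambles of each promoter), and
#' count windows scoring at or above the threshold. Scrambled counts are
#' averaged over scramble replicates. Models without considered positions
#' (full64 id 0) yield `NA` rows.
#'
#' @inheritParams build_count_matrix
#' @param promoters Character vector of promoter sequences (A/C/G/T, any
#'   lengths at or above the site length).
#' @param catalog `"anchored32"` or `"full64"`.
#' @param threshold_positions Percentile positions in `[0, 1]`.
#' @param scrambles_per_promoter Scramble replicates per promoter.
#' @param background Background probabilities.
#' @return A tibble of class `rz_screen` with one row per model x threshold:
#'   `catalog`, `model_id`, `pattern`, `threshold_position`,
#'   `threshold_value`, `real_hits`, `scrambled_hits`, `rz`.
#' @export
run_rz_screen <- function(sites, promoters,
                          catalog = c("anchored32", "full64"),
                          threshold_positions = c(0, 0.25, 0.5, 0.75, 1),
                          scrambles_per_promoter = 1,
                          pseudocount = 1,
                          background = background_freqs()) {
  sites <- validate_sites(sites)
  catalog <- match_catalog(match.arg(catalog))
  if (length(promoters) == 0L) abort("`promoters` must be non-empty")
  promoters <- toupper(promoters)
  background <- validate_background(background)
  site_length <- nchar(sites[1L])
  models <- enumerate_models(site_length, catalog)

  scrambles <- lapply(promoters, function(p) {
    vapply(seq_len(scrambles_per_promoter), function(i) scramble_sequence(p),
           character(1))
  })
  real_win <- sequence_windows(promoters, site_length)
  scr_win <- lapply(seq_len(scrambles_per_promoter), function(r) {
    sequence_windows(vapply(scrambles, `[[`, character(1), r), site_length)
  })

  rows <- lapply(seq_len(nrow(models)), function(i) {
    pattern <- models$pattern[i]
    base <- tibble(catalog = catalog, model_id = models$model_id[i],
                   pattern = pattern,
                   threshold_position = threshold_positions)
    if (models$n_considered[i] == 0L) {
      return(mutate(base, threshold_value = NA_real_, real_hits = NA_real_,
                    scrambled_hits = NA_real_, rz = NA_real_))
    }
    tab <- gapped_tuple_table(sites, pattern, pseudocount = pseudocount)
    train <- score_training_sites(sites, tab, background)
    real_scores <- score_window_codes(real_win$codes, tab, background)
    scr_scores <- lapply(scr_win, function(w) score_window_codes(w$codes, tab, background))
    thr <- vapply(threshold_positions, resolve_threshold, numeric(1), scores = train)
    real_hits <- vapply(thr, function(t) sum(real_scores >= t), numeric(1))
    scrambled_hits <- vapply(thr, function(t) {
      mean(vapply(scr_scores, function(s) sum(s >= t), numeric(1)))
    }, numeric(1))
    mutate(base, threshold_value = thr, real_hits = real_hits,
           scrambled_hits = scrambled_hits,
           rz = rz_score(real_hits, scrambled_hits))
  })
  out <- list_rbind(rows)
  class(out) <- c("rz_screen", class(out))
  out
}

#' Classify good and poor models at each threshold
#'
#' At each threshold position, the `target_count` models with the highest RZ
#' scores (including ties at the cutoff) are classified good, and the
#' `target_count` lowest poor; ties may expand either set. Models whose RZ
#' is undefined are left unclassified, and if the good and poor cutoffs
#' collide (e.g. all scores equal) both sets are empty with a warning.
#'
#' @param rz_table `rz_screen` tibble from [run_rz_screen()].
#' @param target_count Target number of models per class (default 3).
#' @return A tibble with columns `threshold_position`, `model_id`,
#'   `pattern`, `rz`, `class` (`"good"` or `"poor"`) plus the cutoffs used
#'   as columns `good_cutoff`, `poor_cutoff`.
#' @export
classify_models <- function(rz_table, target_count = 3) {
  stopifnot(is.data.frame(rz_table))
  out <- lapply(split(rz_table, rz_table$threshold_position), function(d) {
    d <- d[!is.na(d$rz), , drop = FALSE]
    if (target_count > nrow(d)) {
      abort("`target_count` exceeds the number of models with defined RZ scores")
    }
    sorted <- sort(d$rz, decreasing = TRUE)
    good_cut <- sorted[target_count]
    poor_cut <- sort(d$rz)[target_count]
    if (good_cut <= poor_cut) {
      warn(sprintf("RZ scores at threshold %s do not separate good from poor models",
                   format(d$threshold_position[1])))
      return(NULL)
    }
    d$class <- NA_character_
    d$class[d$rz >= good_cut] <- "good"
    d$class[d$rz <= poor_cut] <- "poor"
    d <- d[!is.na(d$class), c("threshold_position", "model_id", "pattern", "rz", "class")]
    d$good_cutoff <- good_cut
    d$poor_cutoff <- poor_cut
    d
  })
  list_rbind(unname(out))
}
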