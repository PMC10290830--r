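# Count, probability, log-odds and gapped-model matrices from aligned sites.
#
# Matrices are plain 4 x L numeric matrices with rows A, C, G, T and 1-based
# position columns; construction parameters (pseudocount, background, log
# base, model pattern) travel as attributes and are recorded by the writers.

#' Nucleotide count matrix from aligned sites
#'
#' Counts each nucleotide at each position over an alignment of equal-length
#' A/C/G/T sites, adding a pseudocount to every cell. The default +1
#' pseudocount eliminates zero frequencies; every column then sums to
#' `n_sites + 4 * pseudocount`.
#'
#' @param sites Character vector of equal-length sites.
#' @param pseudocount Non-negative number added to every cell (default 1).
#' @return 4 x L numeric matrix (rows A, C, G, T) with attributes
#'   `pseudocount` and `n_sites`.
#' @examples
#' build_count_matrix(c("TCAGTT", "TCAGTC"))
#' @export
build_count_matrix <- function(sites, pseudocount = 1) {
  sites <- validate_sites(sites)
  if (pseudocount < 0) abort("`pseudocount` must be >= 0")
  codes <- seq_to_codes(sites, "site")
  counts <- apply(codes, 2L, tabulate, nbins = 4L) + pseudocount
  dimnames(counts) <- list(NUCLEOTIDES, seq_len(ncol(counts)))
  structure(counts, pseudocount = pseudocount, n_sites = length(sites))
}

#' Column-normalize a count matrix into a probability matrix
#'
#' @param counts 4 x L count matrix from [build_count_matrix()].
#' @return 4 x L column-stochastic matrix.
#' @examples
#' to_probability(build_count_matrix(c("TCAGTT", "TCAGTC")))
#' @export
to_probability <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == 4L)
  prob <- sweep(counts, 2L, colSums(counts), "/")
  structure(prob,
            pseudocount = attr(counts, "pseudocount"),
            n_sites = attr(counts, "n_sites"))
}

#' Log-odds position weight matrix
#'
#' Each entry is the logarithm (base `log_base`, default 2) of the position
#' probability over the background probability of that nucleotide.
#'
#' @param prob 4 x L probability matrix.
#' @param background Named background probability vector (see
#'   [background_freqs()]).
#' @param log_base Logarithm base (default 2).
#' @return 4 x L weight matrix with attributes `background` and `log_base`.
#' @examples
#' prob <- to_probability(build_count_matrix(c("TCAGTT", "TCAGTC")))
#' to_log_odds(prob)
#' @export
to_log_odds <- function(prob, background = background_freqs(), log_base = 2) {
  stopifnot(is.matrix(prob), nrow(prob) == 4L)
  background <- validate_background(background)
  if (any(prob == 0)) {
    abort("probability matrix contains zeros; rebuild counts with a positive pseudocount")
  }
  w <- log(prob / background, base = log_base)
  structure(w, background = background, log_base = log_base,
            pseudocount = attr(prob, "pseudocount"))
}

#' Gapped-model position weight matrix
#'
#' Builds the scanning PWM for a full-length gapped model: considered (`m`)
#' columns carry the log-odds of the site probabilities, ignored (`k`)
#' columns carry the background (zero log-odds), so changing a window at an
#' ignored position never changes its score.
#'
#' @inheritParams to_log_odds
#' @param pattern Model pattern of length `ncol(prob)` (full64 use).
#' @return 4 x L weight matrix with attribute `pattern`.
#' @examples
#' prob <- to_probability(build_count_matrix(c("TCAGTT", "TCAGTC")))
#' gapped_pwm(prob, "mmkkmm")
#' @export
gapped_pwm <- function(prob, pattern, background = background_freqs(),
                       log_base = 2) {
  pattern <- validate_pattern(pattern)
  stopifnot(is.matrix(prob), nrow(prob) == 4L)
  if (nchar(pattern) != ncol(prob)) {
    abort("`pattern` must cover every column of `prob`")
  }
  if (considered_count(pattern) == 0L) {
    abort("model has no considered positions; a scoring matrix needs at least one 'm'")
  }
  w <- to_log_odds(prob, background, log_base)
  w[, pattern_bits(pattern) == 0L] <- 0
  structure(w, pattern = pattern, background = validate_background(background),
            log_base = log_base)
}

# 0-based considered-position offsets of a pattern.
considered_offsets <- function(pattern) {
  which(pattern_bits(pattern) == 1L) - 1L
}

# Tuple labels for c considered positions, in the encoding order used by
# tuple_codes(): first considered position most significant, A=0..T=3.
tuple_labels <- function(arity) {
  if (arity == 0L) return(character(0))
  g <- expand_bits4(arity)
  vapply(seq_len(nrow(g)), function(i) paste(NUCLEOTIDES[g[i, ] + 1L], collapse = ""),
         character(1))
}

expand_bits4 <- function(n) {
  g <- do.call(expand.grid, rep(list(0:3), n))
  as.matrix(g[, rev(seq_len(n)), drop = FALSE])
}

# Encode the considered-position tuple of each row of a code matrix.
# `codes` is n x L (A=1..T=4); `cols` the 1-based considered columns.
# Returns 1-based tuple indices into tuple_labels(length(cols)).
tuple_codes <- function(codes, cols) {
  arity <- length(cols)
  idx <- rep(0L, nrow(codes))
  for (j in seq_along(cols)) {
    idx <- idx * 4L + (codes[, cols[j]] - 1L)
  }
  idx + 1L
}

#' Joint tuple frequency table for a gapped model
#'
#' For each sliding frame of the model within the sites, tallies the joint
#' tuple of nucleotides at the model's considered positions over all sites
#' (a table over the `4^c` tuples of the `c` considered positions), adds a
#' pseudocount to every tuple cell, and normalizes. Unlike a PWM, the tuple
#' table captures within-frame dependence between considered positions.
#'
#' @inheritParams build_count_matrix
#' @param pattern Model pattern, length at most the site length.
#' @param pooled If `TRUE`, average the per-frame tables into one table.
#' @return Object of class `tuple_table`: list with `pattern`, `arity`,
#'   `site_length`, `pooled`, `pseudocount` and `frames` (list of named
#'   frequency vectors, one per frame, or a single pooled table).
#' @examples
#' gapped_tuple_table(c("TCAGTT", "TCAGTC"), "mm")
#' @export
gapped_tuple_table <- function(sites, pattern, pseudocount = 1, pooled = FALSE) {
  sites <- validate_sites(sites)
  pattern <- validate_pattern(pattern)
  if (considered_count(pattern) == 0L) {
    abort("model has no considered positions; a scoring matrix needs at least one 'm'")
  }
  codes <- seq_to_codes(sites, "site")
  site_length <- ncol(codes)
  if (nchar(pattern) > site_length) abort("model is longer than the site")
  arity <- considered_count(pattern)
  offs <- considered_offsets(pattern)
  labels <- tuple_labels(arity)
  n_frames <- frame_count(pattern, site_length)
  frames <- lapply(seq_len(n_frames) - 1L, function(f) {
    idx <- tuple_codes(codes, offs + f + 1L)
    cnt <- tabulate(idx, nbins = 4L^arity) + pseudocount
    setNames(cnt / sum(cnt), labels)
  })
  if (pooled) frames <- list(Reduce(`+`, frames) / n_frames)
  structure(
    list(pattern = pattern, arity = arity, site_length = site_length,
         pooled = pooled, pseudocount = pseudocount, frames = frames),
    class = "tuple_table"
  )
}

#' @export
print.tuple_table <- function(x, ...) {
  cat(sprintf("Gapped tuple table: model %s (%d considered position%s), %s\n",
              x$pattern, x$arity, if (x$arity == 1L) "" else "s",
              if (x$pooled) "pooled over frames" else
                sprintf("%d frame%s", length(x$frames),
                        if (length(x$frames) == 1L) "" else "s")))
  invisible(x)
}

# Background probability of each tuple (product over considered positions).
tuple_background <- function(arity, background) {
  background <- validate_background(background)
  g <- expand_bits4(arity)
  apply(g, 1L, function(r) prod(background[r + 1L]))
}
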