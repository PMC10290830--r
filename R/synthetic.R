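# Synthetic binding sites and promoters with known ground truth.
#
# Every pipeline stage is testable without external data: sites are drawn
# with independent positions from a ppm, optionally with a planted pairwise
# coupling (mixture forcing, which has closed-form joint and marginal
# frequencies), and promoters are i.i.d. background sequence with a planted
# 6-mer at a known, recorded offset.

#' Stylized initiator-like position probability matrix
#'
#' A 4 x 6 matrix with consensus TCAGTY (position 6 split between T and C),
#' loosely shaped like the fly initiator element. Probabilities are stated
#' in the source; this is a synthetic fixture, not the empirical matrix of
#' any promoter database.
#'
#' @return 4 x 6 column-stochastic matrix.
#' @export
inr_ppm <- function() {
  m <- matrix(c(
    # pos1  pos2  pos3  pos4  pos5  pos6
    0.05, 0.14, 0.90, 0.08, 0.10, 0.08,  # A
    0.05, 0.70, 0.04, 0.07, 0.08, 0.40,  # C
    0.05, 0.08, 0.03, 0.75, 0.12, 0.07,  # G
    0.85, 0.08, 0.03, 0.10, 0.70, 0.45   # T
  ), nrow = 4L, byrow = TRUE, dimnames = list(NUCLEOTIDES, 1:6))
  validate_ppm(m)
}

#' Stylized TATA-box-like position probability matrix
#'
#' A 4 x 6 synthetic fixture with consensus TATAAA.
#'
#' @return 4 x 6 column-stochastic matrix.
#' @export
tata_ppm <- function() {
  m <- matrix(c(
    0.10, 0.90, 0.09, 0.90, 0.75, 0.55,  # A
    0.04, 0.03, 0.03, 0.03, 0.05, 0.08,  # C
    0.04, 0.03, 0.03, 0.03, 0.05, 0.12,  # G
    0.82, 0.04, 0.85, 0.04, 0.15, 0.25   # T
  ), nrow = 4L, byrow = TRUE, dimnames = list(NUCLEOTIDES, 1:6))
  validate_ppm(m)
}

#' Background (positionally uninformative) probability matrix
#'
#' Every column equals the genome background (A/T 0.6, G/C 0.4 by default):
#' the null fixture for calibration checks.
#'
#' @inheritParams background_freqs
#' @param site_length Number of columns (default 6).
#' @return 4 x `site_length` column-stochastic matrix.
#' @export
background_ppm <- function(site_length = 6, at = 0.6, gc = 0.4) {
  bg <- background_freqs(at, gc)
  matrix(rep(bg, site_length), nrow = 4L,
         dimnames = list(NUCLEOTIDES, seq_len(site_length)))
}

#' Benchmark matrix with the discriminative signal at positions 2 and 5
#'
#' A 4 x 6 synthetic fixture for parameter-recovery benchmarks of the
#' cross-validation pipeline: positions 2 (A) and 5 (G) carry most of the
#' information against the A/T-rich background, the flanks are mildly
#' informative, and the consensus letters at 2 and 5 are the ones the
#' pairwise coupling forces, so coupling strengthens rather than dilutes
#' the marginal signal. Used to test that models considering positions 2
#' and 5 outrank models ignoring both when the data really concentrate the
#' signal there.
#'
#' @return 4 x 6 column-stochastic matrix.
#' @export
coupled_benchmark_ppm <- function() {
  m <- matrix(c(
    # pos1  pos2  pos3  pos4  pos5  pos6
    0.25, 0.60, 0.50, 0.20, 0.10, 0.15,  # A
    0.15, 0.20, 0.15, 0.15, 0.10, 0.25,  # C
    0.15, 0.10, 0.15, 0.35, 0.60, 0.15,  # G
    0.45, 0.10, 0.20, 0.30, 0.20, 0.45   # T
  ), nrow = 4L, byrow = TRUE, dimnames = list(NUCLEOTIDES, 1:6))
  validate_ppm(m)
}

#' Sample aligned sites from a position probability matrix
#'
#' Positions are independent; letter frequencies converge to the ppm
#' columns. Deterministic given the RNG state.
#'
#' @param ppm 4 x L column-stochastic matrix.
#' @param n Number of sites.
#' @return Character vector of `n` sites of length `ncol(ppm)`.
#' @examples
#' set.seed(1)
#' sample_sites(inr_ppm(), 3)
#' @export
sample_sites <- function(ppm, n) {
  ppm <- validate_ppm(ppm)
  if (n < 1) abort("`n` must be >= 1")
  codes <- vapply(seq_len(ncol(ppm)), function(p) {
    sample.int(4L, n, replace = TRUE, prob = ppm[, p])
  }, integer(n))
  if (n == 1L) codes <- matrix(codes, nrow = 1L)
  codes_to_seq(codes)
}

#' Sample sites with a planted pairwise coupling
#'
#' Mixture forcing: with probability `coupling` a site has the two coupled
#' positions overwritten with the given nucleotides; otherwise all positions
#' are drawn independently from the ppm. The expected joint count of the
#' coupled pair is `n * (coupling + (1 - coupling) * p_i(a) * p_j(b))`.
#' With `coupling = 0` the output is identical to [sample_sites()] at the
#' same RNG state.
#'
#' @inheritParams sample_sites
#' @param positions Length-2 integer vector `(i, j)`, `i < j`.
#' @param nucleotides Length-2 character vector `(a, b)` forced at the
#'   coupled positions.
#' @param coupling Coupling strength in `[0, 1]`.
#' @return Character vector of `n` sites.
#' @examples
#' set.seed(1)
#' sample_sites_coupled(inr_ppm(), 5, c(2, 5), c("A", "G"), coupling = 1)
#' @export
sample_sites_coupled <- function(ppm, n, positions = c(2, 5),
                                 nucleotides = c("A", "G"), coupling = 0.3) {
  ppm <- validate_ppm(ppm)
  if (length(positions) != 2L || positions[1] >= positions[2]) {
    abort("`positions` must be two increasing positions (i < j)")
  }
  if (coupling < 0 || coupling > 1) abort("`coupling` must be in [0, 1]")
  nt <- match(toupper(nucleotides), NUCLEOTIDES)
  if (anyNA(nt) || length(nt) != 2L) abort("`nucleotides` must be two of A/C/G/T")
  sites <- sample_sites(ppm, n)
  force_it <- runif(n) < coupling
  if (any(force_it)) {
    substr(sites[force_it], positions[1], positions[1]) <- NUCLEOTIDES[nt[1]]
    substr(sites[force_it], positions[2], positions[2]) <- NUCLEOTIDES[nt[2]]
  }
  sites
}

#' Sample promoters with a planted site on a biased background
#'
#' Each promoter is an i.i.d. background sequence with a planted 6-mer
#' written at a known offset; the truth interval is recorded per record.
#' The default geometry emulates 100 bp windows spanning -49..+50 around
#' the transcription start site, with the planted site at 1-based positions
#' 48-53 so that site position 3 sits on the +1 TSS.
#'
#' @param n Number of promoters.
#' @param length Promoter length (default 100).
#' @param background Background probabilities for the non-planted sequence.
#' @param site What to plant: a 4 x w ppm (each record gets its own draw),
#'   a fixed string, one string per promoter, or `NULL` for no planting
#'   (then no truth columns).
#' @param offset 0-based planting offset, or a vector of offsets sampled
#'   uniformly per record (default 47, i.e. 1-based 48-53 for a 6-mer).
#' @return Tibble with columns `id`, `sequence` and (when planted)
#'   `truth_start`, `truth_end` (0-based half-open).
#' @examples
#' set.seed(1)
#' sample_promoters(2, site = "TCAGTT")
#' @export
sample_promoters <- function(n, length = 100,
                             background = background_freqs(),
                             site = NULL, offset = 47) {
  if (n < 1) abort("`n` must be >= 1")
  background <- validate_background(background)
  codes <- matrix(sample.int(4L, n * length, replace = TRUE, prob = background),
                  nrow = n, ncol = length)
  seqs <- codes_to_seq(codes)
  out <- tibble(id = sprintf("prom_%03d", seq_len(n)), sequence = seqs)
  if (is.null(site)) return(out)
  planted <- if (is.matrix(site)) {
    sample_sites(validate_ppm(site), n)
  } else if (base::length(site) == 1L) {
    rep(toupper(site), n)
  } else if (base::length(site) == n) {
    toupper(site)
  } else {
    abort("`site` must be a ppm, a single string, or one string per promoter")
  }
  width <- nchar(planted[1L])
  if (any(offset < 0) || any(offset > length - width)) {
    abort(sprintf("`offset` must be in [0, %d]", length - width))
  }
  offsets <- if (base::length(offset) == 1L) rep(as.integer(offset), n)
             else sample(as.integer(offset), n, replace = TRUE)
  substr(out$sequence, offsets + 1L, offsets + width) <- planted
  out$truth_start <- offsets
  out$truth_end <- offsets + width
  out
}
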