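# Monte Carlo test of pairwise positional nucleotide interdependency.
#
# The null model draws sites with independent positions from a 4 x L
# position probability matrix; for each (position pair, nucleotide pair)
# hypothesis the observed joint count in the alignment is compared with its
# distribution over many simulated null sets of the same size. Monte Carlo
# p-values use the add-one convention so they are never exactly zero.

#' Position probability matrix of an alignment (no pseudocount)
#'
#' Frequency of each nucleotide at each position, divided by the number of
#' sites. Unlike [build_count_matrix()] no pseudocount is added: this is the
#' empirical matrix that parameterizes the independence null model.
#'
#' @inheritParams build_count_matrix
#' @return 4 x L column-stochastic matrix.
#' @examples
#' position_probability_matrix(c("TCAGTT", "TCAGTC"))
#' @export
position_probability_matrix <- function(sites) {
  sites <- validate_sites(sites)
  prob <- to_probability(build_count_matrix(sites, pseudocount = 0))
  attr(prob, "pseudocount") <- NULL
  prob
}

validate_ppm <- function(ppm) {
  stopifnot(is.matrix(ppm), nrow(ppm) == 4L)
  if (any(ppm < 0)) abort("`ppm` entries must be >= 0")
  if (any(abs(colSums(ppm) - 1) > 1e-9)) abort("`ppm` columns must sum to 1")
  rownames(ppm) <- NUCLEOTIDES
  ppm
}

#' Enumerate all pairwise interdependency hypotheses
#'
#' All unordered position pairs crossed with all 16 ordered nucleotide
#' pairs: `C(site_length, 2) * 16` hypotheses (240 for 6 bp sites).
#'
#' @param site_length Site length (>= 2; default 6).
#' @return Tibble with columns `pos_i`, `pos_j` (1-based, `pos_i < pos_j`),
#'   `nt_i`, `nt_j`.
#' @examples
#' nrow(enumerate_pair_hypotheses(6))
#' @export
enumerate_pair_hypotheses <- function(site_length = 6) {
  if (site_length < 2) abort("`site_length` must be >= 2")
  pairs <- utils::combn(site_length, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    tidyr::expand_grid(pos_i = pairs[1, k], pos_j = pairs[2, k],
                       nt_i = NUCLEOTIDES, nt_j = NUCLEOTIDES)
  })
  list_rbind(out)
}

# Joint (a at i, b at j) counts of an alignment for every hypothesis, in
# enumerate_pair_hypotheses() row order.
observed_pair_counts <- function(codes, site_length) {
  pairs <- utils::combn(site_length, 2)
  unlist(lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tabulate(4L * (codes[, i] - 1L) + codes[, j], nbins = 16L)
  }))
}

#' Simulate null joint counts under positional independence
#'
#' Draws `n_sets` sets of `set_size` sites with independent positions from
#' the ppm and records, for every (position pair, nucleotide pair)
#' hypothesis, the count of sites carrying that pair in each set. Work is
#' chunked over sets to bound memory.
#'
#' @param ppm 4 x L position probability matrix.
#' @param n_sets Number of null sets.
#' @param set_size Sites per set (the alignment size being tested).
#' @param chunk_size Sets simulated per chunk (default 2000).
#' @return Integer matrix, one row per hypothesis (in
#'   [enumerate_pair_hypotheses()] order), one column per null set; the
#'   hypothesis table is attached as attribute `hypotheses`.
#' @export
simulate_null_counts <- function(ppm, n_sets, set_size, chunk_size = 2000) {
  ppm <- validate_ppm(ppm)
  if (n_sets < 1 || set_size < 1) abort("`n_sets` and `set_size` must be >= 1")
  site_length <- ncol(ppm)
  pairs <- utils::combn(site_length, 2)
  n_hyp <- ncol(pairs) * 16L
  out <- matrix(0L, nrow = n_hyp, ncol = n_sets)
  done <- 0L
  while (done < n_sets) {
    m <- min(chunk_size, n_sets - done)
    letters <- lapply(seq_len(site_length), function(p) {
      matrix(sample.int(4L, set_size * m, replace = TRUE, prob = ppm[, p]),
             nrow = set_size, ncol = m)
    })
    set_offset <- 16L * rep(0:(m - 1L), each = set_size)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      code <- 4L * (letters[[i]] - 1L) + letters[[j]]
      tab <- tabulate(code + set_offset, nbins = 16L * m)
      out[((k - 1L) * 16L + 1L):(k * 16L), (done + 1L):(done + m)] <-
        matrix(tab, nrow = 16L, ncol = m)
    }
    done <- done + m
  }
  attr(out, "hypotheses") <- enumerate_pair_hypotheses(site_length)
  out
}

#' Monte Carlo test of pairwise nucleotide interdependency
#'
#' Tests, for every (position pair, nucleotide pair) hypothesis, whether the
#' joint count observed in the alignment is compatible with positional
#' independence. The null ppm defaults to the alignment's own
#' [position_probability_matrix()] (the plug-in procedure); a known
#' generating ppm may be supplied instead. Monte Carlo p-values use the
#' add-one convention `(1 + #{null >= observed}) / (n_sets + 1)` (upper
#' tail; lower analogous), and the two-tailed p-value is the doubled
#' smaller tail, capped at 1.
#'
#' @inheritParams build_count_matrix
#' @param n_sets Number of null sets (default 100000).
#' @param ppm Optional 4 x L null probability matrix; default estimated
#'   from `sites`.
#' @param alpha Significance levels flagged per hypothesis.
#' @param chunk_size Sets simulated per chunk.
#' @return Tibble of class `interdep_test`, one row per hypothesis:
#'   `pos_i`, `pos_j`, `nt_i`, `nt_j`, `observed`, `expected`
#'   (`n_sites * p_i(a) * p_j(b)`), `p_upper`, `p_lower`, `p_two_tailed`,
#'   and logical significance flags `sig_<alpha>` on the two-tailed
#'   p-value.
#' @export
pair_dependence_test <- function(sites, n_sets = 100000, ppm = NULL,
                                 alpha = c(0.05, 0.01, 0.001),
                                 chunk_size = 2000) {
  sites <- validate_sites(sites)
  if (n_sets < 1000) {
    warn("fewer than 1000 null sets: small significance levels are unresolvable")
  }
  codes <- seq_to_codes(sites, "site")
  site_length <- ncol(codes)
  n_sites <- nrow(codes)
  ppm <- validate_ppm(ppm %||% position_probability_matrix(sites))
  if (ncol(ppm) != site_length) abort("`ppm` width does not match the sites")
  hyp <- enumerate_pair_hypotheses(site_length)
  observed <- observed_pair_counts(codes, site_length)
  nt_idx_i <- match(hyp$nt_i, NUCLEOTIDES)
  nt_idx_j <- match(hyp$nt_j, NUCLEOTIDES)
  expected <- n_sites * ppm[cbind(nt_idx_i, hyp$pos_i)] *
    ppm[cbind(nt_idx_j, hyp$pos_j)]
  nullc <- simulate_null_counts(ppm, n_sets, n_sites, chunk_size)
  p_upper <- (1 + rowSums(nullc >= observed)) / (n_sets + 1)
  p_lower <- (1 + rowSums(nullc <= observed)) / (n_sets + 1)
  p_two <- pmin(1, 2 * pmin(p_upper, p_lower))
  out <- hyp |>
    mutate(observed = observed, expected = expected,
           p_upper = p_upper, p_lower = p_lower, p_two_tailed = p_two)
  for (a in alpha) {
    out[[paste0("sig_", format(a, scientific = FALSE))]] <- p_two <= a
  }
  attr(out, "n_sets") <- n_sets
  attr(out, "n_sites") <- n_sites
  class(out) <- c("interdep_test", class(out))
  out
}
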