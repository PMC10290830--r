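# Internal sequence utilities shared across modules.

# Split equal-length sequences into an n x L integer matrix (A=1,C=2,G=3,T=4).
# Errors on ragged lengths or non-ACGT characters.
seq_to_codes <- function(x, what = "sequence") {
  if (length(x) == 0L) {
    abort(paste0("no ", what, "s supplied"))
  }
  lens <- nchar(x)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    abort(sprintf("%ss must all have equal length; %s %d has length %d (expected %d)",
                  what, what, bad, lens[bad], lens[1L]))
  }
  chars <- strsplit(x, "", fixed = TRUE)
  codes <- match(unlist(chars), NUCLEOTIDES)
  if (anyNA(codes)) {
    bad_seq <- ceiling(which(is.na(codes))[1L] / lens[1L])
    abort(sprintf("%s %d contains characters outside A/C/G/T", what, bad_seq))
  }
  matrix(codes, nrow = length(x), ncol = lens[1L], byrow = TRUE)
}

codes_to_seq <- function(codes) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  apply(codes, 1L, function(r) paste(NUCLEOTIDES[r], collapse = ""))
}

# Validate an alignment of fixed-length A/C/G/T sites; returns uppercase sites.
validate_sites <- function(sites) {
  if (!is.character(sites) || length(sites) == 0L) {
    abort("`sites` must be a non-empty character vector")
  }
  sites <- toupper(sites)
  invisible(seq_to_codes(sites, "site"))
  sites
}

# Per-nucleotide background probabilities, A/T and G/C split equally within
# each pair. Defaults reflect a 60/40 AT/GC genome.
#' Background nucleotide frequencies
#'
#' Builds a named probability vector over A, C, G, T with the A/T and G/C
#' mass split equally within each pair. The default 0.6/0.4 split reflects
#' the overall nucleotide composition of the *Drosophila* genome.
#'
#' @param at Total probability mass on A + T.
#' @param gc Total probability mass on G + C. `at + gc` must equal 1.
#' @return Named numeric vector `c(A, C, G, T)` summing to 1.
#' @examples
#' background_freqs()
#' background_freqs(at = 0.5, gc = 0.5)
#' @export
background_freqs <- function(at = 0.6, gc = 0.4) {
  if (abs(at + gc - 1) > 1e-9) abort("`at` and `gc` must sum to 1")
  if (at <= 0 || gc <= 0) abort("`at` and `gc` must be positive")
  c(A = at / 2, C = gc / 2, G = gc / 2, T = at / 2)
}

validate_background <- function(background) {
  if (!is.numeric(background) || length(background) != 4L) {
    abort("`background` must be a numeric vector of length 4 (A, C, G, T)")
  }
  if (!is.null(names(background))) {
    if (!setequal(names(background), NUCLEOTIDES)) {
      abort("`background` names must be A, C, G, T")
    }
    background <- background[NUCLEOTIDES]
  } else {
    names(background) <- NUCLEOTIDES
  }
  if (any(background <= 0)) abort("background probabilities must all be > 0")
  if (abs(sum(background) - 1) > 1e-9) abort("background probabilities must sum to 1")
  background
}
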