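# Gapped n-mer model catalogs.
#
# A model is a pattern over {m, k}: `m` marks a considered position, `k` an
# ignored one. Two catalogs are supported for 6 bp sites:
#   * "anchored32" — every pattern of length 1..6 that starts and ends with
#     `m` (32 models). Numbering is block-structured: models are grouped by
#     length (block starts 0, 1, 2, 4, 8, 16 for lengths 1..6) and ordered
#     within a block by the binary value of the interior symbols (m = 1).
#   * "full64" — all 2^6 length-6 patterns; the model id is the pattern read
#     as a binary number, m = 1, most significant symbol first (0..63).

CATALOGS <- c("anchored32", "full64")

match_catalog <- function(catalog) {
  if (!is.character(catalog) || length(catalog) != 1L || !catalog %in% CATALOGS) {
    abort(sprintf("unknown catalog; must be one of %s",
                  paste(dQuote(CATALOGS, q = '"'), collapse = ", ")))
  }
  catalog
}

validate_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) < 1L) {
    abort("`pattern` must be a single non-empty string over {m, k}")
  }
  pattern <- tolower(pattern)
  if (grepl("[^mk]", pattern)) abort("`pattern` may only contain 'm' and 'k'")
  pattern
}

pattern_bits <- function(pattern) {
  as.integer(strsplit(pattern, "", fixed = TRUE)[[1]] == "m")
}

bits_to_pattern <- function(bits) {
  paste(c("k", "m")[bits + 1L], collapse = "")
}

#' Number of considered positions in a gapped model
#'
#' @param pattern Model pattern string over `m` (considered) and `k`
#'   (ignored), e.g. `"mmkkmm"`.
#' @return Integer count of `m` symbols.
#' @examples
#' considered_count("mmkkmm")
#' @export
considered_count <- function(pattern) {
  sum(pattern_bits(validate_pattern(pattern)))
}

#' Enumerate a gapped n-mer model catalog
#'
#' Lists every model in a catalog together with its identifier. The anchored
#' catalog contains all patterns of length 1 to `site_length` whose first and
#' last symbols are considered (32 models at `site_length = 6`); the full
#' catalog contains all `2^site_length` fixed-length patterns numbered by
#' binary conversion (m = 1, leftmost symbol most significant).
#'
#' @param site_length Length of the aligned binding sites (default 6, the
#'   length the catalogs are calibrated for).
#' @param catalog `"anchored32"` or `"full64"`.
#' @return A tibble with columns `catalog`, `model_id`, `pattern`, `length`
#'   and `n_considered`, ordered by `model_id`.
#' @examples
#' enumerate_models(6, "anchored32")
#' enumerate_models(6, "full64")
#' @export
enumerate_models <- function(site_length = 6, catalog = c("anchored32", "full64")) {
  catalog <- match_catalog(match.arg(catalog))
  if (site_length < 1) abort("`site_length` must be >= 1")
  if (catalog == "anchored32") {
    patterns <- unlist(lapply(seq_len(site_length), function(len) {
      if (len == 1L) return("m")
      if (len == 2L) return("mm")
      interior <- expand_bits(len - 2L)
      vapply(seq_len(nrow(interior)), function(i) {
        bits_to_pattern(c(1L, interior[i, ], 1L))
      }, character(1))
    }))
  } else {
    bits <- expand_bits(site_length)
    patterns <- vapply(seq_len(nrow(bits)), function(i) bits_to_pattern(bits[i, ]),
                       character(1))
  }
  ids <- vapply(patterns, model_id, integer(1), catalog = catalog,
                USE.NAMES = FALSE)
  tibble(
    catalog = catalog,
    model_id = ids,
    pattern = patterns,
    length = nchar(patterns),
    n_considered = vapply(patterns, considered_count, integer(1),
                          USE.NAMES = FALSE)
  ) |>
    arrange(.data$model_id)
}

# All bit vectors of length `n` ordered by their binary value (MSB first).
expand_bits <- function(n) {
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  g <- do.call(expand.grid, rep(list(c(0L, 1L)), n))
  as.matrix(g[, rev(seq_len(n)), drop = FALSE])
}

#' Model identifier for a pattern
#'
#' @inheritParams considered_count
#' @param catalog `"anchored32"` or `"full64"`.
#' @return Integer model id under the catalog numbering.
#' @examples
#' model_id("mmmkmk", "full64")   # 58
#' model_id("mmkkmm", "anchored32")  # 25
#' @export
model_id <- function(pattern, catalog = c("anchored32", "full64")) {
  catalog <- match_catalog(match.arg(catalog))
  pattern <- validate_pattern(pattern)
  bits <- pattern_bits(pattern)
  len <- length(bits)
  if (catalog == "full64") {
    if (len != 6L) abort("full64 patterns must have length 6")
    return(bits_value(bits))
  }
  if (len > 6L) abort("anchored32 patterns must have length 1..6")
  if (bits[1L] != 1L || bits[len] != 1L) {
    abort("anchored32 patterns must start and end with a considered (m) position")
  }
  block_start <- if (len == 1L) 0L else as.integer(2^(len - 2L))
  offset <- if (len <= 2L) 0L else bits_value(bits[2:(len - 1L)])
  block_start + offset
}

bits_value <- function(bits) {
  as.integer(sum(bits * 2^(rev(seq_along(bits)) - 1L)))
}

#' Pattern for a model identifier
#'
#' Inverse of [model_id()] over a catalog.
#'
#' @param id Non-negative integer model id.
#' @inheritParams model_id
#' @return Pattern string.
#' @examples
#' pattern_from_id(58, "full64")   # "mmmkmk"
#' pattern_from_id(25, "anchored32")  # "mmkkmm"
#' @export
pattern_from_id <- function(id, catalog = c("anchored32", "full64")) {
  catalog <- match_catalog(match.arg(catalog))
  if (length(id) != 1L || is.na(id) || id != trunc(id)) {
    abort("`id` must be a single integer")
  }
  id <- as.integer(id)
  if (catalog == "full64") {
    if (id < 0L || id > 63L) abort("full64 model ids run from 0 to 63")
    return(bits_to_pattern(id_bits(id, 6L)))
  }
  if (id < 0L || id > 31L) abort("anchored32 model ids run from 0 to 31")
  if (id == 0L) return("m")
  if (id == 1L) return("mm")
  len <- 2L + floor(log2(id))
  block_start <- as.integer(2^(len - 2L))
  interior <- id_bits(id - block_start, len - 2L)
  bits_to_pattern(c(1L, interior, 1L))
}

id_bits <- function(id, n) {
  as.integer(rev((id %/% 2^(0:(n - 1L))) %% 2L))
}

#' Number of sliding frames of a model within a site
#'
#' A model shorter than the site slides across it; a length-1 model in a
#' 6 bp site has six frames, a length-6 model one.
#'
#' @inheritParams considered_count
#' @param site_length Site length the model slides within.
#' @return Integer `site_length - length(pattern) + 1`.
#' @examples
#' frame_count("m", 6)
#' @export
frame_count <- function(pattern, site_length = 6) {
  pattern <- validate_pattern(pattern)
  if (nchar(pattern) > site_length) abort("model is longer than the site")
  as.integer(site_length - nchar(pattern) + 1L)
}

#' Mask a site sequence to a model's considered positions
#'
#' Positions covered by a considered (`m`) symbol of the model frame keep
#' their nucleotide; ignored (`k`) positions and positions outside the frame
#' become `N`. This is the masking used to build model-specific sequence
#' logos (e.g. `TCAGTG` under `mmkkmm` becomes `TCNNTG`).
#'
#' @param site Fixed-length nucleotide string over A/C/G/T.
#' @inheritParams considered_count
#' @param frame_offset 0-based offset of the model frame within the site.
#' @return Masked string of the same length as `site`.
#' @examples
#' mask_site("TCAGTG", "mmkkmm")
#' mask_site("TCAGTG", "m", frame_offset = 2)
#' @export
mask_site <- function(site, pattern, frame_offset = 0) {
  pattern <- validate_pattern(pattern)
  site <- toupper(site)
  if (length(site) != 1L || !is.character(site)) abort("`site` must be a single string")
  seq_to_codes(site, "site")
  len_s <- nchar(site)
  len_m <- nchar(pattern)
  if (frame_offset < 0 || frame_offset > len_s - len_m) {
    abort(sprintf("`frame_offset` must be in [0, %d]", len_s - len_m))
  }
  chars <- strsplit(site, "", fixed = TRUE)[[1]]
  keep <- rep(FALSE, len_s)
  keep[frame_offset + which(pattern_bits(pattern) == 1L)] <- TRUE
  chars[!keep] <- "N"
  paste(chars, collapse = "")
}

#' Tally how often each site position is considered by a set of models
#'
#' For every model, each site position covered by a considered (`m`) symbol
#' contributes to the tally. In `"per_frame"` mode (default) a position gains
#' +1 for every sliding frame of every model that covers it with an `m`; in
#' `"per_model_union"` mode it gains +1 per model if covered in at least one
#' frame.
#'
#' @param patterns Character vector of model patterns.
#' @param site_length Site length (default 6).
#' @param mode `"per_frame"` or `"per_model_union"`.
#' @return A tibble with columns `position` (1-based) and `count`.
#' @examples
#' position_inclusion_tally(c("mmkm"), 6)
#' @export
position_inclusion_tally <- function(patterns, site_length = 6,
                                     mode = c("per_frame", "per_model_union")) {
  mode <- match.arg(mode)
  counts <- integer(site_length)
  for (pattern in patterns) {
    pattern <- validate_pattern(pattern)
    bits <- pattern_bits(pattern)
    if (length(bits) > site_length) abort("model is longer than the site")
    covered <- integer(site_length)
    for (off in 0:(site_length - length(bits))) {
      covered[off + which(bits == 1L)] <- covered[off + which(bits == 1L)] + 1L
    }
    if (mode == "per_model_union") covered <- as.integer(covered > 0L)
    counts <- counts + covered
  }
  tibble(position = seq_len(site_length), count = counts)
}

#' Label site positions relative to the transcription start site
#'
#' Initiator site positions 1..6 map to -2, -1, +1, +2, +3, +4 relative to
#' the TSS (there is no position 0).
#'
#' @param positions Integer vector of 1-based site positions.
#' @return Character vector of TSS-relative labels.
#' @examples
#' tss_labels(1:6)
#' @export
tss_labels <- function(positions) {
  offsets <- ifelse(positions <= 2, positions - 3L, positions - 2L)
  ifelse(offsets > 0, paste0("+", offsets), as.character(offsets))
}
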