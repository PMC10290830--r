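# Readers and writers for the formats the pipeline touches: one-sequence-
# per-line site lists, FASTA, BED truth intervals (0-based half-open), TSV
# matrix/catalog tables, MEME minimal motif format, and YAML run manifests.

#' Read aligned binding sites
#'
#' Reads an alignment from a one-sequence-per-line list or a FASTA file
#' (auto-detected from the first non-blank character). Sequences are
#' uppercased and validated (equal lengths, A/C/G/T only); duplicates are
#' preserved.
#'
#' @param path File path.
#' @param format `"auto"`, `"list"` or `"fasta"`.
#' @return Character vector of sites.
#' @export
read_sites <- function(path, format = c("auto", "list", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "list"
  }
  sites <- if (format == "fasta") {
    as.character(Biostrings::readDNAStringSet(path))
  } else {
    lines <- trimws(readLines(path))
    lines[nzchar(lines)]
  }
  sites <- toupper(unname(sites))
  lens <- nchar(sites)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    abort(sprintf("ragged site lengths in %s: entry %d has length %d (expected %d)",
                  path, bad, lens[bad], lens[1L]))
  }
  bad <- grep("[^ACGT]", sites)
  if (length(bad) > 0) {
    abort(sprintf("non-ACGT character in %s at entry %d", path, bad[1L]))
  }
  sites
}

#' Write aligned sites as a one-per-line list
#'
#' @param sites Character vector of sites.
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  writeLines(validate_sites(sites), path)
  invisible(path)
}

#' Read promoter records from FASTA (plus optional BED truth intervals)
#'
#' Truth intervals are 0-based half-open BED records whose first column
#' matches a FASTA record id. Without a truth file, records carry no truth
#' columns and evaluation functions refuse them with a clear error.
#'
#' @param fasta_path FASTA file of promoter sequences.
#' @param truth_path Optional BED file (id, start, end).
#' @param site_length Expected truth interval length for the width warning
#'   (default 6).
#' @return Tibble with columns `id`, `sequence` and, with truth, the
#'   0-based half-open `truth_start`, `truth_end`.
#' @export
read_promoters <- function(fasta_path, truth_path = NULL, site_length = 6) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- tibble(id = sub("\\s.*$", "", names(seqs)),
                sequence = toupper(as.character(unname(seqs))))
  if (is.null(truth_path)) return(out)
  bed <- utils::read.table(truth_path, sep = "\t", stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("id", "truth_start", "truth_end")
  missing_ids <- setdiff(bed$id, out$id)
  if (length(missing_ids) > 0) {
    abort(sprintf("truth id absent from FASTA: %s", missing_ids[1L]))
  }
  out <- left_join(out, as_tibble(bed), by = "id")
  bad <- !is.na(out$truth_start) &
    (out$truth_start < 0 | out$truth_end > nchar(out$sequence) |
       out$truth_start >= out$truth_end)
  if (any(bad)) abort(sprintf("truth interval out of bounds for id %s",
                              out$id[which(bad)[1L]]))
  widths <- out$truth_end - out$truth_start
  if (any(!is.na(widths) & widths != site_length)) {
    warn(sprintf("some truth intervals are not %d bases wide; the >=1-base overlap rule still applies",
                 site_length))
  }
  out
}

#' Write promoter records as FASTA (plus optional BED truth intervals)
#'
#' @param records Tibble with `id`, `sequence` and optionally `truth_start`,
#'   `truth_end`.
#' @param fasta_path Output FASTA path.
#' @param truth_path Optional output BED path.
#' @export
write_promoters <- function(records, fasta_path, truth_path = NULL) {
  stopifnot(is.data.frame(records))
  x <- Biostrings::DNAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(truth_path)) {
    if (!all(c("truth_start", "truth_end") %in% names(records))) {
      abort("`records` has no truth intervals to write")
    }
    readr::write_tsv(records[, c("id", "truth_start", "truth_end")],
                     truth_path, col_names = FALSE)
  }
  invisible(fasta_path)
}

#' Write a nucleotide matrix as TSV
#'
#' Rows A, C, G, T; 1-based position columns. Construction parameters that
#' travel as attributes (pseudocount, log base, model pattern) are recorded
#' as `#`-comment header lines.
#'
#' @param m 4 x L matrix.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == 4L)
  hdr <- character(0)
  for (a in c("pseudocount", "log_base", "pattern", "n_sites")) {
    if (!is.null(attr(m, a))) hdr <- c(hdr, sprintf("# %s: %s", a, attr(m, a)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("nt", seq_len(ncol(m))), collapse = "\t"), con)
  for (r in seq_len(4L)) {
    writeLines(paste(c(NUCLEOTIDES[r], format(m[r, ], digits = 10, trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a nucleotide matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path.
#' @return 4 x L numeric matrix (comment headers restored as attributes
#'   where numeric).
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(body[, -1, drop = FALSE])
  rownames(m) <- body[[1]]
  m <- m[NUCLEOTIDES, , drop = FALSE]
  for (h in hdr) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    attr(m, key) <- if (is.na(num)) val else num
  }
  m
}

#' Export a motif in MEME minimal format
#'
#' Writes the letter-probability matrix of a (possibly gapped) model:
#' considered columns carry the site probabilities, ignored columns the
#' background, so external scanners see the same zero-contribution gap
#' columns as the internal scanner. Pseudocount and model pattern are
#' recorded as comments.
#'
#' @param prob 4 x L probability matrix.
#' @param path Output path.
#' @param name Motif name.
#' @param pattern Optional gapped model pattern; default all-considered.
#' @param background Background probabilities (written to the file).
#' @param nsites Number of source sites recorded in the header.
#' @export
write_meme_motif <- function(prob, path, name = "motif",
                             pattern = NULL,
                             background = background_freqs(),
                             nsites = attr(prob, "n_sites") %||% 20) {
  stopifnot(is.matrix(prob), nrow(prob) == 4L)
  background <- validate_background(background)
  p <- prob
  if (!is.null(pattern)) {
    pattern <- validate_pattern(pattern)
    if (nchar(pattern) != ncol(prob)) abort("`pattern` must cover every column")
    p[, pattern_bits(pattern) == 0L] <- background
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4",
    "",
    "ALPHABET= ACGT",
    "",
    "strands: +",
    "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f",
            background["A"], background["C"], background["G"], background["T"]),
    "",
    if (!is.null(pattern)) sprintf("# gapped model pattern: %s", pattern),
    if (!is.null(attr(prob, "pseudocount")))
      sprintf("# pseudocount: %s", attr(prob, "pseudocount")),
    sprintf("MOTIF %s", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %s E= 0",
            ncol(p), format(nsites))
  ), con)
  for (j in seq_len(ncol(p))) {
    writeLines(sprintf(" %.6f %.6f %.6f %.6f", p["A", j], p["C", j],
                       p["G", j], p["T", j]), con)
  }
  invisible(path)
}

#' Write scanner hits as BED-like TSV
#'
#' Columns: id, start, end (0-based half-open), score, p_value.
#'
#' @param hits Tibble with `id`, `start`, `score`, `p_value`.
#' @param path Output path.
#' @param width Hit window width (default 6).
#' @export
write_hits <- function(hits, path, width = 6) {
  stopifnot(is.data.frame(hits))
  out <- tibble(id = hits$id, start = hits$start, end = hits$start + width,
                score = hits$score, p_value = hits$p_value)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write the RZ heatmap table
#'
#' Rows are models, columns threshold positions, values RZ scores
#' multiplied by one hundred and rounded to integers (0-100 scale).
#'
#' @param rz_table `rz_screen` tibble from [run_rz_screen()].
#' @param path Output path.
#' @export
write_rz_heatmap <- function(rz_table, path) {
  wide <- rz_table |>
    mutate(rz100 = round(100 * .data$rz)) |>
    select("model_id", "pattern", "threshold_position", "rz100") |>
    tidyr::pivot_wider(names_from = "threshold_position", values_from = "rz100",
                       names_prefix = "t")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records every parameter of a run (seed included) as YAML so the run is
#' re-executable from its manifest alone.
#'
#' @param config Named list of parameters.
#' @param path Output path.
#' @export
write_manifest <- function(config, path) {
  stopifnot(is.list(config))
  config$gapmotif_version <- as.character(utils::packageVersion("gapmotif"))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path Manifest path.
#' @return Named list.
#' @export
read_manifest <- function(path) {
  yaml::read_yaml(path)
}
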