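#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning plain
#' upper-case character strings keyed by the first whitespace-delimited
#' token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read aligned-read intervals from a BED file
#'
#' Reads BED3+ into the package's read-interval tibble (0-based half-open,
#' as in the file itself).
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `ref`, `start`, `end` and, when present in
#'   the file, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  cols <- c("ref", "start", "end", "name", "score", "strand")
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  names(x) <- cols[seq_len(min(ncol(x), 6L))]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  as_tibble(x)
}

#' Write read intervals to a BED6 file
#'
#' @param reads Tibble with columns `ref`, `start`, `end`; optional `name`,
#'   `score`, `strand` (defaulted to `"read"`, 0 and `"."`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(reads, path) {
  out <- tibble(
    ref = reads$ref,
    start = as.integer(reads$start),
    end = as.integer(reads$end),
    name = if ("name" %in% names(reads)) reads$name else "read",
    score = if ("score" %in% names(reads)) reads$score else 0L,
    strand = if ("strand" %in% names(reads)) reads$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal per-base value are collapsed into intervals; zero-valued
#' runs are kept so the file tiles each reference completely.
#'
#' @param track A `coverage_track` (see [compute_coverage()]).
#' @param path Output path.
#' @param drop_zero Drop zero-valued intervals? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, drop_zero = FALSE) {
  stopifnot(inherits(track, "coverage_track"))
  rows <- purrr::imap(track$values, function(v, ref) {
    r <- rle(v)
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    tibble(ref = ref, start = s, end = e, value = r$values)
  })
  out <- bind_rows(rows)
  if (drop_zero) out <- filter(out, .data$value != 0)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' @param path Path to a bedGraph produced by [write_bedgraph()] (or any
#'   bedGraph tiling each reference).
#' @param ref_lengths Named integer vector of reference lengths.
#' @param library Library name to record on the track.
#' @param mapped_reads Mapped-read count to record; `NA` when unknown.
#' @param scaled Whether the values are library-size scaled.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, ref_lengths, library = "library",
                          mapped_reads = NA_real_, scaled = FALSE) {
  x <- readr::read_tsv(path, col_names = c("ref", "start", "end", "value"),
                       show_col_types = FALSE, progress = FALSE)
  values <- lapply(setNames(names(ref_lengths), names(ref_lengths)),
                   function(ref) {
    v <- numeric(ref_lengths[[ref]])
    rows <- x[x$ref == ref, ]
    for (i in seq_len(nrow(rows))) {
      v[(rows$start[i] + 1L):rows$end[i]] <- rows$value[i]
    }
    v
  })
  new_coverage_track(values, library = library,
                     mapped_reads = mapped_reads, scaled = scaled)
}
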