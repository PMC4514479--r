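#' Coverage tracks
#'
#' A `coverage_track` stores one non-negative per-base value vector per
#' reference sequence, plus the library name, its mapped-read count and
#' whether the values have been library-size scaled.
#'
#' @param values Named list of numeric vectors, one per reference.
#' @param library Library name (e.g. `"odd"`, `"even"`, `"lacz"`).
#' @param mapped_reads Number of mapped reads in the library.
#' @param scaled Logical; `TRUE` after [scale_track()].
#' @param scale_per Scaling constant (reads-per-`scale_per` units); recorded
#'   once the track is scaled.
#' @return A `coverage_track` object.
#' @keywords internal
new_coverage_track <- function(values, library, mapped_reads, scaled = FALSE,
                               scale_per = NA_real_) {
  structure(
    list(values = values, library = library,
         mapped_reads = mapped_reads, scaled = scaled, scale_per = scale_per),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> library=%s  refs=%d  mapped_reads=%s  %s\n",
    x$library, length(x$values), format(x$mapped_reads),
    if (x$scaled) sprintf("scaled (per %g reads)", x$scale_per) else "raw"
  ))
  invisible(x)
}

#' Compute per-base read coverage
#'
#' Counts, at every reference position, the number of read intervals that
#' contain it. Intervals are 0-based half-open (BED convention); position
#' `p` of the returned vector (1-based in R) corresponds to reference
#' coordinate `p - 1`.
#'
#' @param reads Tibble of read intervals with columns `ref`, `start`, `end`
#'   (0-based half-open). An empty tibble yields all-zero coverage.
#' @param ref_lengths Named integer vector: reference sequence lengths.
#' @param library Library name stored on the track.
#' @return A raw `coverage_track`; `mapped_reads` equals `nrow(reads)`.
#' @export
#' @examples
#' reads <- tibble::tibble(ref = "tx1", start = c(0, 3), end = c(5, 8))
#' cov <- compute_coverage(reads, c(tx1 = 10))
#' cov$values$tx1
compute_coverage <- function(reads, ref_lengths, library = "library") {
  stopifnot(is.numeric(ref_lengths), !is.null(names(ref_lengths)))
  if (nrow(reads) > 0) {
    bad_ref <- setdiff(unique(reads$ref), names(ref_lengths))
    if (length(bad_ref) > 0) {
      abort(sprintf("reads map to unknown reference(s): %s",
                    paste(bad_ref, collapse = ", ")))
    }
    len <- ref_lengths[reads$ref]
    bad <- which(reads$start < 0 | reads$end > len | reads$start >= reads$end)
    if (length(bad) > 0) {
      i <- bad[1]
      abort(sprintf(
        "read interval outside reference bounds: %s:[%d,%d) (reference length %d)",
        reads$ref[i], reads$start[i], reads$end[i], len[i]))
    }
  }
  values <- lapply(setNames(names(ref_lengths), names(ref_lengths)),
                   function(ref) {
    L <- ref_lengths[[ref]]
    v <- numeric(L)
    r <- reads[reads$ref == ref, , drop = FALSE]
    if (nrow(r) > 0) {
      ## difference-array trick: +1 at start, -1 past end, then cumsum
      d <- numeric(L + 1L)
      ts <- tabulate(r$start + 1L, nbins = L)
      te <- tabulate(r$end + 1L, nbins = L + 1L)
      d[seq_len(L)] <- ts
      d <- d - te
      v <- cumsum(d[seq_len(L)])
    }
    v
  })
  new_coverage_track(values, library = library, mapped_reads = nrow(reads))
}

#' Scale a coverage track by library size
#'
#' Divides every per-base value by the mapped-read count and multiplies by a
#' scaling constant (default one million: counts per million mapped reads).
#' The constant cancels in the downstream EScore ratio, so it only sets the
#' working units.
#'
#' @param track A raw `coverage_track` with `mapped_reads > 0`.
#' @param per Scaling constant; default `1e6` (CPM).
#' @return A scaled `coverage_track`.
#' @export
scale_track <- function(track, per = 1e6) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$scaled) abort("track is already scaled")
  if (is.na(track$mapped_reads) || track$mapped_reads <= 0) {
    abort("cannot scale an empty library (mapped_reads = 0)")
  }
  f <- per / track$mapped_reads
  new_coverage_track(lapply(track$values, `*`, f),
                     library = track$library,
                     mapped_reads = track$mapped_reads,
                     scaled = TRUE, scale_per = per)
}

#' @rdname coverage_track-tidiers
#' @export
tidy.coverage_track <- function(x, ...) {
  bind_rows(purrr::imap(x$values, function(v, ref) {
    tibble(ref = ref, pos = seq_along(v) - 1L, value = v)
  }))
}

#' Tidiers for coverage tracks
#'
#' `tidy()` returns one row per reference position (`ref`, `pos`, `value`);
#' `glance()` returns a one-row summary of the track.
#'
#' @param x A `coverage_track`.
#' @param ... Unused.
#' @return A tibble.
#' @name coverage_track-tidiers
#' @export
glance.coverage_track <- function(x, ...) {
  tibble(
    library = x$library,
    n_refs = length(x$values),
    total_length = sum(lengths(x$values)),
    mapped_reads = x$mapped_reads,
    scaled = x$scaled,
    total_value = sum(vapply(x$values, sum, numeric(1)))
  )
}
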