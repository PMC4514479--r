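#' Peak-calling configuration
#'
#' Bundles the tunable parameters of the EScore peak caller.
#'
#' @param log2_threshold Minimum mean log2 EScore for a region to be called
#'   a peak. Default 2 (a 4-fold minimum enrichment over control).
#' @param pseudocount Added to the control (LacZ) scaled coverage in the
#'   EScore denominator, in scaled-coverage units (default 1 CPM). Guards
#'   against division by zero where the control has no reads.
#' @param merge_gap Maximum gap (nt) between defined positions merged into
#'   one region. Default 0: only adjacent positions merge.
#' @param top_k Maximum number of peaks retained for motif discovery
#'   (default 500).
#' @param flank Flank (nt) added on each side of the centre of a short peak
#'   when extracting sequences (default 50).
#' @param min_input_length Minimum extracted sequence length (nt, default
#'   100); peaks shorter than this are widened about their centre.
#' @param mean_scale Scale on which member EScores are averaged into the
#'   region score: `"log2"` (default) or `"linear"` (arithmetic mean of
#'   linear EScores, then log2).
#' @param reported_mean_log2,reported_sd_log2 Reported dataset-level mean
#'   and standard deviation of log2 EScore (defaults 0.285 and 0.410), kept
#'   for the [threshold_zscore()] consistency diagnostic only — they never
#'   enter peak calling.
#' @return A `peak_call_config` list.
#' @export
peak_call_config <- function(log2_threshold = 2,
                             pseudocount = 1,
                             merge_gap = 0L,
                             top_k = 500L,
                             flank = 50L,
                             min_input_length = 100L,
                             mean_scale = c("log2", "linear"),
                             reported_mean_log2 = 0.285,
                             reported_sd_log2 = 0.410) {
  mean_scale <- match.arg(mean_scale)
  stopifnot(log2_threshold > 0, pseudocount >= 0, merge_gap >= 0,
            top_k > 0, flank > 0, min_input_length > 0)
  structure(
    list(log2_threshold = log2_threshold, pseudocount = pseudocount,
         merge_gap = as.integer(merge_gap), top_k = as.integer(top_k),
         flank = as.integer(flank),
         min_input_length = as.integer(min_input_length),
         mean_scale = mean_scale,
         reported_mean_log2 = reported_mean_log2,
         reported_sd_log2 = reported_sd_log2),
    class = "peak_call_config"
  )
}

#' Per-position enrichment score track
#'
#' Computes the EScore at every reference position from the three scaled
#' coverage tracks: the minimum of the two pulldown pool coverages divided
#' by the control coverage plus a pseudocount,
#' \deqn{EScore(p) = \min(odd_p, even_p) / (lacz_p + c).}
#' Taking the minimum across two independent probe pools suppresses
#' probe-specific artifacts: a position enriched in only one pool scores as
#' its (low) other-pool coverage. Positions where either pulldown coverage
#' is zero are undefined and carry no value. The track stores
#' `log2(EScore)`.
#'
#' @param odd,even,lacz Scaled `coverage_track`s on the same references.
#' @param config A [peak_call_config()].
#' @return An `escore_track`: named list of per-reference numeric vectors
#'   of log2 EScores with `NA` at undefined positions, plus the
#'   pseudocount used.
#' @export
escore_track <- function(odd, even, lacz, config = peak_call_config()) {
  for (tr in list(odd, even, lacz)) {
    stopifnot(inherits(tr, "coverage_track"))
    if (!tr$scaled) abort(sprintf("track '%s' is not scaled", tr$library))
  }
  if (!identical(lengths(odd$values), lengths(even$values)) ||
      !identical(lengths(odd$values), lengths(lacz$values))) {
    abort("coverage tracks have mismatched reference lengths")
  }
  pc <- config$pseudocount
  values <- purrr::pmap(list(odd$values, even$values, lacz$values),
                        function(o, e, l) {
    m <- pmin(o, e)
    out <- rep(NA_real_, length(m))
    def <- m > 0
    out[def] <- log2(m[def] / (l[def] + pc))
    out
  })
  structure(list(values = values, pseudocount = pc),
            class = "escore_track")
}

#' @export
print.escore_track <- function(x, ...) {
  nd <- sum(vapply(x$values, function(v) sum(!is.na(v)), numeric(1)))
  cat(sprintf("<escore_track> refs=%d  defined_positions=%d  pseudocount=%g\n",
              length(x$values), nd, x$pseudocount))
  invisible(x)
}

#' @rdname coverage_track-tidiers
#' @export
tidy.escore_track <- function(x, ...) {
  bind_rows(purrr::imap(x$values, function(v, ref) {
    tibble(ref = ref, pos = seq_along(v) - 1L, log2_escore = v)
  }))
}

#' Merge adjacent scored positions into regions
#'
#' Maximal runs of defined EScore positions (gaps up to `merge_gap`
#' allowed) become one region carrying the mean of its members' log2
#' EScores (or, with `mean_scale = "linear"`, the log2 of the mean linear
#' EScore).
#'
#' @param track An `escore_track`.
#' @param config A [peak_call_config()].
#' @return Tibble of regions sorted by coordinate: `ref`, `start`, `end`
#'   (0-based half-open), `mean_log2_escore`, `n_positions`.
#' @export
merge_regions <- function(track, config = peak_call_config()) {
  stopifnot(inherits(track, "escore_track"))
  gap <- config$merge_gap
  rows <- purrr::imap(track$values, function(v, ref) {
    pos <- which(!is.na(v))          # 1-based
    if (length(pos) == 0) return(NULL)
    grp <- cumsum(c(1L, as.integer(diff(pos) > gap + 1L)))
    starts <- tapply(pos, grp, min) - 1L   # back to 0-based
    ends <- tapply(pos, grp, max)          # half-open end
    means <- vapply(split(v[pos], grp), function(s) {
      if (config$mean_scale == "linear") log2(mean(2^s)) else mean(s)
    }, numeric(1))
    np <- as.integer(tapply(pos, grp, length))
    tibble(ref = ref, start = as.integer(starts), end = as.integer(ends),
           mean_log2_escore = unname(means), n_positions = np)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(ref = character(), start = integer(), end = integer(),
                  mean_log2_escore = numeric(), n_positions = integer()))
  }
  arrange(out, .data$ref, .data$start)
}

#' Call peaks from merged EScore regions
#'
#' Retains regions whose mean log2 EScore meets the threshold, sorted by
#' decreasing score (ties broken by reference id then start), keeping at
#' most `top_k`.
#'
#' @param regions Tibble from [merge_regions()].
#' @param config A [peak_call_config()].
#' @return The peak tibble with a `rank` column (1 = best).
#' @export
call_peaks <- function(regions, config = peak_call_config()) {
  peaks <- regions |>
    filter(.data$mean_log2_escore >= config$log2_threshold) |>
    arrange(desc(.data$mean_log2_escore), .data$ref, .data$start) |>
    slice_head(n = config$top_k)
  mutate(peaks, rank = dplyr::row_number())
}

#' Z-score of the peak threshold against track-level statistics
#'
#' Expresses the log2 EScore peak threshold as a number of standard
#' deviations above the mean of the log2 EScore distribution. With the
#' default reported statistics (mean 0.285, sd 0.410) the default
#' threshold of 2 sits more than 4 standard deviations above the mean.
#' Pass an `escore_track` to compute the same diagnostic from observed
#' data.
#'
#' @param config A [peak_call_config()].
#' @param track Optional `escore_track`; when given, its own mean and sd of
#'   defined log2 EScores are used instead of the reported constants.
#' @return A one-row tibble: `threshold`, `mean_log2`, `sd_log2`, `z`.
#' @export
#' @examples
#' threshold_zscore()  # (2 - 0.285) / 0.410 = 4.18
threshold_zscore <- function(config = peak_call_config(), track = NULL) {
  if (is.null(track)) {
    m <- config$reported_mean_log2
    s <- config$reported_sd_log2
  } else {
    v <- unlist(track$values, use.names = FALSE)
    v <- v[!is.na(v)]
    m <- mean(v)
    s <- stats::sd(v)
  }
  if (is.na(s) || s <= 0) abort("standard deviation must be positive")
  tibble(threshold = config$log2_threshold, mean_log2 = m, sd_log2 = s,
         z = (config$log2_threshold - m) / s)
}

#' Extract peak sequences for motif discovery
#'
#' Returns the sequence under each peak. Peaks shorter than
#' `min_input_length` are replaced by a window of `flank` nt on each side
#' of the peak centre (so short peaks are not limited by narrow
#' boundaries), clipped at reference ends with a warning.
#'
#' @param peaks Peak tibble from [call_peaks()].
#' @param reference Named character vector of reference sequences (or path
#'   to a FASTA file).
#' @return Named character vector of sequences; names are
#'   `"peak<rank>|<ref>:<start>-<end>"` with the coordinates of the
#'   extracted window.
#' @export
extract_peak_sequences <- function(peaks, reference,
                                   config = peak_call_config()) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference) && is.null(names(reference))) {
    reference <- read_fasta(reference)
  }
  bad <- setdiff(unique(peaks$ref), names(reference))
  if (length(bad) > 0) {
    abort(sprintf("peak(s) on unknown reference id(s): %s",
                  paste(bad, collapse = ", ")))
  }
  ranks <- if ("rank" %in% names(peaks)) peaks$rank else seq_len(nrow(peaks))
  out <- character(nrow(peaks))
  nms <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    L <- nchar(reference[[peaks$ref[i]]])
    s <- peaks$start[i]
    e <- peaks$end[i]
    if (e - s < config$min_input_length) {
      centre <- (s + e) %/% 2L
      s <- centre - config$flank
      e <- centre + config$flank
    }
    if (s < 0 || e > L) {
      s2 <- max(s, 0L)
      e2 <- min(e, L)
      warn(sprintf(
        "peak window %s:[%d,%d) clipped to [%d,%d) at reference ends",
        peaks$ref[i], s, e, s2, e2))
      s <- s2
      e <- e2
    }
    out[i] <- substr(reference[[peaks$ref[i]]], s + 1L, e)
    nms[i] <- sprintf("peak%d|%s:%d-%d", ranks[i], peaks$ref[i], s, e)
  }
  setNames(out, nms)
}

#' @rdname coverage_track-tidiers
#' @export
#' @param x A track object.
#' @param ... Unused.
glance.escore_track <- function(x, ...) {
  v <- unlist(x$values, use.names = FALSE)
  v <- v[!is.na(v)]
  tibble(n_refs = length(x$values), n_defined = length(v),
         mean_log2 = mean(v), sd_log2 = stats::sd(v),
         pseudocount = x$pseudocount)
}
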