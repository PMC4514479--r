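#' Run the EScore peak-calling pipeline
#'
#' Convenience wrapper chaining the per-library steps: per-base coverage,
#' library-size scaling, the EScore track (min of the pulldown pools over
#' the LacZ control), region merging, peak calling and peak-sequence
#' extraction.
#'
#' @param reference Named character vector of reference sequences.
#' @param odd,even,lacz Read tibbles (`ref`, `start`, `end`) for the two
#'   pulldown pools and the control library.
#' @param config A [peak_call_config()].
#' @param scale_per Scaling constant passed to [scale_track()]. The default
#'   (`NULL`) scales to the control library size, so one control read has
#'   scaled weight 1 and the default pseudocount of 1 in the EScore
#'   denominator corresponds to a single control read regardless of
#'   sequencing depth. Pass `1e6` for plain CPM units.
#' @return List with `track` (the `escore_track`), `regions` (all merged
#'   regions), `peaks` (called peaks with ranks) and `sequences` (peak
#'   sequences for motif discovery).
#' @export
escore_pipeline <- function(reference, odd, even, lacz,
                            config = peak_call_config(), scale_per = NULL) {
  lens <- nchar(reference)
  scale_per <- scale_per %||% nrow(lacz)
  scaled <- purrr::imap(list(odd = odd, even = even, lacz = lacz),
                        function(reads, lib) {
    scale_track(compute_coverage(reads, lens, library = lib), per = scale_per)
  })
  track <- escore_track(scaled$odd, scaled$even, scaled$lacz, config)
  regions <- merge_regions(track, config)
  peaks <- call_peaks(regions, config)
  sequences <- if (nrow(peaks) > 0) {
    extract_peak_sequences(peaks, reference, config)
  } else character(0)
  list(track = track, regions = regions, peaks = peaks,
       sequences = sequences)
}
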