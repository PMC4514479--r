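make_track <- function(values, library, scaled = TRUE) {
  chirpmotif:::new_coverage_track(values, library = library,
                                  mapped_reads = 1, scaled = scaled,
                                  scale_per = 1)
}

test_that("escore is min of pulldown pools over control plus pseudocount", {
  odd <- make_track(list(r = c(8, 100, 0)), "odd")
  even <- make_track(list(r = c(6, 0, 4)), "even")
  lacz <- make_track(list(r = c(2, 0, 0)), "lacz")
  tr <- escore_track(odd, even, lacz, peak_call_config(pseudocount = 1))
  expect_equal(tr$values$r[1], log2(6 / 3))  # min(8,6)/(2+1) = 2 -> 1.0
  ## single-pool artifact: min with zero is undefined
  expect_true(is.na(tr$values$r[2]))
  ## odd zero likewise
  expect_true(is.na(tr$values$r[3]))
})

test_that("escore requires scaled tracks on matching references", {
  raw <- make_track(list(r = c(1, 2)), "odd", scaled = FALSE)
  sc <- make_track(list(r = c(1, 2)), "even")
  expect_error(escore_track(raw, sc, sc), "not scaled")
  other <- make_track(list(r = c(1, 2, 3)), "lacz")
  expect_error(escore_track(sc, sc, other), "mismatched")
})

test_that("escore is invariant to uniform scaling of any single library", {
  withr::with_seed(3, {
    o <- rpois(50, 5) + 1
    e <- rpois(50, 5) + 1
    l <- rpois(50, 2)
  })
  base <- function(mult) {
    reads_to_track <- function(v, lib, m) {
      ## build a raw track directly, then scale: multiplying every count
      ## and the library size by m must cancel
      tr <- chirpmotif:::new_coverage_track(list(r = v * m), lib,
                                            mapped_reads = sum(v) * m)
      scale_track(tr)
    }
    escore_track(reads_to_track(o, "odd", mult), reads_to_track(e, "even", 1),
                 reads_to_track(l, "lacz", 1))$values$r
  }
  expect_equal(base(1), base(7))
})

test_that("escore never decreases when both pulldown coverages increase", {
  lacz <- make_track(list(r = rep(2, 4)), "lacz")
  lo <- escore_track(make_track(list(r = rep(3, 4)), "odd"),
                     make_track(list(r = rep(4, 4)), "even"), lacz)
  hi <- escore_track(make_track(list(r = rep(6, 4)), "odd"),
                     make_track(list(r = rep(5, 4)), "even"), lacz)
  expect_true(all(hi$values$r >= lo$values$r))
})

test_that("region merging matches the brute-force run-length oracle", {
  ## tiny hand-checked example: defined positions {3,4,5, 9,10} (0-based), gap 0
  v <- rep(NA_real_, 12)
  v[c(4, 5, 6, 10, 11)] <- c(1, 2, 3, 4, 5)  # 1-based indices
  tr <- structure(list(values = list(r = v), pseudocount = 1),
                  class = "escore_track")
  reg <- merge_regions(tr)
  expect_equal(reg$start, c(3L, 9L))
  expect_equal(reg$end, c(6L, 11L))
  expect_equal(reg$mean_log2_escore, c(2, 4.5))
  expect_equal(reg$n_positions, c(3L, 2L))

  ## randomised oracle equivalence, including gap tolerance
  withr::with_seed(99, {
    for (rep in 1:8) {
      len <- sample(20:1000, 1)
      vv <- ifelse(stats::runif(len) < 0.4, stats::rnorm(len), NA_real_)
      gap <- sample(0:3, 1)
      trk <- structure(list(values = list(r = vv), pseudocount = 1),
                       class = "escore_track")
      got <- merge_regions(trk, peak_call_config(merge_gap = gap))
      want <- brute_merge(vv, gap)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$mean_log2_escore, want$mean)
    }
  })
})

test_that("a fully defined track merges to one region with the track mean", {
  v <- c(1, 2, 3, 4)
  tr <- structure(list(values = list(r = v), pseudocount = 1),
                  class = "escore_track")
  reg <- merge_regions(tr)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$mean_log2_escore, mean(v))
  ## empty track gives an empty region list
  tr0 <- structure(list(values = list(r = rep(NA_real_, 5)), pseudocount = 1),
                   class = "escore_track")
  expect_equal(nrow(merge_regions(tr0)), 0)
})

test_that("peak calling thresholds, sorts and truncates", {
  reg <- tibble::tibble(ref = c("a", "b", "c"), start = c(0L, 0L, 0L),
                        end = c(5L, 5L, 5L),
                        mean_log2_escore = c(2.5, 1.9, 3.1),
                        n_positions = c(5L, 5L, 5L))
  pk <- call_peaks(reg, peak_call_config(log2_threshold = 2))
  expect_equal(pk$mean_log2_escore, c(3.1, 2.5))
  expect_equal(pk$rank, 1:2)
  pk1 <- call_peaks(reg, peak_call_config(log2_threshold = 2, top_k = 1))
  expect_equal(nrow(pk1), 1)
  expect_equal(pk1$ref, "c")
  ## deterministic tie-break on (ref, start)
  reg2 <- tibble::tibble(ref = c("b", "a"), start = c(0L, 0L),
                         end = c(3L, 3L), mean_log2_escore = c(2.2, 2.2),
                         n_positions = c(3L, 3L))
  expect_equal(call_peaks(reg2)$ref, c("a", "b"))
})

test_that("threshold z-score reproduces the reported >4 sd separation", {
  z <- threshold_zscore()
  expect_equal(z$z, (2 - 0.285) / 0.410)
  expect_gt(z$z, 4)
  ## threshold at the mean gives z = 0; doubling the sd halves z
  z0 <- threshold_zscore(peak_call_config(log2_threshold = 0.285))
  expect_equal(z0$z, 0)
  z2 <- threshold_zscore(peak_call_config(reported_sd_log2 = 0.820))
  expect_equal(z2$z, z$z / 2)
  expect_error(threshold_zscore(peak_call_config(reported_sd_log2 = 0)),
               "positive")
})

test_that("peak sequences are widened to the minimum input length", {
  ref <- c(chr = rand_dna(1000))
  pk <- tibble::tibble(ref = "chr", start = 195L, end = 205L, rank = 1L)
  out <- extract_peak_sequences(pk, ref)
  expect_equal(nchar(out), 100L, ignore_attr = TRUE)
  expect_equal(out[[1]], substr(ref[[1]], 151, 250))  # [150, 250)
  ## long peaks pass through unmodified
  pk2 <- tibble::tibble(ref = "chr", start = 100L, end = 400L, rank = 1L)
  out2 <- extract_peak_sequences(pk2, ref)
  expect_equal(nchar(out2), 300L, ignore_attr = TRUE)
  ## clipping at the reference start warns and shortens
  pk3 <- tibble::tibble(ref = "chr", start = 5L, end = 15L, rank = 1L)
  expect_warning(out3 <- extract_peak_sequences(pk3, ref), "clipped")
  expect_equal(out3[[1]], substr(ref[[1]], 1, 60))  # [0, 60), length 60
  expect_error(extract_peak_sequences(
    tibble::tibble(ref = "zz", start = 0L, end = 5L, rank = 1L), ref),
    "unknown reference")
})
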