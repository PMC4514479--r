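test_that("config invariants are enforced", {
  expect_error(sim_config(n_bound = 10, n_transcripts = 5), "n_bound")
  expect_error(sim_config(bound_region_width = 2000,
                          transcript_length = 1000), "bound_region_width")
  expect_error(sim_config(enrichment_fold = 0.5), "enrichment_fold")
  expect_error(sim_config(motif_width = 3), "motif_width")
  expect_error(sim_config(motif_width = 50, bound_region_width = 40),
               "motif_width")
  expect_error(sim_config(gc_content = 1), "gc_content")
})

test_that("zero transcripts gives an empty reference and empty truth", {
  sim <- generate_reference(sim_config(n_transcripts = 0, n_bound = 0,
                                       n_artifact_spikes = 0))
  expect_length(sim$reference, 0)
  expect_equal(nrow(sim$truth$bound_regions), 0)
  expect_equal(nrow(sim$truth$motif_positions), 0)
})

test_that("base composition hits the configured GC content", {
  cfg <- sim_config(n_transcripts = 1000, transcript_length = 1000,
                    gc_content = 0.5, seed = 5)
  sim <- generate_reference(cfg)
  bases <- table(strsplit(paste(sim$reference, collapse = ""), "")[[1]])
  gc <- sum(bases[c("G", "C")]) / sum(bases)
  ## binomial 3 sigma at n = 1e6 is ~0.0015; assert a safely wider 0.01
  expect_lt(abs(gc - 0.5), 0.01)
})

test_that("implants are present, recorded exactly and inside bound regions", {
  cfg <- sim_config(seed = 11)
  sim <- generate_reference(cfg)
  mp <- sim$truth$motif_positions
  expect_equal(nrow(mp), cfg$n_bound)
  ## truth consistency: re-reading the FASTA at each position reproduces
  ## the implanted k-mer byte for byte
  for (i in seq_len(nrow(mp))) {
    got <- substr(sim$reference[[mp$ref[i]]], mp$offset[i] + 1,
                  mp$offset[i] + cfg$motif_width)
    expect_identical(got, mp$site_seq[i])
  }
  ## each implant lies inside its bound region
  br <- sim$truth$bound_regions
  joined <- dplyr::left_join(mp, br, by = "ref")
  expect_true(all(joined$offset >= joined$start &
                    joined$offset + cfg$motif_width <= joined$end))
  ## implants match the truth PWM consensus at least at the PWM's expected
  ## identity (minus sampling noise)
  cons <- strsplit(pwm_consensus(sim$truth$pwm), "")[[1]]
  exp_id <- mean(apply(sim$truth$pwm$mat, 2, max))
  idents <- vapply(seq_len(nrow(mp)), function(i) {
    site <- if (mp$strand[i] == "+") mp$site_seq[i] else revcomp(mp$site_seq[i])
    mean(strsplit(site, "")[[1]] == cons)
  }, numeric(1))
  sd3 <- 3 * sqrt(exp_id * (1 - exp_id) / cfg$motif_width)
  expect_gt(mean(idents), exp_id - sd3)
})

test_that("truth PWM columns hit the configured information content", {
  tp <- withr::with_seed(1, chirpmotif:::sample_truth_pwm(21, 1.2))
  col_ic <- apply(tp$mat, 2, function(p) sum(ifelse(p > 0,
                                                    p * log2(p / 0.25), 0)))
  expect_equal(col_ic, rep(1.2, 21), tolerance = 1e-6)
  expect_equal(pwm_information_content(tp), 21 * 1.2, tolerance = 1e-6)
})

test_that("artifact spikes never overlap bound regions", {
  for (sd in 1:3) {
    sim <- generate_reference(sim_config(seed = sd))
    sp <- sim$truth$artifact_spikes
    br <- sim$truth$bound_regions
    expect_equal(nrow(sp), 5)
    expect_true(all(sp$pool %in% c("odd", "even")))
    for (i in seq_len(nrow(sp))) {
      expect_false(overlaps_any(sp$ref[i], sp$start[i], sp$end[i], br))
    }
  }
})

test_that("the simulator is deterministic given the config", {
  cfg <- sim_config(seed = 21, n_transcripts = 50)
  a <- generate_reference(cfg)
  b <- generate_reference(cfg)
  expect_identical(a, b)
  la <- simulate_pulldown(cfg, a$reference, a$truth)
  lb <- simulate_pulldown(cfg, b$reference, b$truth)
  expect_identical(la, lb)
  da <- simulate_de_table(cfg, a$truth, n_up = 10, n_down = 10)
  db <- simulate_de_table(cfg, b$truth, n_up = 10, n_down = 10)
  expect_identical(da, db)
})

test_that("pulldown coverage ratio approximates the enrichment fold", {
  cfg <- sim_config(seed = 8, background_rate = 0.05, enrichment_fold = 20,
                    n_transcripts = 200)
  sim <- generate_reference(cfg)
  libs <- simulate_pulldown(cfg, sim$reference, sim$truth)
  br <- sim$truth$bound_regions
  for (lib in c("odd", "even")) {
    cov <- compute_coverage(libs[[lib]], nchar(sim$reference))
    inside <- unlist(mapply(function(r, s, e) cov$values[[r]][(s + 1):e],
                            br$ref, br$start, br$end))
    mask <- cov$values
    for (i in seq_len(nrow(br))) {
      ## exclude the read-length ramp around each region from "outside"
      lo <- max(br$start[i] - cfg$read_length, 0) + 1
      hi <- min(br$end[i] + cfg$read_length, cfg$transcript_length)
      mask[[br$ref[i]]][lo:hi] <- NA
    }
    for (i in seq_len(nrow(sim$truth$artifact_spikes))) {
      sp <- sim$truth$artifact_spikes[i, ]
      lo <- max(sp$start - cfg$read_length, 0) + 1
      hi <- min(sp$end + cfg$read_length, cfg$transcript_length)
      mask[[sp$ref]][lo:hi] <- NA
    }
    outside <- unlist(mask)
    ratio <- mean(inside) / mean(outside, na.rm = TRUE)
    expect_lt(abs(ratio - 20) / 20, 0.25)
  }
})

test_that("an artifact spike is background-level in the other pool", {
  cfg <- sim_config(seed = 13, background_rate = 0.05)
  sim <- generate_reference(cfg)
  libs <- simulate_pulldown(cfg, sim$reference, sim$truth)
  sp <- sim$truth$artifact_spikes
  bg_cov <- cfg$background_rate * cfg$read_length
  for (i in seq_len(nrow(sp))) {
    other <- if (sp$pool[i] == "odd") "even" else "odd"
    cov <- compute_coverage(libs[[other]], nchar(sim$reference))
    at_spike <- mean(cov$values[[sp$ref[i]]][(sp$start[i] + 1):sp$end[i]])
    ## Poisson background, mean cov 5 over 300 positions (~3 independent
    ## read-length windows): stay within a generous factor of background
    expect_lt(at_spike, 4 * bg_cov)
    ## and nowhere near the spiked pool's level
    cov_own <- compute_coverage(libs[[sp$pool[i]]], nchar(sim$reference))
    own <- mean(cov_own$values[[sp$ref[i]]][(sp$start[i] + 1):sp$end[i]])
    expect_gt(own, 3 * at_spike)
  }
})

test_that("library-size bookkeeping: total coverage = reads x read length", {
  cfg <- sim_config(seed = 4, n_transcripts = 50)
  sim <- generate_reference(cfg)
  libs <- simulate_pulldown(cfg, sim$reference, sim$truth)
  for (lib in names(libs)) {
    cov <- compute_coverage(libs[[lib]], nchar(sim$reference))
    expect_equal(sum(unlist(cov$values)),
                 nrow(libs[[lib]]) * cfg$read_length)
  }
})

test_that("DE table respects class sizes and motif fractions", {
  cfg <- sim_config(seed = 2, n_transcripts = 800, transcript_length = 400,
                    n_bound = 106, bound_region_width = 50,
                    n_artifact_spikes = 0)
  sim <- generate_reference(cfg)
  de <- simulate_de_table(cfg, sim$truth, n_up = 120, n_down = 120,
                          motif_frac_up = 0.6, motif_frac_other = 0.05)
  expect_equal(sum(de$class == "up"), 120)
  expect_equal(sum(de$class == "down"), 120)
  expect_equal(sum(de$class == "unchanged"), 560)
  expect_equal(sort(de$transcript_id), sort(names(sim$reference)))
  motif_ids <- unique(sim$truth$motif_positions$ref)
  frac <- function(cls) mean(de$transcript_id[de$class == cls] %in% motif_ids)
  ## up and down classes receive their target counts exactly (by
  ## construction); the unchanged class absorbs the remaining carriers
  expect_equal(frac("up"), round(0.6 * 120) / 120)
  expect_equal(frac("down"), round(0.05 * 120) / 120)
  expect_lt(abs(frac("unchanged") - 0.05), 3 * sqrt(0.05 * 0.95 / 560))
  ## sign conventions of the fold changes
  expect_true(all(de$log2fc[de$class == "up"] > 0))
  expect_true(all(de$log2fc[de$class == "down"] < 0))
  ## class sizes beyond the transcriptome are an error
  expect_error(simulate_de_table(cfg, sim$truth, n_up = 500, n_down = 400),
               "exceed")
})

test_that("writing a simulation produces the documented files", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 6, n_transcripts = 30, n_bound = 5,
                    n_artifact_spikes = 2)
  out <- write_simulation(cfg, dir, n_up = 5, n_down = 5)
  expect_setequal(list.files(dir),
                  c("reference.fa", "odd.bed", "even.bed", "lacz.bed",
                    "truth.json", "de_table.tsv"))
  ref <- read_fasta(file.path(dir, "reference.fa"))
  expect_identical(ref, out$reference)
  reads <- read_bed(file.path(dir, "odd.bed"))
  expect_equal(nrow(reads), nrow(out$libraries$odd))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$bound_regions), 5)
  de <- readr::read_tsv(file.path(dir, "de_table.tsv"),
                        show_col_types = FALSE)
  expect_equal(nrow(de), 30)
})
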