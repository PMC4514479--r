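make_de <- function(n_up = 531, n_down = 291, n_unch = 5000) {
  tibble::tibble(
    transcript_id = sprintf("g%04d", seq_len(n_up + n_down + n_unch)),
    log2fc = c(stats::runif(n_up, 0.5, 5), stats::runif(n_down, -5, -0.5),
               stats::rnorm(n_unch, 0, 0.1)),
    class = rep(c("up", "down", "unchanged"), c(n_up, n_down, n_unch))
  )
}

test_that("set selection reproduces the 300/291/100x300 design", {
  withr::with_seed(1, de <- make_de())
  sets <- select_sets(de, enrichment_config(seed = 5))
  expect_equal(sum(sets$group == "up"), 300)
  expect_equal(sum(sets$group == "down"), 291)
  expect_equal(sum(sets$group == "unchanged"), 100 * 300)
  expect_equal(dplyr::n_distinct(sets$set[sets$group == "unchanged"]), 100)
  ## sampling without replacement within each control set
  per_set <- tapply(sets$transcript_id[sets$group == "unchanged"],
                    sets$set[sets$group == "unchanged"],
                    function(x) anyDuplicated(x) == 0)
  expect_true(all(per_set))
  ## the top 300 by |log2fc| are selected from the up class
  up <- de[de$class == "up", ]
  want <- up$transcript_id[order(-abs(up$log2fc))][1:300]
  expect_setequal(sets$transcript_id[sets$group == "up"], want)
})

test_that("set selection is seed-deterministic and validates sizes", {
  withr::with_seed(2, de <- make_de(310, 291, 400))
  cfg <- enrichment_config(seed = 7)
  expect_identical(select_sets(de, cfg), select_sets(de, cfg))
  expect_error(select_sets(de, enrichment_config(n_up = 400)),
               "'up' has 310")
  ## an up class of exactly n_up is returned whole, ranking irrelevant
  withr::with_seed(3, de2 <- make_de(300, 291, 400))
  s <- select_sets(de2, enrichment_config(seed = 1))
  expect_setequal(s$transcript_id[s$group == "up"],
                  de2$transcript_id[de2$class == "up"])
})

test_that("welch_t matches its closed form and stats::t.test", {
  res <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * stats::pt(-3 / sqrt(2 / 3), 4))
  ## symmetry: swapping negates t, p unchanged
  rev <- welch_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$t, -res$t)
  expect_equal(rev$p_value, res$p_value)
  ## identical degenerate samples: p = 1 by convention
  expect_equal(welch_t(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(welch_t(c(2, 2), c(2, 2))$t, 0)
  ## agreement with stats::t.test on ordinary data
  withr::with_seed(4, {
    a <- stats::rnorm(20)
    b <- stats::rnorm(15, 0.5)
  })
  tt <- stats::t.test(a, b)
  mine <- welch_t(a, b)
  expect_equal(mine$t, unname(tt$statistic))
  expect_equal(mine$p_value, tt$p.value)
})

test_that("enrichment pools control sets and reports per-set means", {
  withr::with_seed(5, de <- make_de(20, 20, 100))
  cfg <- enrichment_config(n_up = 10, n_down = 10, n_unchanged_sets = 4,
                           unchanged_set_size = 10, seed = 2)
  sets <- select_sets(de, cfg)
  withr::with_seed(6, {
    ev <- tibble::tibble(seq = de$transcript_id,
                         e_value = stats::runif(nrow(de), 0.1, 50))
  })
  res <- run_enrichment(ev, sets, cfg)
  expect_s3_class(res, "enrichment_result")
  expect_equal(nrow(res$set_means), 4)
  expect_equal(res$groups$n[res$groups$group == "unchanged"], 40)
  expect_equal(sort(res$tests$comparison),
               sort(c("up_vs_unchanged", "up_vs_down", "down_vs_unchanged")))
  expect_true(all(res$tests$p_value > 0 & res$tests$p_value <= 1))
  ## per-set means equal direct recomputation
  lut <- setNames(log(ev$e_value), ev$seq)
  for (k in 1:4) {
    ids <- sets$transcript_id[sets$group == "unchanged" &
                                !is.na(sets$set) & sets$set == k]
    expect_equal(res$set_means$mean_log_e[res$set_means$set == k],
                 mean(lut[ids]), ignore_attr = TRUE)
  }
  ## missing e-values are reported by transcript
  victim <- sets$transcript_id[1]
  expect_error(run_enrichment(ev[ev$seq != victim, ], sets, cfg), victim)
})

test_that("identical groups give t = 0", {
  de <- tibble::tibble(transcript_id = sprintf("g%d", 1:30),
                       log2fc = rep(c(1, -1, 0), each = 10),
                       class = rep(c("up", "down", "unchanged"), each = 10))
  cfg <- enrichment_config(n_up = 10, n_down = 10, n_unchanged_sets = 2,
                           unchanged_set_size = 10, seed = 1)
  sets <- select_sets(de, cfg)
  ev <- tibble::tibble(seq = de$transcript_id, e_value = 2)
  res <- run_enrichment(ev, sets, cfg)
  expect_true(all(res$tests$t == 0))
  expect_true(all(res$tests$p_value == 1))
})

test_that("motif-enriched up class is detected with the right direction", {
  run_one <- function(seed, null) {
    cfg <- sim_config(seed = seed, n_transcripts = 800,
                      transcript_length = 500, n_bound = 106,
                      bound_region_width = 120, n_artifact_spikes = 0)
    sim <- generate_reference(cfg)
    de <- simulate_de_table(cfg, sim$truth, n_up = 120, n_down = 120,
                            motif_frac_up = if (null) 0.05 else 0.6,
                            motif_frac_other = 0.05)
    ecfg <- enrichment_config(n_up = 100, n_down = 100,
                              n_unchanged_sets = 20,
                              unchanged_set_size = 100, seed = seed)
    sets <- select_sets(de, ecfg)
    sc <- scan_set(sim$reference[unique(sets$transcript_id)],
                   sim$truth$pwm)
    glance(run_enrichment(sc$evalues, sets, ecfg))
  }
  g <- run_one(1, null = FALSE)
  expect_lt(g$p_value, 0.01)
  expect_lt(g$estimate, 0)   # up group has lower log e-scores
})

test_that("permuting class labels destroys the enrichment signal", {
  cfg <- sim_config(seed = 3, n_transcripts = 800, transcript_length = 500,
                    n_bound = 106, bound_region_width = 120,
                    n_artifact_spikes = 0)
  sim <- generate_reference(cfg)
  de <- simulate_de_table(cfg, sim$truth, n_up = 120, n_down = 120,
                          motif_frac_up = 0.6, motif_frac_other = 0.05)
  ecfg <- enrichment_config(n_up = 100, n_down = 100, n_unchanged_sets = 10,
                            unchanged_set_size = 100, seed = 3)
  sc <- scan_set(sim$reference, sim$truth$pwm)
  real_p <- glance(run_enrichment(sc$evalues, select_sets(de, ecfg),
                                  ecfg))$p_value
  perm_p <- vapply(1:10, function(k) {
    dp <- de
    dp$class <- withr::with_seed(100 + k, sample(dp$class))
    glance(run_enrichment(sc$evalues, select_sets(dp, ecfg), ecfg))$p_value
  }, numeric(1))
  expect_lt(real_p, 0.01)
  expect_gt(stats::median(perm_p), 0.2)
})
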