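#' Motif-enrichment test configuration
#'
#' Defaults follow the reverse-search design: the top 300 upregulated
#' transcripts, all 291 downregulated transcripts, and 100 independently
#' resampled sets of 300 unchanged transcripts as the control.
#'
#' @param n_up Number of upregulated transcripts selected (default 300).
#' @param n_down Number of downregulated transcripts selected (default 291).
#' @param n_unchanged_sets Number of resampled unchanged control sets
#'   (default 100).
#' @param unchanged_set_size Size of each unchanged set (default 300).
#' @param up_ranking How the top `n_up` upregulated transcripts are chosen:
#'   `"abs_log2fc"` (default, largest absolute fold change) or `"log2fc"`.
#' @param seed Integer RNG seed for the unchanged-set resampling.
#' @param log_floor Smallest admissible e-value before the log transform
#'   (default 1e-300).
#' @param var_equal Use the pooled-variance t-test instead of Welch
#'   (default `FALSE`).
#' @return An `enrichment_config` list.
#' @export
enrichment_config <- function(n_up = 300L, n_down = 291L,
                              n_unchanged_sets = 100L,
                              unchanged_set_size = 300L,
                              up_ranking = c("abs_log2fc", "log2fc"),
                              seed = 1L, log_floor = 1e-300,
                              var_equal = FALSE) {
  up_ranking <- match.arg(up_ranking)
  stopifnot(n_up >= 2, n_down >= 2, n_unchanged_sets >= 1,
            unchanged_set_size >= 2, log_floor > 0)
  structure(
    list(n_up = as.integer(n_up), n_down = as.integer(n_down),
         n_unchanged_sets = as.integer(n_unchanged_sets),
         unchanged_set_size = as.integer(unchanged_set_size),
         up_ranking = up_ranking, seed = as.integer(seed),
         log_floor = log_floor, var_equal = isTRUE(var_equal)),
    class = "enrichment_config"
  )
}

#' Select transcript sets from a differential-expression table
#'
#' Picks the top `n_up` upregulated transcripts by the configured ranking,
#' the first `n_down` downregulated transcripts, and `n_unchanged_sets`
#' independent samples (without replacement within each set) of
#' `unchanged_set_size` unchanged transcripts.
#'
#' @param de_table Tibble with columns `transcript_id`, `log2fc`, `class`
#'   (values `"up"`, `"down"`, `"unchanged"`).
#' @param config An [enrichment_config()].
#' @return Tibble with columns `group` (`up`/`down`/`unchanged`), `set`
#'   (control-set index, `NA` for up/down) and `transcript_id`.
#' @export
select_sets <- function(de_table, config = enrichment_config()) {
  stopifnot(all(c("transcript_id", "log2fc", "class") %in% names(de_table)))
  up <- filter(de_table, .data$class == "up")
  down <- filter(de_table, .data$class == "down")
  unch <- filter(de_table, .data$class == "unchanged")
  check <- function(have, want, cls) {
    if (have < want) {
      abort(sprintf(
        "class '%s' has %d transcripts but %d were requested", cls, have, want))
    }
  }
  check(nrow(up), config$n_up, "up")
  check(nrow(down), config$n_down, "down")
  check(nrow(unch), config$unchanged_set_size, "unchanged")
  key <- if (config$up_ranking == "abs_log2fc") abs(up$log2fc) else up$log2fc
  up_ids <- up$transcript_id[order(-key, up$transcript_id)][seq_len(config$n_up)]
  down_ids <- down$transcript_id[seq_len(config$n_down)]
  unch_sets <- withr::with_seed(config$seed, {
    lapply(seq_len(config$n_unchanged_sets), function(k) {
      sample(unch$transcript_id, config$unchanged_set_size)
    })
  })
  bind_rows(
    tibble(group = "up", set = NA_integer_, transcript_id = up_ids),
    tibble(group = "down", set = NA_integer_, transcript_id = down_ids),
    bind_rows(purrr::imap(unch_sets, function(ids, k) {
      tibble(group = "unchanged", set = as.integer(k), transcript_id = ids)
    }))
  )
}

#' Two-sample t-test on log e-scores
#'
#' Welch's unequal-variance t-test (two-tailed) via [stats::t.test()]; the
#' pooled-variance form is available with `var_equal = TRUE`. Degenerate
#' inputs (zero variance in both samples) are handled by convention:
#' p = 1 when the means are equal.
#'
#' @param a,b Numeric samples, each of length at least 2.
#' @param var_equal Pooled-variance form? Default `FALSE` (Welch).
#' @return One-row tibble: `estimate` (mean(a) − mean(b)), `t`, `df`,
#'   `p_value`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
welch_t <- function(a, b, var_equal = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(c(a, b))))
  d <- mean(a) - mean(b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (d == 0) {
      return(tibble(estimate = 0, t = 0, df = NA_real_, p_value = 1))
    }
    return(tibble(estimate = d, t = sign(d) * Inf, df = NA_real_,
                  p_value = .Machine$double.xmin))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  tibble(estimate = d, t = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value)
}

#' Resampling motif-enrichment test across DE classes
#'
#' Floors and log-transforms per-transcript motif E-values, then compares
#' the three groups with two-tailed t-tests: upregulated vs unchanged
#' (pooled across all control sets; the headline test), upregulated vs
#' downregulated, and downregulated vs unchanged. Per-control-set mean log
#' e-scores are also reported. Lower log e-scores mean stronger motif
#' presence, so enrichment in the up class shows as a negative
#' up-vs-unchanged estimate.
#'
#' @param evalues Tibble with `seq` (or `transcript_id`) and `e_value`
#'   columns, one row per transcript ([scan_set()] output).
#' @param sets Tibble from [select_sets()].
#' @param config An [enrichment_config()].
#' @return An `enrichment_result` with `groups` (per-group n/mean/sd of log
#'   e-scores), `tests` (three pairwise t-tests), `set_means`
#'   (per-unchanged-set means) and the per-transcript values.
#' @export
run_enrichment <- function(evalues, sets, config = enrichment_config()) {
  if ("transcript_id" %in% names(evalues) && !"seq" %in% names(evalues)) {
    evalues <- rename(evalues, seq = "transcript_id")
  }
  missing <- setdiff(unique(sets$transcript_id), evalues$seq)
  if (length(missing) > 0) {
    abort(sprintf("no e-value for transcript(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  lut <- setNames(evalues$e_value, evalues$seq)
  vals <- mutate(
    sets,
    e_value = unname(lut[.data$transcript_id]),
    log_e = log(pmax(.data$e_value, config$log_floor))
  )
  grp <- function(g) vals$log_e[vals$group == g]
  groups <- vals |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(), mean_log_e = mean(.data$log_e),
              sd_log_e = stats::sd(.data$log_e), .groups = "drop")
  tests <- bind_rows(
    mutate(welch_t(grp("up"), grp("unchanged"), config$var_equal),
           comparison = "up_vs_unchanged", .before = 1),
    mutate(welch_t(grp("up"), grp("down"), config$var_equal),
           comparison = "up_vs_down", .before = 1),
    mutate(welch_t(grp("down"), grp("unchanged"), config$var_equal),
           comparison = "down_vs_unchanged", .before = 1)
  )
  set_means <- vals |>
    filter(.data$group == "unchanged") |>
    group_by(.data$set) |>
    summarise(mean_log_e = mean(.data$log_e), .groups = "drop")
  structure(
    list(groups = groups, tests = tests, set_means = set_means,
         values = vals, config = config),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>\n")
  print(x$groups)
  print(x$tests)
  invisible(x)
}

#' Tidiers for enrichment results
#'
#' `tidy()` returns the three pairwise tests; `glance()` a one-row summary
#' with the headline up-vs-unchanged test.
#'
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.enrichment_result <- function(x, ...) x$tests

#' @rdname tidy.enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  main <- filter(x$tests, .data$comparison == "up_vs_unchanged")
  tibble(
    n_up = x$groups$n[x$groups$group == "up"],
    n_unchanged = x$groups$n[x$groups$group == "unchanged"],
    estimate = main$estimate, t = main$t, p_value = main$p_value,
    up_enriched = main$estimate < 0 & main$p_value < 0.05
  )
}
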