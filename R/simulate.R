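#' Simulation configuration
#'
#' Free parameters of the synthetic pulldown experiment: a transcriptome
#' reference (one "chromosome" per transcript), three read libraries (odd
#' pool, even pool, LacZ control) with Poisson read-start background,
#' shared true-binding enrichment in both pulldown pools, pool-specific
#' artifact spikes, a motif implanted at the centre of every bound region,
#' and a differential-expression table whose upregulated class can be
#' enriched for motif-carrying transcripts.
#'
#' @param n_transcripts Number of reference transcripts (default 1000).
#' @param transcript_length Length of each transcript in nt (default 1000).
#' @param gc_content GC fraction of the background sequence, in (0,1)
#'   (default 0.5).
#' @param n_bound Number of true target transcripts, one bound region each
#'   (default 20).
#' @param bound_region_width Width of each bound region in nt (default 300).
#' @param enrichment_fold Coverage fold of bound regions over background in
#'   both pulldown pools; also used for artifact spikes (default 20; must
#'   be >= 1).
#' @param background_rate Expected read starts per base per library
#'   (default 0.008, i.e. mean background coverage below one read so
#'   off-target positions are mostly uncovered in at least one pool, as in
#'   real pulldown libraries where reads concentrate at captured regions).
#' @param n_artifact_spikes Number of single-pool artifact regions
#'   (default 5).
#' @param motif_width Width of the implanted motif in nt (default 21).
#' @param motif_info_content Information content of the truth PWM in bits
#'   per column (default 1.2).
#' @param read_length Read length in nt (default 100; single-end reads
#'   fully inside a transcript).
#' @param seed Integer RNG seed; all simulator outputs are deterministic
#'   given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 1000L, transcript_length = 1000L,
                       gc_content = 0.5, n_bound = 20L,
                       bound_region_width = 300L, enrichment_fold = 20,
                       background_rate = 0.008, n_artifact_spikes = 5L,
                       motif_width = 21L, motif_info_content = 1.2,
                       read_length = 100L, seed = 1L) {
  cfg <- list(
    n_transcripts = as.integer(n_transcripts),
    transcript_length = as.integer(transcript_length),
    gc_content = gc_content, n_bound = as.integer(n_bound),
    bound_region_width = as.integer(bound_region_width),
    enrichment_fold = enrichment_fold, background_rate = background_rate,
    n_artifact_spikes = as.integer(n_artifact_spikes),
    motif_width = as.integer(motif_width),
    motif_info_content = motif_info_content,
    read_length = as.integer(read_length), seed = as.integer(seed)
  )
  if (cfg$n_bound > cfg$n_transcripts) {
    abort("n_bound must not exceed n_transcripts")
  }
  if (cfg$bound_region_width > cfg$transcript_length) {
    abort("bound_region_width must not exceed transcript_length")
  }
  if (cfg$enrichment_fold < 1) abort("enrichment_fold must be >= 1")
  if (cfg$motif_width < 4) abort("motif_width must be >= 4")
  if (cfg$motif_width > cfg$bound_region_width) {
    abort("motif_width must not exceed bound_region_width")
  }
  if (cfg$gc_content <= 0 || cfg$gc_content >= 1) {
    abort("gc_content must be in (0, 1)")
  }
  structure(cfg, class = "sim_config")
}

## Dirichlet-sample PWM columns, then temper each column (p^t renormalised,
## t found by bisection) so its relative entropy against the uniform
## background hits the target bits/column.
sample_truth_pwm <- function(width, bits_per_col) {
  stopifnot(bits_per_col >= 0, bits_per_col < 2)
  col_ic <- function(p) sum(ifelse(p > 0, p * log2(p / 0.25), 0))
  temper <- function(p, target) {
    f <- function(t) {
      q <- p^t
      col_ic(q / sum(q)) - target
    }
    if (f(1) >= 0) {
      lo <- 0; hi <- 1
    } else {
      lo <- 1; hi <- 2
      while (f(hi) < 0 && hi < 4096) hi <- hi * 2
    }
    t <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    q <- p^t
    q / sum(q)
  }
  mat <- vapply(seq_len(width), function(w) {
    g <- stats::rgamma(4, shape = 1)
    temper(g / sum(g), bits_per_col)
  }, numeric(4))
  pwm(mat, background = rep(0.25, 4), name = "truth")
}

## sample one site (character string) from a PWM
sample_pwm_site <- function(x) {
  paste(.BASES[apply(x$mat, 2, function(p) sample.int(4, 1, prob = p))],
        collapse = "")
}

empty_truth <- function(truth_pwm = NULL) {
  structure(
    list(
      bound_regions = tibble(ref = character(0), start = integer(0),
                             end = integer(0)),
      motif_positions = tibble(ref = character(0), offset = integer(0),
                               strand = character(0), site_seq = character(0)),
      artifact_spikes = tibble(pool = character(0), ref = character(0),
                               start = integer(0), end = integer(0)),
      pwm = truth_pwm
    ),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> bound_regions=%d  motif_positions=%d  spikes=%d\n",
    nrow(x$bound_regions), nrow(x$motif_positions), nrow(x$artifact_spikes)))
  invisible(x)
}

#' Generate a synthetic transcriptome reference with ground truth
#'
#' Draws `n_transcripts` i.i.d. sequences at the configured GC content,
#' places one bound region per target transcript (with at least a
#' read-length margin from transcript ends where possible), implants one
#' motif instance sampled from a Dirichlet-drawn truth PWM at the centre of
#' every bound region (random strand), and places pool-specific artifact
#' spike intervals that never overlap bound regions.
#'
#' @param cfg A [sim_config()].
#' @return List with `reference` (named character vector, names
#'   `tx0001`, ...) and `truth` (a `synthetic_truth`: `bound_regions`,
#'   `motif_positions` with the implanted k-mer, `artifact_spikes`, and the
#'   truth `pwm`).
#' @export
generate_reference <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed)
  if (cfg$n_transcripts == 0) {
    return(list(reference = setNames(character(0), character(0)),
                truth = empty_truth()))
  }
  truth_pwm <- sample_truth_pwm(cfg$motif_width, cfg$motif_info_content)
  L <- cfg$transcript_length
  gc <- cfg$gc_content
  base_p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ids <- sprintf("tx%04d", seq_len(cfg$n_transcripts))
  mat <- matrix(sample(.BASES, cfg$n_transcripts * L, replace = TRUE,
                       prob = base_p),
                nrow = cfg$n_transcripts)
  reference <- setNames(apply(mat, 1, paste, collapse = ""), ids)

  w <- cfg$bound_region_width
  margin <- min(cfg$read_length, max((L - w) %/% 2, 0))
  bound_ids <- sort(sample(ids, cfg$n_bound))
  starts <- vapply(bound_ids, function(i) {
    lo <- margin
    hi <- L - w - margin
    if (hi < lo) { lo <- 0; hi <- L - w }
    if (hi > lo) sample(lo:hi, 1) else lo
  }, numeric(1))
  bound <- tibble(ref = bound_ids, start = as.integer(starts),
                  end = as.integer(starts + w))

  ## implant one motif instance at the centre of each bound region
  mw <- cfg$motif_width
  motif_rows <- vector("list", nrow(bound))
  for (i in seq_len(nrow(bound))) {
    site <- sample_pwm_site(truth_pwm)
    strand <- sample(c("+", "-"), 1)
    placed <- if (strand == "+") site else revcomp(site)
    off <- bound$start[i] + (w - mw) %/% 2L
    s <- reference[[bound$ref[i]]]
    reference[[bound$ref[i]]] <-
      paste0(substr(s, 1, off), placed, substr(s, off + mw + 1L, L))
    motif_rows[[i]] <- tibble(ref = bound$ref[i], offset = off,
                              strand = strand, site_seq = placed)
  }

  ## pool-specific artifact spikes, never overlapping bound regions
  spikes <- tibble(pool = character(0), ref = character(0),
                   start = integer(0), end = integer(0))
  if (cfg$n_artifact_spikes > 0) {
    pools <- rep(c("odd", "even"), length.out = cfg$n_artifact_spikes)
    rows <- vector("list", cfg$n_artifact_spikes)
    attempts <- 0L
    k <- 1L
    while (k <= cfg$n_artifact_spikes && attempts < 10000L) {
      attempts <- attempts + 1L
      ref <- sample(ids, 1)
      lo <- margin
      hi <- L - w - margin
      if (hi < lo) { lo <- 0; hi <- L - w }
      s <- if (hi > lo) sample(lo:hi, 1) else lo
      clash_bound <- any(bound$ref == ref &
                           intervals_overlap(s, s + w, bound$start, bound$end))
      placed_sp <- bind_rows(rows[seq_len(k - 1L)])
      clash_spike <- nrow(placed_sp) > 0 &&
        any(placed_sp$ref == ref &
              intervals_overlap(s, s + w, placed_sp$start, placed_sp$end))
      if (clash_bound || clash_spike) next
      rows[[k]] <- tibble(pool = pools[k], ref = ref, start = as.integer(s),
                          end = as.integer(s + w))
      k <- k + 1L
    }
    if (k <= cfg$n_artifact_spikes) {
      abort("could not place artifact spikes without overlapping bound regions")
    }
    spikes <- bind_rows(rows)
  }

  truth <- structure(
    list(bound_regions = bound,
         motif_positions = bind_rows(motif_rows) %||%
           empty_truth()$motif_positions,
         artifact_spikes = spikes,
         pwm = truth_pwm),
    class = "synthetic_truth"
  )
  if (nrow(bound) == 0) truth$motif_positions <- empty_truth()$motif_positions
  list(reference = reference, truth = truth)
}

## Poisson reads of fixed length with starts uniform over a start window.
## Returns a tibble(ref, start, end).
draw_reads <- function(ref, win_lo, win_hi, rate, read_length) {
  n_pos <- win_hi - win_lo + 1L
  if (n_pos <= 0) return(NULL)
  n <- rpois(1, rate * n_pos)
  if (n == 0) return(NULL)
  s <- win_lo + sample.int(n_pos, n, replace = TRUE) - 1L
  tibble(ref = ref, start = s, end = s + read_length)
}

#' Simulate the three pulldown read libraries
#'
#' Every library (odd pool, even pool, LacZ control) receives Poisson
#' background reads at `background_rate` starts per base, fully inside each
#' transcript. Bound regions receive additional reads in the odd AND even
#' libraries so their interior coverage is `enrichment_fold` times
#' background; artifact spikes receive the same excess in exactly one
#' pulldown library. Extra read starts are drawn from the window
#' `[start - read_length + 1, end)` (clipped) so per-base coverage inside
#' the region is uniform.
#'
#' @param cfg A [sim_config()].
#' @param reference Named character vector from [generate_reference()]
#'   (lengths only are used).
#' @param truth The matching `synthetic_truth`.
#' @return Named list (`odd`, `even`, `lacz`) of read tibbles (`ref`,
#'   `start`, `end`, 0-based half-open); `nrow()` of each is its
#'   mapped-read count.
#' @export
simulate_pulldown <- function(cfg, reference, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "synthetic_truth"))
  withr::local_seed((cfg$seed + 1000003L) %% .Machine$integer.max)
  rl <- cfg$read_length
  lens <- nchar(reference)
  libs <- c("odd", "even", "lacz")
  out <- setNames(vector("list", 3), libs)
  extra_rate <- (cfg$enrichment_fold - 1) * cfg$background_rate
  for (lib in libs) {
    parts <- list()
    ## background everywhere
    for (ref in names(reference)) {
      parts[[length(parts) + 1L]] <-
        draw_reads(ref, 0L, lens[[ref]] - rl, cfg$background_rate, rl)
    }
    ## shared enrichment at bound regions (pulldown pools only)
    if (lib != "lacz" && extra_rate > 0) {
      for (i in seq_len(nrow(truth$bound_regions))) {
        b <- truth$bound_regions[i, ]
        parts[[length(parts) + 1L]] <- draw_reads(
          b$ref, max(0L, b$start - rl + 1L), min(b$end - 1L, lens[[b$ref]] - rl),
          extra_rate, rl)
      }
    }
    ## pool-specific artifact spikes
    sp <- truth$artifact_spikes[truth$artifact_spikes$pool == lib, ]
    if (nrow(sp) > 0 && extra_rate > 0) {
      for (i in seq_len(nrow(sp))) {
        b <- sp[i, ]
        parts[[length(parts) + 1L]] <- draw_reads(
          b$ref, max(0L, b$start - rl + 1L), min(b$end - 1L, lens[[b$ref]] - rl),
          extra_rate, rl)
      }
    }
    reads <- bind_rows(parts)
    if (is.null(reads) || nrow(reads) == 0) {
      reads <- tibble(ref = character(0), start = integer(0), end = integer(0))
    }
    out[[lib]] <- arrange(reads, .data$ref, .data$start)
  }
  out
}

#' Simulate a differential-expression table
#'
#' Labels transcripts up/down/unchanged with the given class sizes. The
#' fraction of motif-carrying (bound) transcripts placed in the up class is
#' `motif_frac_up`; the other classes receive motif transcripts at
#' `motif_frac_other`. With equal fractions the classes are exchangeable
#' with respect to motif content (labels are assigned by random
#' permutation). Log2 fold changes are drawn per class (up positive, down
#' negative, unchanged near zero).
#'
#' @param cfg A [sim_config()].
#' @param truth The matching `synthetic_truth`.
#' @param n_up,n_down Class sizes (defaults 531 and 291); the remainder is
#'   unchanged.
#' @param motif_frac_up Target fraction of up-class transcripts carrying an
#'   implanted motif (default 0.6).
#' @param motif_frac_other Same fraction for the down and unchanged classes
#'   (default 0.05). Equal fractions give the exchangeable null.
#' @return Tibble: `transcript_id`, `log2fc`, `class`.
#' @export
simulate_de_table <- function(cfg, truth, n_up = 531L, n_down = 291L,
                              motif_frac_up = 0.6, motif_frac_other = 0.05) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "synthetic_truth"))
  n <- cfg$n_transcripts
  n_up <- as.integer(n_up)
  n_down <- as.integer(n_down)
  if (n_up + n_down > n) {
    abort(sprintf("class sizes (%d up + %d down) exceed n_transcripts (%d)",
                  n_up, n_down, n))
  }
  withr::local_seed((cfg$seed + 2000003L) %% .Machine$integer.max)
  ids <- sprintf("tx%04d", seq_len(n))
  n_unch <- n - n_up - n_down
  sizes <- c(up = n_up, down = n_down, unchanged = n_unch)

  if (motif_frac_up == motif_frac_other) {
    ## exchangeable null: labels independent of motif content
    perm <- sample(ids)
    assign <- split(perm, rep(names(sizes), sizes))
  } else {
    ## stratified assignment: the up and down classes receive their target
    ## numbers of motif-carrying transcripts; all remaining motif carriers
    ## land in the unchanged class, whose motif fraction is therefore
    ## (n_bound - up - down carriers) / n_unchanged — pick n_bound to set it.
    motif_ids <- unique(truth$motif_positions$ref)
    want_up <- round(motif_frac_up * n_up)
    want_down <- round(motif_frac_other * n_down)
    if (want_up + want_down > length(motif_ids)) {
      abort(sprintf(
        "need %d motif-carrying transcripts for the up and down classes but truth has only %d (raise n_bound)",
        want_up + want_down, length(motif_ids)))
    }
    if (length(motif_ids) - want_up - want_down > n_unch) {
      abort("more leftover motif-carrying transcripts than unchanged slots")
    }
    motif_pool <- sample(motif_ids)
    plain_pool <- sample(setdiff(ids, motif_ids))
    want <- c(up = want_up, down = want_down,
              unchanged = length(motif_ids) - want_up - want_down)
    assign <- list()
    mi <- 0L
    pi <- 0L
    for (cls in names(sizes)) {
      nm <- unname(want[cls])
      np <- sizes[[cls]] - nm
      assign[[cls]] <- c(motif_pool[seq_len(nm) + mi],
                         plain_pool[seq_len(np) + pi])
      mi <- mi + nm
      pi <- pi + np
    }
  }
  lfc <- function(cls, k) {
    switch(cls,
           up = 0.3 + abs(rnorm(k, 2, 0.7)),
           down = -(0.3 + abs(rnorm(k, 2, 0.7))),
           unchanged = rnorm(k, 0, 0.15))
  }
  out <- bind_rows(lapply(names(sizes), function(cls) {
    k <- length(assign[[cls]])
    tibble(transcript_id = assign[[cls]], log2fc = lfc(cls, k), class = cls)
  }))
  arrange(out, .data$transcript_id)
}

#' Write a full synthetic experiment to disk
#'
#' Emits the reference FASTA, one BED6 per library, the truth record as
#' JSON and the DE table as TSV.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @param ... Passed to [simulate_de_table()].
#' @return Invisibly, the list of generated objects.
#' @export
write_simulation <- function(cfg, outdir, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_reference(cfg)
  libs <- simulate_pulldown(cfg, sim$reference, sim$truth)
  de <- simulate_de_table(cfg, sim$truth, ...)
  write_fasta(sim$reference, file.path(outdir, "reference.fa"))
  for (lib in names(libs)) {
    write_bed(mutate(libs[[lib]], name = lib),
              file.path(outdir, paste0(lib, ".bed")))
  }
  truth <- sim$truth
  jsonlite::write_json(
    list(bound_regions = truth$bound_regions,
         motif_positions = truth$motif_positions,
         artifact_spikes = truth$artifact_spikes,
         truth_pwm = unname(as.data.frame(truth$pwm$mat))),
    file.path(outdir, "truth.json"), digits = NA)
  readr::write_tsv(de, file.path(outdir, "de_table.tsv"), progress = FALSE)
  invisible(list(reference = sim$reference, truth = truth,
                 libraries = libs, de_table = de))
}
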