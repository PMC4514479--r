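# Shared fixtures, all generated in code.

# Random DNA string
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A truth PWM plus sequences carrying one implant each (random strand,
# random offset): the parameter-recovery benchmark for motif discovery.
make_implant_case <- function(seed, n_seq = 100, len = 150, width = 21,
                              bits_per_col = 1.2) {
  withr::with_seed(seed, {
    tp <- chirpmotif:::sample_truth_pwm(width, bits_per_col)
    seqs <- vapply(seq_len(n_seq), function(i) {
      s <- rand_dna(len)
      site <- chirpmotif:::sample_pwm_site(tp)
      if (stats::runif(1) < 0.5) site <- revcomp(site)
      off <- sample(0:(len - width), 1)
      paste0(substr(s, 1, off), site, substr(s, off + width + 1, len))
    }, character(1))
    list(pwm = tp, seqs = stats::setNames(seqs, sprintf("s%d", seq_len(n_seq))))
  })
}

# Mean per-column Pearson correlation between two PWMs, taking the better
# of the forward and reverse-complement orientations.
pwm_column_cor <- function(a, b) {
  stopifnot(ncol(a$mat) == ncol(b$mat))
  rc <- b$mat[4:1, ncol(b$mat):1]
  f <- mean(vapply(seq_len(ncol(a$mat)),
                   function(w) stats::cor(a$mat[, w], b$mat[, w]),
                   numeric(1)))
  r <- mean(vapply(seq_len(ncol(a$mat)),
                   function(w) stats::cor(a$mat[, w], rc[, w]),
                   numeric(1)))
  max(f, r)
}

# Do any of the intervals in `b` overlap interval (ref, start, end)?
overlaps_any <- function(ref, start, end, b) {
  any(b$ref == ref & b$start < end & start < b$end)
}

# Brute-force per-position coverage: count intervals containing each
# position (the oracle for compute_coverage).
brute_coverage <- function(reads, len) {
  vapply(seq_len(len) - 1L,
         function(p) sum(reads$start <= p & p < reads$end), numeric(1))
}

# Brute-force run-length merging of defined track positions (the oracle
# for merge_regions): scan positions left to right, split on gaps.
brute_merge <- function(values, gap = 0) {
  pos <- which(!is.na(values))
  if (length(pos) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      mean = numeric(0)))
  }
  out <- list()
  run <- pos[1]
  for (p in pos[-1]) {
    if (p - run[length(run)] > gap + 1) {
      out[[length(out) + 1]] <- run
      run <- p
    } else {
      run <- c(run, p)
    }
  }
  out[[length(out) + 1]] <- run
  data.frame(
    start = vapply(out, function(r) min(r) - 1L, integer(1)),
    end = vapply(out, max, integer(1)),
    mean = vapply(out, function(r) mean(values[r]), numeric(1))
  )
}
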