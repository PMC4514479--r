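#' Motif scanning configuration
#'
#' Defaults mirror the conventional reverse-search settings: e-value
#' cutoff 100 and maximum position p-value 0.0001 for a reported match.
#'
#' @param max_hit_pvalue Largest position p-value reported as a motif hit
#'   (default 1e-4).
#' @param evalue_cutoff Sequences with E-value above this are flagged
#'   non-matching, but still reported (default 100).
#' @param score_bins Number of discretization bins for the exact score
#'   distribution (default 1000).
#' @param both_strands Scan both strands (default `TRUE`).
#' @return A `scan_config` list.
#' @export
scan_config <- function(max_hit_pvalue = 1e-4, evalue_cutoff = 100,
                        score_bins = 1000L, both_strands = TRUE) {
  stopifnot(max_hit_pvalue > 0, max_hit_pvalue < 1, evalue_cutoff > 0,
            score_bins >= 10)
  structure(
    list(max_hit_pvalue = max_hit_pvalue, evalue_cutoff = evalue_cutoff,
         score_bins = as.integer(score_bins),
         both_strands = isTRUE(both_strands)),
    class = "scan_config"
  )
}

#' Log-odds score of a k-mer against a PWM
#'
#' \deqn{\sum_w \log_2( p_w(x_w) / q(x_w) )}. The reverse strand scores
#' the reverse complement of the k-mer.
#'
#' @param x A `pwm`.
#' @param kmer Character string of length `pwm_width(x)` over ACGT.
#' @param strand `"+"` (default) or `"-"`.
#' @return Score in bits; `NA` with a warning if the k-mer contains an
#'   ambiguous base.
#' @export
logodds_score <- function(x, kmer, strand = "+") {
  stopifnot(inherits(x, "pwm"))
  W <- ncol(x$mat)
  if (nchar(kmer) != W) abort(sprintf("k-mer must have length %d", W))
  code <- encode_seq(toupper(kmer))
  if (strand == "-") code <- 5L - rev(code)
  if (any(code %in% c(0L, 5L))) {
    warn(sprintf("ambiguous base in k-mer '%s'; score undefined", kmer))
    return(NA_real_)
  }
  lo <- log2(x$mat) - log2(x$background)
  sum(lo[cbind(code, seq_len(W))])
}

#' Exact null distribution of discretized PWM scores
#'
#' Discretizes each column's log-odds contributions onto a common integer
#' grid (cell values floored, so discretized scores never exceed the exact
#' ones and the resulting p-values are conservative) and convolves the
#' per-column distributions under the background model. The result supports
#' exact `P(score >= s)` queries for any k-mer.
#'
#' @param x A `pwm`.
#' @param config A [scan_config()]; `score_bins` sets the grid resolution.
#' @return A `score_dist`: integer cell-score matrix, survival function over
#'   the integer grid, and the grid scale (bits per integer unit).
#' @export
score_distribution <- function(x, config = scan_config()) {
  stopifnot(inherits(x, "pwm"))
  W <- ncol(x$mat)
  lo <- log2(x$mat) - log2(x$background)       # bits, 4 x W
  col_min <- apply(lo, 2, min)
  rng <- sum(apply(lo, 2, max) - col_min)
  scale <- if (rng > 0) config$score_bins / rng else 1
  icell <- matrix(as.integer(floor((lo - rep(col_min, each = 4)) * scale)),
                  4, W)
  ## pmf over integer scores by per-column convolution
  max_int <- sum(apply(icell, 2, max))
  pmf <- c(1, numeric(max_int))                # index k+1 <-> int score k
  for (w in seq_len(W)) {
    new <- numeric(max_int + 1L)
    for (b in 1:4) {
      s <- icell[b, w]
      nz <- which(pmf > 0)
      new[nz + s] <- new[nz + s] + pmf[nz] * x$background[b]
    }
    pmf <- new
  }
  stopifnot(abs(sum(pmf) - 1) < 1e-9)
  sf <- rev(cumsum(rev(pmf)))                  # P(int score >= k)
  sf <- pmin(sf, 1)
  structure(
    list(icell = icell, lo = lo, sf = sf, scale = scale,
         offset_bits = sum(col_min), width = W,
         background = x$background),
    class = "score_dist"
  )
}

#' @export
print.score_dist <- function(x, ...) {
  cat(sprintf("<score_dist> width=%d  grid=%d ints  scale=%.3f bits/unit\n",
              x$width, length(x$sf) - 1L, 1 / x$scale))
  invisible(x)
}

## p-value of integer-discretized scores (vectorized)
score_pvalue_int <- function(dist, int_scores) {
  dist$sf[pmax(int_scores, 0L) + 1L]
}

## score all windows of one encoded sequence; returns offsets (0-based,
## forward-strand coordinates), strand, bits score, int score. Windows
## containing non-ACGT characters are dropped. Backed by the compiled
## scorer (src/scan.cpp).
scan_windows <- function(code, dist, both_strands) {
  w <- scan_windows_cpp(as.integer(code), dist$icell, dist$lo, both_strands)
  list(offset = w$offset, strand = c("+", "-")[w$istrand],
       bits = w$bits, int = w$int)
}

#' Scan one sequence for motif matches
#'
#' Scores every position (both strands unless configured otherwise) against
#' the PWM, reports hits with position p-value at or below
#' `max_hit_pvalue`, and combines the best position p-value into a sequence
#' p-value with the m-trials rule \eqn{1 - (1 - p_{best})^m}, where m is
#' the number of scored positions. The E-value is the sequence p-value
#' multiplied by the number of sequences in the query set.
#'
#' @param seq DNA string.
#' @param x A `pwm` or a precomputed [score_distribution()].
#' @param config A [scan_config()].
#' @param n_query Number of sequences in the query set (E-value factor).
#' @param id Sequence id used in the output.
#' @return List with `hits` (tibble: `seq`, `offset`, `strand`, `score`,
#'   `p_value`) and `evalue` (one-row tibble: `seq`, `best_p`,
#'   `seq_p`, `e_value`, `n_scored`, `matching`).
#' @export
scan_sequence <- function(seq, x, config = scan_config(), n_query = 1L,
                          id = "seq") {
  dist <- if (inherits(x, "score_dist")) x else score_distribution(x, config)
  code <- encode_seq(toupper(seq))
  w <- scan_windows(code, dist, config$both_strands)
  m <- length(w$offset)
  if (m == 0) {
    return(list(
      hits = tibble(seq = character(0), offset = integer(0),
                    strand = character(0), score = numeric(0),
                    p_value = numeric(0)),
      evalue = tibble(seq = id, best_p = 1, seq_p = 1,
                      e_value = 1 * n_query, n_scored = 0L,
                      matching = n_query <= config$evalue_cutoff)
    ))
  }
  p <- score_pvalue_int(dist, w$int)
  keep <- p <= config$max_hit_pvalue
  hits <- tibble(seq = id, offset = w$offset[keep], strand = w$strand[keep],
                 score = w$bits[keep], p_value = p[keep]) |>
    arrange(.data$p_value)
  best_p <- min(p)
  seq_p <- -expm1(m * log1p(-best_p))   # 1 - (1 - p)^m, stable for small p
  seq_p <- min(max(seq_p, .Machine$double.xmin), 1)
  ev <- seq_p * n_query
  list(hits = hits,
       evalue = tibble(seq = id, best_p = best_p, seq_p = seq_p,
                       e_value = ev, n_scored = m,
                       matching = ev <= config$evalue_cutoff))
}

#' Scan a set of sequences
#'
#' Applies [scan_sequence()] to every sequence; the E-value factor is the
#' number of sequences in the set.
#'
#' @param sequences Named character vector of DNA sequences (or data frame
#'   with `id` and `seq`/`sequence` columns).
#' @param x A `pwm`.
#' @param config A [scan_config()].
#' @return List with `evalues` (one row per sequence) and `hits` tibbles.
#' @export
scan_set <- function(sequences, x, config = scan_config()) {
  if (is.data.frame(sequences)) {
    sc <- intersect(c("seq", "sequence"), names(sequences))[1]
    sequences <- setNames(sequences[[sc]], sequences$id)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  }
  dist <- score_distribution(x, config)
  n <- length(sequences)
  ids <- names(sequences)
  best_p <- numeric(n)
  m <- integer(n)
  hit_parts <- vector("list", n)
  for (i in seq_len(n)) {
    w <- scan_windows(encode_seq(toupper(sequences[[i]])), dist,
                      config$both_strands)
    m[i] <- length(w$offset)
    if (m[i] == 0) {
      best_p[i] <- 1
      next
    }
    p <- score_pvalue_int(dist, w$int)
    best_p[i] <- min(p)
    keep <- which(p <= config$max_hit_pvalue)
    if (length(keep) > 0) {
      hit_parts[[i]] <- tibble(seq = ids[i], offset = w$offset[keep],
                               strand = w$strand[keep],
                               score = w$bits[keep], p_value = p[keep])
    }
  }
  seq_p <- ifelse(m == 0, 1, -expm1(m * log1p(-best_p)))
  seq_p <- pmin(pmax(seq_p, .Machine$double.xmin), 1)
  ev <- seq_p * n
  hits <- bind_rows(hit_parts)
  if (nrow(hits) == 0) {
    hits <- tibble(seq = character(0), offset = integer(0),
                   strand = character(0), score = numeric(0),
                   p_value = numeric(0))
  }
  list(evalues = tibble(seq = ids, best_p = best_p, seq_p = seq_p,
                        e_value = ev, n_scored = m,
                        matching = ev <= config$evalue_cutoff),
       hits = hits)
}
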