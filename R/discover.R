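#' Motif discovery configuration
#'
#' @param width Motif width in nt, either a single value or a numeric range
#'   `c(min, max)`; every width in the range is fitted and the winner is
#'   chosen by BIC-penalised likelihood.
#' @param mode Occurrence model: `"zoops"` (zero or one occurrence per
#'   sequence, the default — top peaks need not all contain the motif) or
#'   `"oops"` (exactly one occurrence per sequence).
#' @param max_iter Maximum EM iterations per start (default 200).
#' @param tol Convergence tolerance on the log-likelihood change (default
#'   1e-6).
#' @param n_seeds Number of seed starting points: distinct W-mers sampled
#'   from the input and converted to near-delta PWMs (default 1000, or all
#'   distinct W-mers when fewer). Generous seeding matters: the EM surface
#'   is multimodal and the basin of the true motif is reliably reached only
#'   from starts at or near genuine sites.
#' @param n_refine Number of best screened seeds run to full convergence
#'   (default 5); all seeds first get `screen_iter` iterations.
#' @param screen_iter EM iterations used to screen seeds (default 2).
#' @param both_strands Scan and model both strands (default `TRUE`).
#' @param pseudocount Per-cell pseudocount added in every M-step (default
#'   0.01) so no PWM column collapses to zero.
#' @param seed Integer RNG seed; discovery is deterministic given the seed.
#' @param engine EM implementation: `"cpp"` (compiled, default) or `"r"`
#'   (plain-R reference, used for cross-checking).
#' @return A `discovery_config` list.
#' @export
discovery_config <- function(width = 21, mode = c("zoops", "oops"),
                             max_iter = 200L, tol = 1e-6,
                             n_seeds = 1000L, n_refine = 5L, screen_iter = 2L,
                             both_strands = TRUE, pseudocount = 0.01,
                             seed = 1L, engine = c("cpp", "r")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  stopifnot(max_iter >= 1, tol > 0, n_seeds >= 1, n_refine >= 1,
            all(width >= 4), length(width) %in% c(1L, 2L))
  structure(
    list(width = as.integer(width), mode = mode,
         max_iter = as.integer(max_iter), tol = tol,
         n_seeds = as.integer(n_seeds), n_refine = as.integer(n_refine),
         screen_iter = as.integer(screen_iter),
         both_strands = isTRUE(both_strands), pseudocount = pseudocount,
         seed = as.integer(seed), engine = engine),
    class = "discovery_config"
  )
}

## Build the window table for one width: an n_windows x W integer matrix of
## base codes plus the owning sequence index and strand of each window.
## Reverse-strand windows are the reverse complements of the forward
## windows, so a single PWM models both orientations.
build_windows <- function(codes, W, both_strands) {
  n <- length(codes)
  per_seq <- lengths(codes) - W + 1L
  idx_rows <- function(code_vec) {
    nw <- length(code_vec) - W + 1L
    if (nw <= 0) return(NULL)
    outer(seq_len(nw), 0:(W - 1L), `+`)
  }
  mats <- vector("list", n * 2L)
  seq_idx <- vector("list", n * 2L)
  strands <- vector("list", n * 2L)
  offs <- vector("list", n * 2L)
  for (i in seq_len(n)) {
    rows <- idx_rows(codes[[i]])
    m <- matrix(codes[[i]][rows], nrow = nrow(rows))
    mats[[i]] <- m
    seq_idx[[i]] <- rep.int(i, nrow(m))
    strands[[i]] <- rep.int("+", nrow(m))
    offs[[i]] <- seq_len(nrow(m)) - 1L
    if (both_strands) {
      rc <- 5L - rev(codes[[i]])
      m2 <- matrix(rc[rows], nrow = nrow(rows))
      mats[[n + i]] <- m2
      seq_idx[[n + i]] <- rep.int(i, nrow(m2))
      strands[[n + i]] <- rep.int("-", nrow(m2))
      ## offset of the site on the forward strand
      offs[[n + i]] <- rev(seq_len(nrow(m2)) - 1L)
    }
  }
  X <- do.call(rbind, mats[!vapply(mats, is.null, logical(1))])
  list(
    X = X,
    flat = sweep(X, 2, (seq_len(W) - 1L) * 4L, `+`),
    seq_idx = unlist(seq_idx),
    strand = unlist(strands),
    offset = unlist(offs),
    m_per_seq = as.numeric(per_seq * (1L + both_strands)),
    n_seq = n
  )
}

## One EM pass (E+M) for ZOOPS/OOPS. Returns updated theta, gamma and the
## log-likelihood of the *current* parameters (computed in the E-step, so a
## non-decreasing sequence certifies EM monotonicity).
em_step <- function(win, theta, gamma, bg, mode, pseudocount) {
  W <- ncol(theta)
  llr <- log(theta) - log(bg)          # 4 x W
  sc <- as.vector(llr)[win$flat]
  dim(sc) <- dim(win$flat)
  lr <- exp(rowSums(sc))               # likelihood ratio per window
  s_i <- as.vector(rowsum(lr, win$seq_idx))   # per-sequence sums
  m_i <- win$m_per_seq
  if (mode == "zoops") {
    denom <- (1 - gamma) + gamma * s_i / m_i
    ll <- sum(log(denom))
    z <- (gamma / m_i[win$seq_idx]) * lr / denom[win$seq_idx]
    q_i <- gamma * (s_i / m_i) / denom
    gamma_new <- min(max(mean(q_i), 1e-3), 1 - 1e-3)
  } else {
    ll <- sum(log(s_i / m_i))
    z <- lr / s_i[win$seq_idx]
    q_i <- rep(1, win$n_seq)
    gamma_new <- 1
  }
  counts <- matrix(pseudocount, 4, W)
  for (w in seq_len(W)) {
    cw <- rowsum(z, win$X[, w])
    counts[as.integer(rownames(cw)), w] <-
      counts[as.integer(rownames(cw)), w] + cw
  }
  theta_new <- sweep(counts, 2, colSums(counts), `/`)
  list(theta = theta_new, gamma = gamma_new, ll = ll, z = z, q = q_i)
}

## Run EM from one starting matrix until convergence; returns final state
## and the (monotone) log-likelihood trace. The compiled core is the
## default; engine = "r" runs the plain-R reference implementation
## (em_step), kept as an independent cross-check of the C++ code.
run_em <- function(win, theta0, gamma0, bg, mode, pseudocount,
                   max_iter, tol, engine = "cpp") {
  if (engine == "cpp") {
    st <- em_fit_cpp(win$X, as.integer(win$seq_idx), win$m_per_seq,
                     theta0, gamma0, bg, mode == "zoops", pseudocount,
                     as.integer(max_iter), tol)
    return(list(theta = st$theta, gamma = st$gamma, ll = st$ll,
                trace = st$trace, z = as.vector(st$z), q = as.vector(st$q)))
  }
  theta <- theta0
  gamma <- gamma0
  trace <- numeric(0)
  st <- NULL
  for (it in seq_len(max_iter)) {
    st <- em_step(win, theta, gamma, bg, mode, pseudocount)
    trace <- c(trace, st$ll)
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) break
    theta <- st$theta
    gamma <- st$gamma
  }
  list(theta = theta, gamma = gamma, ll = trace[length(trace)],
       trace = trace, z = st$z, q = st$q)
}

## Fit a single width; seeds are screened for a few iterations, the best
## few run to convergence.
fit_width <- function(codes, W, cfg, bg) {
  short <- which(lengths(codes) < W)
  if (length(short) > 0) {
    abort(sprintf("sequence(s) shorter than motif width %d: %s", W,
                  paste(names(codes)[short], collapse = ", ")))
  }
  win <- build_windows(codes, W, cfg$both_strands)
  ## seed W-mers: distinct forward windows, sampled
  fwd <- win$strand == "+"
  keys <- apply(win$X[fwd, , drop = FALSE], 1, paste, collapse = "")
  uniq <- which(fwd)[!duplicated(keys)]
  n_seed <- min(cfg$n_seeds, length(uniq))
  picks <- sample(uniq, n_seed)
  gamma0 <- if (cfg$mode == "zoops") 0.5 else 1
  if (cfg$engine == "cpp") {
    st <- em_discover_cpp(win$X, as.integer(win$seq_idx), win$m_per_seq,
                          as.integer(picks), 0.6, gamma0, bg,
                          cfg$mode == "zoops", cfg$pseudocount,
                          cfg$screen_iter, cfg$n_refine, cfg$max_iter,
                          cfg$tol)
    best <- list(theta = st$theta, gamma = st$gamma, ll = st$ll,
                 trace = as.vector(st$trace), z = as.vector(st$z),
                 q = as.vector(st$q))
  } else {
    seed_theta <- function(row) {
      th <- matrix((1 - 0.6) / 3, 4, W)
      th[cbind(win$X[row, ], seq_len(W))] <- 0.6
      th
    }
    screened <- lapply(picks, function(rw) {
      run_em(win, seed_theta(rw), gamma0, bg, cfg$mode, cfg$pseudocount,
             max_iter = cfg$screen_iter, tol = 0, engine = "r")
    })
    lls <- vapply(screened, `[[`, numeric(1), "ll")
    top <- order(lls, decreasing = TRUE)[seq_len(min(cfg$n_refine, n_seed))]
    fits <- lapply(top, function(k) {
      run_em(win, screened[[k]]$theta, screened[[k]]$gamma, bg,
             cfg$mode, cfg$pseudocount, cfg$max_iter, cfg$tol, engine = "r")
    })
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
  }
  ## per-sequence best site from the final responsibilities
  ord <- order(win$seq_idx, -best$z)
  first <- ord[!duplicated(win$seq_idx[ord])]
  sites <- tibble(
    seq = names(codes)[win$seq_idx[first]],
    offset = win$offset[first],
    strand = win$strand[first],
    posterior = best$q
  )
  list(theta = best$theta, gamma = best$gamma, ll = best$ll,
       trace = best$trace, sites = sites, win_n = nrow(win$X))
}

#' De novo PWM motif discovery by expectation-maximization
#'
#' Finds an ungapped motif in a set of sequences with a ZOOPS
#' (zero-or-one-occurrence-per-sequence) or OOPS finite mixture model
#' fitted by EM, the same model family used by classical de novo motif
#' search tools on pulldown peak sequences. Starting points are distinct
#' W-mers from the input converted to near-delta PWMs; each start is
#' screened with a couple of EM iterations and the best are run to
#' convergence. With a width range, every width is fitted and the winner
#' minimises BIC (−2 log L + (3W+1) log n).
#'
#' @param sequences Named character vector of DNA sequences (or a
#'   `data.frame` with columns `seq`/`sequence` and optional ids).
#' @param config A [discovery_config()].
#' @return A `motif_fit`: list with elements `pwm`, `loglik`, `ll_trace`
#'   (monotone non-decreasing), `gamma` (fitted occurrence probability),
#'   `sites` (tibble of per-sequence best sites with posteriors), `width`,
#'   and `width_table` (per-width log-likelihood and BIC when a range was
#'   searched).
#' @export
discover_motif <- function(sequences, config = discovery_config()) {
  if (is.data.frame(sequences)) {
    sc <- intersect(c("seq", "sequence"), names(sequences))[1]
    ids <- if ("id" %in% names(sequences)) sequences$id
           else sprintf("seq%d", seq_len(nrow(sequences)))
    sequences <- setNames(sequences[[sc]], ids)
  }
  if (length(sequences) < 2) abort("need at least 2 sequences")
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  }
  codes <- lapply(toupper(sequences), encode_seq)
  if (any(vapply(codes, function(x) any(x == 0L), logical(1)))) {
    abort("sequences must be over the ACGT alphabet for discovery")
  }
  ## 0-order background from the input (both strands when modelled)
  cnt <- tabulate(unlist(codes), nbins = 4)
  if (config$both_strands) cnt <- cnt + rev(cnt)
  bg <- cnt / sum(cnt)
  widths <- if (length(config$width) == 2) {
    seq(config$width[1], config$width[2])
  } else config$width

  withr::local_seed(config$seed)
  fits <- lapply(widths, function(W) fit_width(codes, W, config, bg))
  n <- length(codes)
  bic <- vapply(seq_along(widths), function(k) {
    -2 * fits[[k]]$ll + (3 * widths[k] + 1) * log(n)
  }, numeric(1))
  k <- which.min(bic)
  best <- fits[[k]]
  q <- best$sites$posterior
  res <- structure(
    list(
      pwm = pwm(best$theta, background = bg,
                n_sites = as.integer(round(sum(q))), name = "motif1"),
      loglik = best$ll,
      ll_trace = best$trace,
      gamma = best$gamma,
      sites = best$sites,
      width = widths[k],
      width_table = tibble(width = widths,
                           loglik = vapply(fits, `[[`, numeric(1), "ll"),
                           bic = bic, selected = seq_along(widths) == k),
      config = config
    ),
    class = "motif_fit"
  )
  res
}

#' @export
print.motif_fit <- function(x, ...) {
  cat(sprintf(
    "<motif_fit> width=%d  logLik=%.2f  gamma=%.3f  IC=%.2f bits\n",
    x$width, x$loglik, x$gamma, pwm_information_content(x$pwm)))
  cat("consensus:", pwm_consensus(x$pwm), "\n")
  invisible(x)
}

#' @rdname pwm-tidiers
#' @export
tidy.motif_fit <- function(x, ...) tidy(x$pwm)

#' @rdname pwm-tidiers
#' @export
glance.motif_fit <- function(x, ...) {
  tibble(width = x$width, loglik = x$loglik, gamma = x$gamma,
         information_content = pwm_information_content(x$pwm),
         n_sites = x$pwm$n_sites, n_iter = length(x$ll_trace))
}
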