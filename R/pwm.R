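#' Position weight matrices
#'
#' Constructs a PWM object: a 4 x W column-stochastic probability matrix
#' (rows A, C, G, T) with a 0-order background distribution.
#'
#' @param mat Numeric 4 x W matrix of per-column base probabilities; rows
#'   in order A, C, G, T. Each column must sum to 1.
#' @param background Length-4 background base distribution (default
#'   uniform).
#' @param n_sites Number of sites that contributed to the matrix (metadata).
#' @param name Motif name.
#' @return A `pwm` object.
#' @export
pwm <- function(mat, background = rep(0.25, 4), n_sites = NA_integer_,
                name = "motif") {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) abort("PWM matrix must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 4) abort("PWM width must be at least 4")
  if (any(mat < 0) || any(abs(colSums(mat) - 1) > 1e-9)) {
    abort("PWM columns must be non-negative and sum to 1")
  }
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9) {
    abort("background must be a length-4 distribution summing to 1")
  }
  rownames(mat) <- .BASES
  structure(
    list(mat = mat, background = as.numeric(background),
         n_sites = n_sites, name = name),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s  width=%d  IC=%.2f bits  n_sites=%s\n",
              x$name, ncol(x$mat), pwm_information_content(x),
              format(x$n_sites)))
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' PWM width
#' @param x A `pwm`.
#' @return Integer width in nt.
#' @export
pwm_width <- function(x) ncol(x$mat)

#' Consensus sequence of a PWM (most probable base per column)
#' @param x A `pwm`.
#' @return Character string of length `pwm_width(x)`.
#' @export
pwm_consensus <- function(x) {
  paste(.BASES[apply(x$mat, 2, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param x A `pwm`.
#' @return A `pwm` describing the motif on the opposite strand.
#' @export
pwm_revcomp <- function(x) {
  pwm(x$mat[4:1, ncol(x$mat):1, drop = FALSE],
      background = x$background[c(4, 3, 2, 1)],
      n_sites = x$n_sites, name = paste0(x$name, "_rc"))
}

#' Information content of a PWM
#'
#' Total relative entropy of the motif against its background,
#' \deqn{\sum_w \sum_b p_{w,b} \log_2 (p_{w,b} / q_b),}
#' with the convention \eqn{0 \log 0 = 0}.
#'
#' @param x A `pwm`.
#' @return Information content in bits.
#' @export
#' @examples
#' unif <- pwm(matrix(0.25, 4, 6))
#' pwm_information_content(unif)  # 0 bits
pwm_information_content <- function(x) {
  p <- x$mat
  q <- x$background
  terms <- p * log2(p / q)
  terms[p == 0] <- 0
  sum(terms)
}

#' @rdname pwm-tidiers
#' @export
tidy.pwm <- function(x, ...) {
  tidyr::expand_grid(position = seq_len(ncol(x$mat)), base = .BASES) |>
    mutate(prob = as.vector(x$mat[cbind(match(.data$base, .BASES),
                                        .data$position)]))
}

#' Tidiers for PWMs
#'
#' `tidy()` returns one row per (position, base) with the probability;
#' `glance()` a one-row summary (width, information content, sites).
#'
#' @param x A `pwm`.
#' @param ... Unused.
#' @return A tibble.
#' @name pwm-tidiers
#' @export
glance.pwm <- function(x, ...) {
  tibble(name = x$name, width = ncol(x$mat),
         information_content = pwm_information_content(x),
         n_sites = x$n_sites)
}

#' Write a motif in MEME minimal text format
#'
#' @param x A `pwm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", .BASES, x$background), collapse = " "), "",
    sprintf("MOTIF %s", x$name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            ncol(x$mat), ifelse(is.na(x$n_sites), 20L, x$n_sites))
  ), con)
  writeLines(apply(x$mat, 2, function(col)
    paste(sprintf("%.6f", col), collapse = "  ")), con)
  close(con)
  on.exit()
  invisible(path)
}

#' Read a motif from MEME minimal text format
#'
#' Reads the first motif in the file.
#'
#' @param path Path to a MEME minimal format motif file.
#' @return A `pwm`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  i_bg <- grep("^Background letter frequencies", lines)
  if (length(i_bg) > 0) {
    tok <- strsplit(trimws(lines[i_bg[1] + 1]), "\\s+")[[1]]
    bg <- as.numeric(tok[seq(2, 8, by = 2)])
  }
  i_m <- grep("^MOTIF", lines)[1]
  if (is.na(i_m)) abort("no MOTIF record found")
  name <- strsplit(trimws(lines[i_m]), "\\s+")[[1]][2]
  i_h <- grep("^letter-probability matrix", lines)
  i_h <- i_h[i_h > i_m][1]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[i_h]))
  ns <- if (grepl("nsites=", lines[i_h])) {
    as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", lines[i_h]))
  } else NA_integer_
  rows <- lines[(i_h + 1):(i_h + w)]
  mat <- t(vapply(rows, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
  ## renormalise against printf truncation
  m <- apply(t(mat), 2, function(col) col / sum(col))
  pwm(m, background = bg / sum(bg), n_sites = ns, name = name)
}
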