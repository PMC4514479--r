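#' Summarize differential-expression contrasts
#'
#' Bookkeeping arithmetic over per-gene direction calls: counts of up- and
#' downregulated genes, one-decimal percentages of expressed genes
#' (rounded half away from zero), the up/down ratio to one decimal, and
#' pairwise gene-id overlaps between contrasts per direction.
#'
#' @param contrasts Named list of tibbles, one per contrast, each with
#'   columns `gene_id` and `direction` (`"up"`, `"down"` or
#'   `"unchanged"`); every expressed gene is one row.
#' @return A `de_summary`: list with `contrasts` (one row per contrast:
#'   `contrast`, `n_expressed`, `n_up`, `n_down`, `pct_up`, `pct_down`,
#'   `up_down_ratio`) and `overlaps` (one row per contrast pair and
#'   direction: `contrast_a`, `contrast_b`, `direction`, `overlap`).
#' @export
#' @examples
#' x <- tibble::tibble(
#'   gene_id = sprintf("g%d", 1:13326),
#'   direction = rep(c("up", "down", "unchanged"), c(1973, 1915, 9438))
#' )
#' summarize_de(list(phx_vs_sham = x))$contrasts
summarize_de <- function(contrasts) {
  if (is.data.frame(contrasts)) contrasts <- list(contrast1 = contrasts)
  if (is.null(names(contrasts))) {
    names(contrasts) <- sprintf("contrast%d", seq_along(contrasts))
  }
  per <- purrr::imap(contrasts, function(tb, nm) {
    stopifnot(all(c("gene_id", "direction") %in% names(tb)))
    if (anyDuplicated(tb$gene_id)) {
      abort(sprintf("duplicate gene ids in contrast '%s'", nm))
    }
    n <- nrow(tb)
    if (n == 0) abort(sprintf("contrast '%s' has no expressed genes", nm))
    n_up <- sum(tb$direction == "up")
    n_down <- sum(tb$direction == "down")
    tibble(
      contrast = nm, n_expressed = n, n_up = n_up, n_down = n_down,
      pct_up = round_half_up(100 * n_up / n, 1),
      pct_down = round_half_up(100 * n_down / n, 1),
      up_down_ratio = if (n_down > 0) round_half_up(n_up / n_down, 1)
                      else NA_real_
    )
  })
  overlaps <- NULL
  nms <- names(contrasts)
  if (length(contrasts) >= 2) {
    pairs <- utils::combn(nms, 2, simplify = FALSE)
    overlaps <- bind_rows(lapply(pairs, function(p) {
      a <- contrasts[[p[1]]]
      b <- contrasts[[p[2]]]
      bind_rows(lapply(c("up", "down"), function(d) {
        tibble(contrast_a = p[1], contrast_b = p[2], direction = d,
               overlap = length(intersect(a$gene_id[a$direction == d],
                                          b$gene_id[b$direction == d])))
      }))
    }))
  }
  structure(list(contrasts = bind_rows(per), overlaps = overlaps),
            class = "de_summary")
}

#' @export
print.de_summary <- function(x, ...) {
  cat("<de_summary>\n")
  print(x$contrasts)
  if (!is.null(x$overlaps)) print(x$overlaps)
  invisible(x)
}

#' @rdname tidy.enrichment_result
#' @export
tidy.de_summary <- function(x, ...) x$contrasts
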