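#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_text
#'   geom_boxplot geom_jitter geom_hline facet_wrap labs theme_minimal
NULL

#' Plot a PWM as an information-content logo
#'
#' Stacked bars per position, each base's share scaled by the column
#' information content, with base letters overlaid.
#'
#' @param object A `pwm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pwm <- function(object, ...) {
  df <- tidy(object) |>
    group_by(.data$position) |>
    mutate(
      col_ic = sum(ifelse(.data$prob > 0,
                          .data$prob * log2(.data$prob / 0.25), 0)),
      height = .data$prob * pmax(.data$col_ic, 0)
    ) |>
    arrange(.data$position, .data$height) |>
    mutate(ymax = cumsum(.data$height),
           ymid = .data$ymax - .data$height / 2) |>
    ungroup()
  ggplot(df, aes(x = .data$position, y = .data$height, fill = .data$base)) +
    geom_col(width = 0.9, colour = NA) +
    geom_text(aes(y = .data$ymid, label = .data$base),
              data = function(d) d[d$height > 0.15, ], size = 3,
              colour = "white") +
    labs(x = "motif position", y = "bits",
         title = sprintf("%s (%.1f bits)", object$name,
                         pwm_information_content(object))) +
    theme_minimal()
}

#' Plot an EScore track
#'
#' Per-position log2 EScore for one or more references, with the peak
#' threshold drawn as a horizontal line.
#'
#' @param object An `escore_track`.
#' @param refs Reference ids to show (default: first 4 with any defined
#'   position).
#' @param config A [peak_call_config()]; supplies the threshold line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.escore_track <- function(object, refs = NULL,
                                  config = peak_call_config(), ...) {
  if (is.null(refs)) {
    has <- names(object$values)[vapply(object$values,
                                       function(v) any(!is.na(v)), logical(1))]
    refs <- head(has, 4)
  }
  df <- tidy(object) |> filter(.data$ref %in% refs)
  ggplot(df, aes(x = .data$pos, y = .data$log2_escore)) +
    geom_line(na.rm = TRUE) +
    geom_hline(yintercept = config$log2_threshold, linetype = "dashed",
               colour = "red") +
    facet_wrap(~ref, scales = "free_x") +
    labs(x = "position (nt)", y = "log2 EScore") +
    theme_minimal()
}

#' Plot an enrichment result
#'
#' Box plots of log e-scores by DE class, the quantity the pairwise
#' t-tests compare; lower values mean stronger motif matches.
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot(object$values,
         aes(x = .data$group, y = .data$log_e, fill = .data$group)) +
    geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    labs(x = NULL, y = "log e-score") +
    theme_minimal()
}
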