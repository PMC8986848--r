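#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   labs scale_y_log10 facet_wrap theme_minimal geom_hline geom_errorbar
#'   position_dodge
#' @export
ggplot2::autoplot

#' Plot an SSCS pileup: coverage track and non-reference allele fractions
#'
#' @param object an `sscs_pileup`
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.sscs_pileup <- function(object, ...) {
  tb <- as_tibble(object)
  alt <- purrr::map(DNA_BASES, function(b) {
    cnt <- tb[[paste0(b, "_f")]] + tb[[paste0(b, "_r")]]
    keep <- tb$ref != b & cnt > 0 & tb$coverage > 0
    tibble(chrom = tb$chrom[keep], pos = tb$pos[keep],
           frac = cnt[keep] / tb$coverage[keep])
  }) |> bind_rows()
  cov <- select(tb, "chrom", "pos", "coverage")
  p1 <- ggplot(cov, aes(x = .data$pos + 1L, y = .data$coverage)) +
    geom_line(colour = "grey30") +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position", y = "SSCS coverage") +
    theme_minimal()
  if (nrow(alt) > 0L) {
    p1 <- p1 + geom_point(data = alt,
                          aes(x = .data$pos + 1L,
                              y = .data$frac * max(cov$coverage)),
                          colour = "firebrick", size = 0.8)
  }
  p1
}

#' Plot variant calls: VAF against position, coloured by filter verdict
#'
#' @param object a `variant_calls` object
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.variant_calls <- function(object, ...) {
  calls <- object$calls
  ggplot(calls, aes(x = .data$pos + 1L, y = .data$vaf,
                    colour = .data$filter)) +
    geom_point() +
    facet_wrap(~chrom, scales = "free_x") +
    scale_y_log10() +
    labs(x = "position", y = "VAF", colour = "filter") +
    theme_minimal()
}

#' Bar chart of error rates across processing levels
#'
#' @param reports tibble of [error_rate()] rows (one per level)
#' @return a ggplot object (log-scale y)
#' @export
plot_error_rates <- function(reports) {
  reports$level <- factor(reports$level, levels = c("raw", "sscs", "called"))
  ggplot(reports, aes(x = .data$level, y = .data$rate)) +
    geom_col(fill = "steelblue") +
    scale_y_log10() +
    labs(x = NULL, y = "substitution errors per base") +
    theme_minimal()
}

#' Dilution-series plot: measured against nominal VAF
#'
#' @param series tibble with columns `nominal_vaf`, `measured_vaf` and
#'   optionally `variant`
#' @return a ggplot object
#' @export
plot_dilution_series <- function(series) {
  p <- ggplot(series, aes(x = factor(.data$nominal_vaf * 100),
                          y = .data$measured_vaf * 100))
  if ("variant" %in% names(series)) {
    p <- p + geom_point(aes(colour = .data$variant),
                        position = position_dodge(width = 0.4))
  } else {
    p <- p + geom_point()
  }
  p + scale_y_log10() +
    labs(x = "nominal VAF (%)", y = "measured VAF (%)") +
    theme_minimal()
}
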