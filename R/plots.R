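#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_histogram
#'   geom_bar labs scale_x_log10 theme_minimal
#' @export
ggplot2::autoplot

#' Plot per-cloud quality (size vs purity)
#'
#' Scatter of cloud size against purity, the standard view of how
#' deconvolution trades cloud size for single-origin composition.
#'
#' @param object A [cloud_quality()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cloud_quality <- function(object, ...) {
  ggplot(object, aes(x = .data$size, y = .data$purity,
                     colour = .data$class)) +
    geom_point(alpha = 0.4) +
    scale_x_log10() +
    labs(x = "cloud size (reads)", y = "purity P",
         colour = "class") +
    theme_minimal()
}

#' Plot a deconvolution result
#'
#' Histogram of the number of enhanced clouds each processed read
#' cloud was split into.
#'
#' @param object A `deconv_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deconv_result <- function(object, ...) {
  ggplot(object$clouds, aes(x = .data$n_subgroups)) +
    geom_bar() +
    labs(x = "enhanced clouds per original cloud", y = "clouds") +
    theme_minimal()
}

#' Plot a simulated library
#'
#' Fragment length distribution of the simulated library's truth
#' table.
#'
#' @param object A `sim_library`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sim_library <- function(object, ...) {
  frags <- object$truth %>%
    distinct(.data$fragment_id, .data$frag_start, .data$frag_end)
  ggplot(frags, aes(x = .data$frag_end - .data$frag_start)) +
    geom_histogram(bins = 30) +
    labs(x = "fragment length (bp)", y = "fragments") +
    theme_minimal()
}
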