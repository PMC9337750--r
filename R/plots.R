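# Plot helpers (ggplot2, suggested dependency).

#' Energy-density scatter of a landscape
#'
#' The classic CSP landscape view: one point per unique predicted structure,
#' lattice energy against density.
#'
#' @param landscape a `ccs_landscape`.
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_landscape needs the ggplot2 package")
  df <- as.data.frame(landscape)
  ggplot2::ggplot(df, ggplot2::aes(x = density, y = U_total)) +
    ggplot2::geom_point(ggplot2::aes(colour = spacegroup)) +
    ggplot2::labs(x = expression(density ~ (g ~ cm^-3)),
                  y = expression(U[total] ~ (kJ ~ mol^-1)),
                  title = landscape$composition) +
    ggplot2::theme_minimal()
}

#' Ranked bar chart of a coformer screen
#'
#' @param report a `ccs_screenreport`.
#' @return A ggplot object with one bar per coformer, observed cocrystal
#'   formers highlighted, and the classification threshold marked.
#' @export
plot_screen <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_screen needs the ggplot2 package")
  df <- report$entries
  df$coformer <- factor(df$coformer, levels = df$coformer[order(df$rank)])
  ggplot2::ggplot(df, ggplot2::aes(x = coformer, y = ddU, fill = observed)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = report$threshold, linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(Delta * Delta * U ~ (kJ ~ mol^-1)),
                  title = paste("Coformer screen:", report$api)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
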