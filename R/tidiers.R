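#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.mode_set <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$values), eigenvalue = x$values,
                 frequency = sqrt(x$values))
}

#' @export
glance.mode_set <- function(x, ...) {
  tibble::tibble(n_modes = length(x$values), n_zero = x$n_zero,
                 n_nodes = x$n_nodes,
                 lambda_min = if (length(x$values)) min(x$values) else NA_real_,
                 lambda_max = if (length(x$values)) max(x$values) else NA_real_)
}

#' @export
tidy.overlap_matrix <- function(x, ...) {
  m <- unclass(x)
  out <- tibble::tibble(
    component_mode = rep(seq_len(nrow(m)), times = ncol(m)),
    assembly_mode = rep(seq_len(ncol(m)), each = nrow(m)),
    overlap = as.vector(m))
  out
}

#' @export
tidy.slope_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "assembly_mode"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.slope_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, abs_slope = x$abs_slope,
                 intercept = x$intercept, n_points = x$n_points,
                 threshold = x$threshold)
}

#' Heat-map display of an overlap matrix
#'
#' Renders the matrix in the conventional orientation: component modes on
#' an inverted y axis (mode 1 at the top), assembly modes on x, so a
#' conserved spectrum reads as the main diagonal.
#'
#' @param object An `overlap_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_matrix <- function(object, ...) {
  df <- tidy.overlap_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$assembly_mode,
                                   y = .data$component_mode,
                                   fill = .data$overlap)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "assembly mode", y = "component mode",
                  fill = "overlap") +
    ggplot2::theme_minimal()
}

#' Cumulative-overlap curve with per-mode overlap bars
#'
#' @param object A `co_curve` tibble from [overlap_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.co_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mode)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$overlap), fill = "darkgreen",
                      width = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$co), colour = "red",
                       linewidth = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$co), colour = "red") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "mode", y = "overlap / cumulative overlap") +
    ggplot2::theme_minimal()
}

#' Per-residue communication-occurrence profile plot
#'
#' @param object An `occurrence_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.occurrence_profile <- function(object, ...) {
  df <- dplyr::mutate(object, index = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$occurrence)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "occurrence in pathways (%)") +
    ggplot2::theme_minimal()
}

#' Signed inter-residue distance-variation map
#'
#' Blue entries are residue pairs moving closer along the mode, red pairs
#' moving apart; zero blocks flag rigid-body motion of a subunit.
#'
#' @param object A `distvar_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distvar_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tibble::tibble(i = rep(seq_len(nrow(m)), times = ncol(m)),
                       j = rep(seq_len(ncol(m)), each = nrow(m)),
                       dvar = as.vector(m))
  lim <- max(abs(df$dvar))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$dvar)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-lim, lim)) +
    ggplot2::labs(x = "residue", y = "residue", fill = "d|Rij|") +
    ggplot2::theme_minimal()
}

#' Mobility profile plot with hinge markers
#'
#' @param profile Tibble from [ms_fluctuations()].
#' @param hinges Optional tibble from [find_hinges()].
#' @return A ggplot object.
#' @export
plot_mobility <- function(profile, hinges = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$residue,
                                             y = .data$msf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "mean-square fluctuation") +
    ggplot2::theme_minimal()
  if (!is.null(hinges) && nrow(hinges) > 0) {
    p <- p + ggplot2::geom_point(data = hinges,
                                 ggplot2::aes(x = .data$residue,
                                              y = .data$value),
                                 shape = 17, colour = "black", size = 2)
  }
  p
}
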