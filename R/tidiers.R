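#' Tidy an ICC result
#'
#' @param x A `pat_icc`.
#' @param ... Unused.
#' @return A one-row tibble: `icc`, `form`, `n_subjects`, `n_raters`,
#'   `f_statistic`, `p_value`.
#' @export
tidy.pat_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, form = x$form, n_subjects = x$n_subjects,
                 n_raters = x$n_raters, f_statistic = x$f_statistic,
                 p_value = x$p_value)
}

#' @rdname tidy.pat_icc
#' @return `glance` adds the ANOVA mean squares (`ms_rows`, `ms_cols`,
#'   `ms_error`).
#' @export
glance.pat_icc <- function(x, ...) {
  dplyr::bind_cols(tidy(x),
                   tibble::tibble(ms_rows = x$ms_rows, ms_cols = x$ms_cols,
                                  ms_error = x$ms_error))
}

#' Tidy a Bland-Altman result
#'
#' @param x A `pat_bland_altman`.
#' @param ... Unused.
#' @return A one-row tibble: `bias`, `sd_diff`, `k`, `loa_lower`,
#'   `loa_upper`, `half_width`, `n`.
#' @export
tidy.pat_bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff, k = x$k,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 half_width = x$half_width, n = x$n)
}

#' Bland-Altman plot
#'
#' Scatter of paired differences against paired means with the bias and the
#' limits of agreement drawn as horizontal lines.
#'
#' @param object A `pat_bland_altman`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pat_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = 2) +
    ggplot2::labs(x = "Mean of methods", y = "Difference (second - first)",
                  title = sprintf("Bland-Altman: bias %.2f, LoA [%.2f, %.2f]",
                                  object$bias, object$loa_lower,
                                  object$loa_upper)) +
    ggplot2::theme_minimal()
}

#' Faceted Bland-Altman plot for an agreement report
#'
#' One Bland-Altman panel per quantity, built from the original paired
#' table.
#'
#' @param object A `pat_paired_table`.
#' @param k Limits-of-agreement multiplier (default 2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pat_paired_table <- function(object, k = 2, ...) {
  methods <- attr(object, "methods")
  df <- dplyr::mutate(tibble::as_tibble(object),
                      mean = (.data[[methods[1]]] + .data[[methods[2]]]) / 2,
                      diff = .data[[methods[2]]] - .data[[methods[1]]])
  lines <- dplyr::summarise(
    dplyr::group_by(df, .data$quantity),
    bias = mean(.data$diff),
    lo = mean(.data$diff) - k * stats::sd(.data$diff),
    hi = mean(.data$diff) + k * stats::sd(.data$diff), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = lines, ggplot2::aes(yintercept = .data$bias)) +
    ggplot2::geom_hline(data = lines, ggplot2::aes(yintercept = .data$lo),
                        linetype = 2) +
    ggplot2::geom_hline(data = lines, ggplot2::aes(yintercept = .data$hi),
                        linetype = 2) +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = sprintf("Mean of %s and %s (g)", methods[1], methods[2]),
                  y = sprintf("%s - %s (g)", methods[2], methods[1])) +
    ggplot2::theme_minimal()
}

#' Plot one slice of a stack with an optional mask overlay
#'
#' @param stack A `pat_image_stack`.
#' @param i 0-based slice index.
#' @param mask Optional binary `pat_image_stack` aligned to `stack`.
#' @return A ggplot raster of the slice, mask pixels overlaid in red.
#' @export
plot_slice <- function(stack, i, mask = NULL) {
  sl <- get_slice(stack, i)
  df <- tidyr::expand_grid(col = 0:(ncol(sl) - 1), row = 0:(nrow(sl) - 1))
  df$intensity <- as.vector(sl)  # column-major: row varies fastest
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    mdf <- df[as.vector(get_slice(mask, i)) == 1, ]
    if (nrow(mdf))
      p <- p + ggplot2::geom_raster(data = mdf, fill = "red", alpha = 0.5)
  }
  p
}
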