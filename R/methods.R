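#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the Pareto front of a clustering fit
#'
#' @param x An `mscc_fit`.
#' @param ... Unused.
#' @return One row per front member: `solution`, `xb`, `jp`, `si`
#'   (`NA` when the member's crisp labelling collapses to one cluster),
#'   `n_selected`, and whether the member is the silhouette-selected final
#'   solution.
#' @export
tidy.mscc_fit <- function(x, ...) {
  si <- vapply(seq_along(x$front), function(i) {
    labels <- crisp_assignment(x$front[[i]]$U)
    if (length(unique(labels)) < 2L) return(NA_real_)
    silhouette_index(x$expr, labels)
  }, numeric(1))
  tibble::tibble(
    solution = seq_along(x$front),
    xb = vapply(x$front, function(s) s$fitness[[1]], numeric(1)),
    jp = vapply(x$front, function(s) s$fitness[[2]], numeric(1)),
    si = si,
    n_selected = lengths(lapply(x$front, `[[`, "sel")),
    selected = seq_along(x$front) == (x$best$index %||% -1L)
  )
}

#' One-row summary of a clustering fit
#'
#' @param x An `mscc_fit`.
#' @param ... Unused.
#' @return Tibble with `n`, `k`, `s`, `n_front`, `si`, `xb`, `jp` of the
#'   selected solution.
#' @export
glance.mscc_fit <- function(x, ...) {
  best <- x$best
  tibble::tibble(
    n = nrow(x$expr), k = x$config$k, s = x$config$s,
    n_front = length(x$front),
    si = best$si %||% NA_real_,
    xb = if (is.null(best)) NA_real_ else best$fitness[[1]],
    jp = if (is.null(best)) NA_real_ else best$fitness[[2]]
  )
}

#' Plot the Pareto front of a clustering fit
#'
#' Scatter of the two objectives over the final front, colored by
#' silhouette index, with the selected solution circled.
#'
#' @param object An `mscc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mscc_fit <- function(object, ...) {
  tb <- tidy(object)
  tb <- tb[is.finite(tb$xb) & is.finite(tb$jp), ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$xb, y = .data$jp)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$si), size = 2.5) +
    ggplot2::geom_point(data = tb[tb$selected, ], shape = 1, size = 5,
                        stroke = 1) +
    ggplot2::scale_color_viridis_c(name = "silhouette") +
    ggplot2::labs(x = "Xie-Beni index", y = "penalized fuzzy objective",
                  title = "Pareto front") +
    ggplot2::theme_minimal()
}

#' Plot per-gene silhouette widths grouped by cluster
#'
#' @param widths Tibble from [silhouette_widths()].
#' @return A ggplot.
#' @export
plot_silhouette <- function(widths) {
  tb <- dplyr::arrange(widths, .data$label, dplyr::desc(.data$width))
  tb$pos <- seq_len(nrow(tb))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$pos, y = .data$width,
                                   fill = factor(.data$label))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = attr(widths, "si"), linetype = 2) +
    ggplot2::labs(x = NULL, y = "silhouette width", fill = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @importFrom rlang .data %||%
NULL
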