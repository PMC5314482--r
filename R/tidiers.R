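#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a repository into a tibble of items
#'
#' @param x A repository handle.
#' @param include_hidden Include hidden items? Default `TRUE` (a tidy view
#'   should see everything).
#' @param ... Unused.
#' @return The same tibble as [repo_list()].
#' @method tidy repo
#' @export
tidy.repo <- function(x, include_hidden = TRUE, ...) {
  repo_list(x, include_hidden = include_hidden)
}

#' One-row summary of a repository
#'
#' @param x A repository handle.
#' @param ... Unused.
#' @return A tibble with `root`, `n_items`, `n_hidden`, `total_bytes`.
#' @method glance repo
#' @export
glance.repo <- function(x, ...) {
  hidden <- vapply(x$items, rec_has_flag, TRUE, "hidden")
  tibble::tibble(
    root = x$root,
    n_items = length(x$items),
    n_hidden = sum(hidden),
    total_bytes = sum(vapply(x$items, `[[`, 0, "size_bytes"))
  )
}

#' Pie chart of per-item disk usage
#'
#' The classic disk-usage pie: one slice per item, area proportional to the
#' payload's share of the repository's total size.
#'
#' @param object A tibble from [repo_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot repo_stats
#' @export
autoplot.repo_stats <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = "", y = .data$fraction, fill = .data$name)) +
    ggplot2::geom_col(width = 1, color = "white") +
    ggplot2::coord_polar("y") +
    ggplot2::labs(fill = "item", x = NULL, y = NULL,
                  title = "Repository disk usage") +
    ggplot2::theme_void()
}

#' @rdname autoplot.repo_stats
#' @param x A tibble from [repo_stats()].
#' @param y Unused.
#' @export
plot.repo_stats <- function(x, y, ...) {
  print(autoplot.repo_stats(x, ...))
  invisible(x)
}
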