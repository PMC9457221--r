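#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a control-ratio sweep
#'
#' Returns the per-point results as a plain tibble (one row per grid value of
#' the swept parameter), stripped of the sweep class and attributes.
#'
#' @param x a `cora_sweep` or `cora_grid`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.cora_sweep <- function(x, ...) {
  tibble::as_tibble(unclass_sweep(x))
}

#' @rdname tidy.cora_sweep
#' @export
tidy.cora_grid <- tidy.cora_sweep

unclass_sweep <- function(x) {
  class(x) <- setdiff(class(x), c("cora_sweep", "cora_grid"))
  attr(x, "spec") <- NULL
  attr(x, "second_param") <- NULL
  x
}

#' Glance at a control-ratio sweep
#'
#' One-row summary of a sweep (see [summarize_sweep()]); for a grid, one row
#' per value of the second parameter.
#'
#' @param x a `cora_sweep` or `cora_grid`.
#' @param ... unused.
#' @return a tibble with columns `n_points`, `n_ok`, `frac_ok`, `min_cora`,
#'   `max_cora`, `max_jump`, `transition` (grids gain a leading
#'   `second_value`).
#' @export
glance.cora_sweep <- function(x, ...) summarize_sweep(x)

#' @rdname glance.cora_sweep
#' @export
glance.cora_grid <- function(x, ...) {
  dat <- tidy.cora_sweep(x)
  dplyr::group_modify(dplyr::group_by(dat, .data$second_value),
                      ~ summarize_sweep(.x)) |>
    dplyr::ungroup()
}

#' Plot a control-ratio sweep
#'
#' Control ratio against the swept parameter (log axis); points that failed
#' (`status != "ok"`) are dropped from the line and shown in the subtitle
#' count. For grids, one curve per second-parameter value.
#'
#' @param object a `cora_sweep` or `cora_grid`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cora_sweep <- function(object, ...) {
  spec <- attr(object, "spec")
  dat <- dplyr::filter(tidy.cora_sweep(object), .data$status == "ok")
  n_bad <- nrow(object) - nrow(dat)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$theta_value, y = .data$cora)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::geom_point(size = 0.9, color = "#2166ac") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = spec$sweep,
      y = sprintf("CoRa(%s)", spec$perturb),
      title = sprintf("%s: control ratio under %s perturbation", spec$model, spec$perturb),
      subtitle = if (n_bad > 0) sprintf("%d point(s) without a valid steady-state comparison omitted", n_bad) else NULL
    ) +
    ggplot2::coord_cartesian(ylim = c(min(0, dat$cora), max(1, dat$cora))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cora_sweep
#' @export
autoplot.cora_grid <- function(object, ...) {
  spec <- attr(object, "spec")
  second <- attr(object, "second_param")
  dat <- dplyr::filter(tidy.cora_sweep(object), .data$status == "ok")
  dat$curve <- factor(signif(dat$second_value, 4))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$theta_value, y = .data$cora,
                                    color = .data$curve, group = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = spec$sweep, y = sprintf("CoRa(%s)", spec$perturb),
                  color = second,
                  title = sprintf("%s: control ratio as %s varies", spec$model, second)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cora_sweep
#' @param x a `cora_sweep` or `cora_grid`.
#' @param y unused.
#' @export
plot.cora_sweep <- function(x, y, ...) print(autoplot.cora_sweep(x, ...))

#' @rdname autoplot.cora_sweep
#' @export
plot.cora_grid <- function(x, y, ...) print(autoplot.cora_grid(x, ...))

#' @importFrom rlang .data
NULL
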