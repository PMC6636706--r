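# ggplot2 visualisations and broom-style summaries of result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_tile
#'   facet_wrap labs scale_x_log10
#' @importFrom generics tidy glance
NULL

#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Plot a spine trajectory
#'
#' Faceted time-series panels of the requested channels.
#'
#' @param object a `spine_trajectory`.
#' @param vars channel names to display.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spine_trajectory <- function(object,
                                      vars = c("ca", "ip3", "u", "acam"),
                                      ...) {
  vars <- intersect(vars, names(object))
  long <- tidyr::pivot_longer(
    object[, c("time", vars)], -"time",
    names_to = "channel", values_to = "value"
  )
  long$channel <- factor(long$channel, levels = vars)
  ggplot(long, aes(x = .data$time, y = .data$value)) +
    geom_line() +
    facet_wrap(~channel, scales = "free_y", ncol = 1) +
    labs(x = "time (s)", y = NULL)
}

#' Plot a plasticity induction curve
#'
#' @param object a `spine_plasticity_curve`.
#' @param ... further curves to overlay.
#' @return A ggplot object.
#' @export
autoplot.spine_plasticity_curve <- function(object, ...) {
  extra <- list(...)
  curves <- c(list(object), Filter(function(z) inherits(z, "spine_plasticity_curve"), extra))
  df <- dplyr::bind_rows(lapply(curves, function(cv) {
    tibble::tibble(x = cv$x, dw = cv$dw, spine = if (cv$er[1]) "ER+" else "ER-")
  }))
  xlab <- if (identical(attr(object, "family"), "stdp")) {
    "spike timing difference (ms)"
  } else "input rate (Hz)"
  ggplot(df, aes(x = .data$x, y = .data$dw, colour = .data$spine)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_line() +
    labs(x = xlab, y = "weight change Δw", colour = NULL)
}

#' Plot a steady-state open-probability map
#'
#' @param object a `spine_popen_map`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spine_popen_map <- function(object, ...) {
  ggplot(object, aes(x = .data$ca, y = factor(.data$glu), fill = .data$popen)) +
    geom_tile() +
    scale_x_log10() +
    labs(x = "clamped Ca (uM)", y = "clamped glutamate (uM)", fill = "P_open")
}

#' @export
tidy.spine_plasticity_curve <- function(x, ...) {
  out <- x[, c("x", "dw", "er")]
  class(out) <- class(tibble::tibble())
  out
}

#' @export
glance.spine_plasticity_curve <- function(x, ...) {
  w <- window_widths(x$x, x$dw)
  tibble::tibble(
    family = attr(x, "family") %||% "rate",
    er = x$er[1],
    n = nrow(x),
    dw_min = min(x$dw), dw_max = max(x$dw),
    ltd_width = w[["ltd"]], ltp_width = w[["ltp"]]
  )
}

#' @export
tidy.spine_rest <- function(x, ...) {
  tibble::tibble(state = names(x$state), value = as.numeric(x$state))
}

#' @export
glance.spine_rest <- function(x, ...) {
  tibble::tibble(
    ca_nM = x$state[["ca"]] * 1000,
    ip3_uM = x$state[["ip3"]],
    h = x$state[["h"]],
    nu_ip3 = x$nu_ip3,
    k_S_eff = x$k_S_eff,
    residual = x$residual
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
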