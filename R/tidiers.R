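#' Tidy the state table of an assembled system
#'
#' @param x A `bg_ode`.
#' @param ... Unused.
#' @return A tibble with one row per state: `id`, `kind` (`q` stored volume,
#'   `v` stored flow), `component` and `param`.
#' @method tidy bg_ode
#' @export
tidy.bg_ode <- function(x, ...) x$states

#' One-row summary of an assembled system
#'
#' @param x A `bg_ode`.
#' @param ... Unused.
#' @method glance bg_ode
#' @export
glance.bg_ode <- function(x, ...) {
  tibble::tibble(
    module = x$module$name,
    n_states = nrow(x$states),
    n_inputs = nrow(x$inputs),
    n_junctions = nrow(x$module$junctions),
    n_bonds = nrow(x$module$bonds),
    n_unbound_ports = sum(is.na(x$module$ports$binding))
  )
}

#' Tidy a module's element inventory
#'
#' @param x A `bg_module`.
#' @param ... Unused.
#' @return A long tibble with columns `element` (component/junction/bond/
#'   port), `id` and `kind`.
#' @method tidy bg_module
#' @export
tidy.bg_module <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(element = "component", id = x$components$id,
                   kind = x$components$kind),
    tibble::tibble(element = "junction", id = x$junctions$id,
                   kind = x$junctions$kind),
    tibble::tibble(element = "bond", id = x$bonds$id, kind = "bond"),
    tibble::tibble(element = "port", id = x$ports$id, kind = x$ports$kind)
  )
}

#' @method glance bg_module
#' @export
glance.bg_module <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    n_components = nrow(x$components),
    n_junctions = nrow(x$junctions),
    n_bonds = nrow(x$bonds),
    n_ports = nrow(x$ports),
    n_unbound_ports = sum(is.na(x$ports$binding)),
    n_annotations = nrow(x$annotations)
  )
}

#' Pivot simulation traces to long format
#'
#' @param x A `bg_sim`.
#' @param variables Trace names to keep (default all).
#' @param ... Unused.
#' @return A tibble with columns `time`, `variable`, `value`.
#' @method tidy bg_sim
#' @export
tidy.bg_sim <- function(x, variables = NULL, ...) {
  keep <- c("time", variables %||% setdiff(names(x), "time"))
  tidyr::pivot_longer(tibble::as_tibble(x[keep]), -"time",
                      names_to = "variable", values_to = "value")
}

#' Plot simulation traces
#'
#' Line plot of selected traces against time, faceted by variable (free y
#' scales, since pressures and flows live on different scales).
#'
#' @param object A `bg_sim`.
#' @param variables Trace names to plot; default: the junction potentials.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bg_sim
#' @export
autoplot.bg_sim <- function(object, variables = NULL, ...) {
  if (is.null(variables)) {
    variables <- grep("\\.u$", attr(object, "var_names"), value = TRUE)
    variables <- head(variables[variables %in% names(object)], 6)
  }
  dat <- tidy.bg_sim(object, variables)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Plot an NRMSE comparison table
#'
#' @param object A `bg_comparison` from [compare_runs()].
#' @param ... Unused.
#' @return A ggplot bar chart of per-variable NRMSE (percent).
#' @method autoplot bg_comparison
#' @export
autoplot.bg_comparison <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = stats::reorder(.data$variable,
                                                  .data$nrmse_percent),
                               y = .data$nrmse_percent)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "NRMSE (%)")
}
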