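#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_raster
#'   scale_fill_viridis_c labs theme_minimal coord_equal
#' @export
ggplot2::autoplot

#' Heatmap of an index over the (p, r) parameter plane
#'
#' Averages the chosen index per `(update_p, rebel_r)` cell (the paper's
#' colour-map view of a sweep) and draws it as a tile map.
#'
#' @param records A sweep tibble from [run_sweep()].
#' @param index Index column to display.
#' @return A ggplot object.
#' @export
plot_index_heatmap <- function(records, index = "cooperation_degree") {
  agg <- aggregate_indices(records, index, by = c("update_p", "rebel_r"))
  ggplot(agg, aes(x = .data$update_p, y = .data$rebel_r,
                  fill = .data$mean_value)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1), name = index) +
    labs(x = "updating probability p", y = "rebel ratio r") +
    theme_minimal()
}

#' @export
autoplot.fashion_sweep <- function(object, index = "cooperation_degree", ...) {
  plot_index_heatmap(object, index)
}

#' Index trajectories of a single run
#'
#' Requires `record_series = TRUE` in [run_dynamics()].
#'
#' @param object A `fashion_run`.
#' @param ... Unused.
#' @export
autoplot.fashion_run <- function(object, ...) {
  if (is.null(object$index_series))
    abort("run was made without `record_series = TRUE`.")
  long <- tidyr::pivot_longer(object$index_series, -"step",
                              names_to = "index", values_to = "value")
  ggplot(long, aes(x = .data$step, y = .data$value,
                   colour = .data$index)) +
    geom_line() +
    labs(x = "step", y = "index value") +
    theme_minimal()
}

#' Raster view of a torus configuration
#'
#' Colour encodes the action; rebels can be faceted out via the returned
#' data if needed.
#'
#' @param object A `fashion_state` on a torus-layout network.
#' @param ... Unused.
#' @export
autoplot.fashion_state <- function(object, ...) {
  net <- object$network
  if (is.null(net$rows)) abort("state's network has no torus layout.")
  df <- tibble::tibble(
    row = (0:(net$n_agents - 1L)) %/% net$cols,
    col = (0:(net$n_agents - 1L)) %% net$cols,
    action = factor(object$actions),
    type = type_labels(object$types)
  )
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$action)) +
    geom_raster() +
    coord_equal() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}
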