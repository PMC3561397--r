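#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a game state into a per-agent tibble
#'
#' @param x A `fashion_state`.
#' @param ... Unused.
#' @return A tibble with one row per agent: `agent_id`, `type` (`"C"` /
#'   `"R"`), `action`, `degree`, `liked`, `satisfaction`, `satisfied`.
#' @export
tidy.fashion_state <- function(x, ...) {
  prof <- satisfaction_profile(x)
  tibble::tibble(
    agent_id = 0:(x$network$n_agents - 1L),
    type = type_labels(x$types),
    action = x$actions,
    degree = prof$degree,
    liked = prof$liked,
    satisfaction = prof$satisfaction,
    satisfied = prof$satisfied
  )
}

#' One-row summary of a game state
#'
#' @param x A `fashion_state`.
#' @param ... Unused.
#' @return A one-row tibble: agent counts plus the four indices.
#' @export
glance.fashion_state <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_agents = x$network$n_agents,
                   n_rebels = sum(x$types),
                   n_edges = nrow(x$network$edges)),
    compute_indices(x)
  )
}

#' Tidy a dynamics run into its index trajectory
#'
#' Requires the run to have been made with `record_series = TRUE`;
#' otherwise returns the single final-step row.
#'
#' @param x A `fashion_run`.
#' @param ... Unused.
#' @export
tidy.fashion_run <- function(x, ...) {
  if (!is.null(x$index_series)) return(x$index_series)
  dplyr::bind_cols(tibble::tibble(step = x$steps_run),
                   x$final_indices[, 1:3])
}

#' One-row summary of a dynamics run
#'
#' @param x A `fashion_run`.
#' @param ... Unused.
#' @export
glance.fashion_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(steps_run = x$steps_run,
                   reached_nash = x$reached_nash,
                   first_nash_step = x$first_nash_step),
    x$final_indices
  )
}
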