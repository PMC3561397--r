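# ---- Initialization ------------------------------------------------------

#' Random initial state
#'
#' Types are i.i.d. Bernoulli(`r`) rebels; actions are i.i.d. uniform on
#' {0, 1}; all draws independent across agents. Uses the current R random
#' stream unless `seed` is supplied.
#'
#' @param network A `fashion_network`.
#' @param r Rebel ratio in `[0, 1]`.
#' @param seed Optional integer seed (leaves the caller's RNG state alone).
#' @return A `fashion_state`.
#' @export
init_state <- function(network, r, seed = NULL) {
  stopifnot(inherits(network, "fashion_network"))
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 1)
    abort("`r` must be a probability in [0, 1].")
  n <- network$n_agents
  draw <- function() {
    types <- as.integer(stats::runif(n) < r)
    actions <- as.integer(stats::runif(n) < 0.5)
    make_state(network, types, actions)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# ---- One step ------------------------------------------------------------

#' One step of the stochastic best-response dynamic
#'
#' Satisfaction is evaluated for *all* agents against the input profile;
#' each unsatisfied agent then independently flips her action with
#' probability `p` (uniform draws taken in increasing agent-id order);
#' satisfied agents never flip; flips are applied simultaneously. A pure
#' Nash state is therefore a fixed point for every `p`.
#'
#' @param state A `fashion_state`.
#' @param p Updating probability in `(0, 1]`.
#' @return The next `fashion_state`.
#' @export
br_step <- function(state, p) {
  stopifnot(inherits(state, "fashion_state"))
  check_p(p)
  prof <- satisfaction_profile(state)
  unsat <- which(!prof$satisfied)
  actions <- state$actions
  if (length(unsat) > 0) {
    flip <- stats::runif(length(unsat)) < p
    actions[unsat[flip]] <- 1L - actions[unsat[flip]]
  }
  make_state(state$network, state$types, actions)
}

check_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    abort("`p` must be a probability in (0, 1].")
  invisible(p)
}

# ---- Full runs -----------------------------------------------------------

#' Run the best-response dynamic
#'
#' Iterates [br_step()] up to `max_steps` steps. With `stop_at_nash` the
#' run halts as soon as every agent is satisfied (the state is absorbing,
#' so the final indices are unaffected). `mode = "sequential"` instead
#' flips exactly one uniformly chosen unsatisfied agent per step — the
#' asynchronous limit of vanishing `p` (ignored for `p` in that mode).
#'
#' @param state Initial `fashion_state`.
#' @param p Updating probability in `(0, 1]`.
#' @param max_steps Step budget (>= 1).
#' @param seed Optional integer seed for the flip stream.
#' @param stop_at_nash Halt on reaching a pure Nash equilibrium.
#' @param record_series Record the index trajectory per step.
#' @param mode `"parallel"` (the model's dynamic) or `"sequential"`.
#' @return A `fashion_run` object: `final_state`, `steps_run`,
#'   `reached_nash`, `first_nash_step` (NA if never), `final_indices`
#'   (one-row tibble), and `index_series` (tibble, or NULL).
#' @examples
#' net <- make_torus_moore(10, 10)
#' st <- init_state(net, r = 0, seed = 1)
#' run <- run_dynamics(st, p = 0.5, max_steps = 500, seed = 2)
#' run$reached_nash
#' @export
run_dynamics <- function(state, p, max_steps = 500L, seed = NULL,
                         stop_at_nash = TRUE, record_series = FALSE,
                         mode = c("parallel", "sequential")) {
  stopifnot(inherits(state, "fashion_state"))
  mode <- match.arg(mode)
  if (mode == "parallel") check_p(p)
  max_steps <- as.integer(max_steps)
  if (is.na(max_steps) || max_steps < 1L) abort("`max_steps` must be >= 1.")
  net <- state$network
  go <- function() {
    run_dynamics_cpp(net$csr_ptr, net$csr_idx, state$types, state$actions,
                     p, max_steps, stop_at_nash, record_series,
                     mode == "sequential")
  }
  res <- if (is.null(seed)) go() else withr::with_seed(seed, go())
  final_state <- make_state(net, state$types, res$actions)
  series <- NULL
  if (record_series) {
    m <- res$series
    series <- tibble::tibble(
      step = 0:(nrow(m) - 1L),
      cooperation_degree = m[, 1],
      average_satisfaction = m[, 2],
      complete_ratio = m[, 3]
    )
  }
  structure(
    list(final_state = final_state,
         steps_run = res$steps_run,
         reached_nash = res$reached_nash,
         first_nash_step = res$first_nash_step,
         final_indices = compute_indices(final_state),
         index_series = series,
         params = list(p = p, max_steps = max_steps, seed = seed,
                       stop_at_nash = stop_at_nash, mode = mode)),
    class = "fashion_run"
  )
}

#' @export
print.fashion_run <- function(x, ...) {
  cat(sprintf(
    "<fashion_run> %d step(s); %s; cooperation %.3f, avg satisfaction %.3f\n",
    x$steps_run,
    if (x$reached_nash) sprintf("pure Nash at step %d", x$first_nash_step)
    else "no pure Nash reached",
    x$final_indices$cooperation_degree,
    x$final_indices$average_satisfaction))
  invisible(x)
}

# ---- Limit cycles of the deterministic dynamic --------------------------

#' Detect the limit cycle of the synchronous (p = 1) dynamic
#'
#' Iterates the deterministic synchronous best-response map, storing every
#' visited profile, and reports the first recurrence. For all-rebel
#' populations the period is always 1 or 2 regardless of network structure
#' (Cannings); period 1 means the cycle state is a pure Nash equilibrium.
#' Only the deterministic `p = 1` map is supported: for `p < 1` the
#' dynamic is stochastic and "period" is not well defined.
#'
#' @param state Initial `fashion_state`.
#' @param max_period Report a cycle only if its period is at most this.
#' @param max_steps Iteration budget for finding a recurrence.
#' @param p Must be 1; any other value errors.
#' @return A list with `period` (NA if none found), `entered_at` (step at
#'   which the recurring profile was first seen) and `states_in_cycle`
#'   (integer matrix, one profile per row).
#' @export
detect_limit_cycle <- function(state, max_period = 10L, max_steps = 5000L,
                               p = 1) {
  stopifnot(inherits(state, "fashion_state"))
  if (!identical(as.numeric(p), 1)) {
    abort("limit cycles are defined for the deterministic p = 1 dynamic only.")
  }
  if (max_period < 1L) abort("`max_period` must be >= 1.")
  net <- state$network
  seen <- new.env(hash = TRUE, parent = emptyenv())
  actions <- state$actions
  history <- vector("list", max_steps + 1L)
  for (step in 0:max_steps) {
    key <- paste(actions, collapse = "")
    prev <- get0(key, envir = seen)
    if (!is.null(prev)) {
      period <- step - prev
      if (period <= max_period) {
        cyc <- do.call(rbind, history[(prev + 1L):step])
        return(list(period = period, entered_at = prev,
                    states_in_cycle = cyc))
      }
      return(list(period = NA_integer_, entered_at = NA_integer_,
                  states_in_cycle = NULL))
    }
    assign(key, step, envir = seen)
    history[[step + 1L]] <- actions
    # deterministic synchronous step: all unsatisfied agents flip
    same <- same_counts_cpp(net$csr_ptr, net$csr_idx, actions)
    deg <- net$degrees
    liked <- ifelse(state$types == 0L, same, deg - same)
    unsat <- deg > 0L & 2L * liked < deg
    actions <- ifelse(unsat, 1L - actions, actions)
  }
  list(period = NA_integer_, entered_at = NA_integer_, states_in_cycle = NULL)
}
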