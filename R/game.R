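# ---- Game states ---------------------------------------------------------

#' Construct a game state
#'
#' A state couples a network with a per-agent type (conformist or rebel)
#' and a binary action. Conformists like neighbours playing the *same*
#' action; rebels like neighbours playing the *different* action.
#'
#' @param network A `fashion_network`.
#' @param types Per-agent types: a character vector of `"conformist"` /
#'   `"rebel"` (or `"C"` / `"R"`), or an integer/logical vector where 1 /
#'   `TRUE` means rebel.
#' @param actions Per-agent actions in `{0, 1}`.
#' @return An object of class `fashion_state`.
#' @examples
#' net <- make_torus_moore(3, 3)
#' st <- make_state(net, rep("conformist", 9), rep(0, 9))
#' compute_indices(st)
#' @export
make_state <- function(network, types, actions) {
  stopifnot(inherits(network, "fashion_network"))
  n <- network$n_agents
  if (is.character(types) || is.factor(types)) {
    types <- as.character(types)
    ok <- types %in% c("conformist", "rebel", "C", "R")
    if (!all(ok)) abort("`types` must be 'conformist'/'rebel' (or 'C'/'R').")
    types <- as.integer(types %in% c("rebel", "R"))
  } else {
    types <- as.integer(types)
    if (anyNA(types) || !all(types %in% c(0L, 1L)))
      abort("integer `types` must be 0 (conformist) or 1 (rebel).")
  }
  actions <- as.integer(actions)
  if (length(types) != n || length(actions) != n)
    abort("`types` and `actions` must have one entry per agent.")
  if (anyNA(actions) || !all(actions %in% c(0L, 1L)))
    abort("`actions` must be binary (0/1).")
  structure(list(network = network, types = types, actions = actions),
            class = "fashion_state")
}

#' @export
print.fashion_state <- function(x, ...) {
  idx <- compute_indices(x)
  cat(sprintf(
    "<fashion_state> %d agents (%d rebels), cooperation %.3f, avg satisfaction %.3f%s\n",
    x$network$n_agents, sum(x$types), idx$cooperation_degree,
    idx$average_satisfaction, if (idx$is_pure_nash) " [pure Nash]" else ""))
  invisible(x)
}

type_labels <- function(types) c("C", "R")[types + 1L]

# per-agent liked counts and satisfaction, vectorised via the C++ core
satisfaction_profile <- function(state) {
  net <- state$network
  same <- same_counts_cpp(net$csr_ptr, net$csr_idx, state$actions)
  deg <- net$degrees
  liked <- ifelse(state$types == 0L, same, deg - same)
  satisfaction <- ifelse(deg == 0L, 1, liked / deg)
  satisfied <- deg == 0L | 2L * liked >= deg
  list(same = same, liked = liked, degree = deg,
       satisfaction = satisfaction, satisfied = satisfied)
}

# ---- Per-agent quantities ------------------------------------------------

#' Satisfaction of a single agent
#'
#' The satisfaction degree of an agent is the fraction of her neighbours
#' she likes: same-action neighbours for a conformist, different-action
#' neighbours for a rebel. She is satisfied iff this is at least 1/2.
#' Degree-0 agents are defined completely satisfied.
#'
#' @param state A `fashion_state`.
#' @param i 0-based agent id.
#' @return A one-row tibble with `liked`, `degree`, `satisfaction`,
#'   `satisfied`.
#' @export
agent_satisfaction <- function(state, i) {
  stopifnot(inherits(state, "fashion_state"))
  n <- state$network$n_agents
  i <- as.integer(i)
  if (is.na(i) || i < 0L || i >= n) abort(sprintf("unknown agent id %s.", i))
  nb <- state$network$neighbors[[i + 1L]]
  deg <- length(nb)
  same <- sum(state$actions[nb + 1L] == state$actions[i + 1L])
  liked <- if (state$types[i + 1L] == 0L) same else deg - same
  tibble::tibble(
    liked = liked, degree = deg,
    satisfaction = if (deg == 0L) 1 else liked / deg,
    satisfied = deg == 0L || 2L * liked >= deg
  )
}

#' Utility of a single agent
#'
#' `utility = liked - hated = 2 * liked - degree`; an agent is satisfied
#' iff her utility is non-negative (equivalently satisfaction >= 1/2).
#' Degree-0 agents have utility 0.
#'
#' @inheritParams agent_satisfaction
#' @return Integer utility.
#' @export
utility <- function(state, i) {
  a <- agent_satisfaction(state, i)
  as.integer(2L * a$liked - a$degree)
}

# ---- Indices -------------------------------------------------------------

#' The four cooperation indices of a configuration
#'
#' * `cooperation_degree`: fraction of satisfied agents; equals 1 exactly
#'   when the configuration is a pure Nash equilibrium.
#' * `average_satisfaction`: mean of per-agent satisfaction degrees.
#' * `complete_ratio`: fraction of agents with satisfaction exactly 1.
#' * `is_pure_nash`: whether every agent is satisfied.
#'
#' @param state A `fashion_state`.
#' @return A one-row tibble.
#' @export
compute_indices <- function(state) {
  stopifnot(inherits(state, "fashion_state"))
  prof <- satisfaction_profile(state)
  tibble::tibble(
    cooperation_degree = mean(prof$satisfied),
    average_satisfaction = mean(prof$satisfaction),
    complete_ratio = mean(prof$degree == 0L | prof$liked == prof$degree),
    is_pure_nash = all(prof$satisfied)
  )
}

#' Expected indices of a uniform random initialization
#'
#' With actions i.i.d. uniform on {0, 1}, each neighbour independently
#' matches an agent's action with probability 1/2, so the chance that an
#' agent of degree d is initially satisfied is the binomial tail
#' P(Bin(d, 1/2) >= ceil(d/2)) — identical for conformists and rebels by
#' symmetry, hence the result does not depend on the rebel ratio. The
#' expected satisfaction degree is 1/2 and the expected complete ratio is
#' (1/2)^d per agent (degree-0 agents count as completely satisfied).
#'
#' @param network A `fashion_network`.
#' @param r Rebel ratio (accepted for interface symmetry; the expectation
#'   is invariant in it).
#' @return A one-row tibble with `expected_cooperation`,
#'   `expected_avg_satisfaction`, `expected_complete_ratio`.
#' @export
expected_initial_indices <- function(network, r = 0.5) {
  stopifnot(inherits(network, "fashion_network"))
  d <- network$degrees
  p_sat <- stats::pbinom(ceiling(d / 2) - 1, d, 0.5, lower.tail = FALSE)
  tibble::tibble(
    expected_cooperation = mean(p_sat),
    expected_avg_satisfaction = mean(ifelse(d == 0L, 1, 0.5)),
    expected_complete_ratio = mean(0.5^d)
  )
}

# ---- Exact equilibrium enumeration --------------------------------------

#' Enumerate all pure Nash equilibria by brute force
#'
#' Walks all `2^n` action profiles and keeps those in which every agent is
#' satisfied. Intended as an exact oracle for small instances.
#'
#' @param network A `fashion_network`.
#' @param types Per-agent types, as in [make_state()].
#' @param cap Refuse instances with more than this many agents.
#' @return Integer matrix with one equilibrium profile per row (0 rows if
#'   none), columns ordered by agent id, rows in binary counting order of
#'   the profile (agent 0 is the least significant bit).
#' @examples
#' dyad <- make_network(2, rbind(c(0, 1)))
#' enumerate_pure_equilibria(dyad, c("conformist", "rebel"))  # none
#' @export
enumerate_pure_equilibria <- function(network, types, cap = 20L) {
  stopifnot(inherits(network, "fashion_network"))
  n <- network$n_agents
  if (n > cap) abort(sprintf("instance has %d agents; cap is %d.", n, cap))
  st <- make_state(network, types, rep(0L, n))  # validates types
  types <- st$types
  adj <- matrix(0L, n, n)
  if (nrow(network$edges) > 0) {
    adj[network$edges + 1L] <- 1L
    adj[network$edges[, 2:1, drop = FALSE] + 1L] <- 1L
  }
  deg <- network$degrees
  total <- 2^n
  chunk <- 2^min(n, 14L)
  keep <- vector("list", ceiling(total / chunk))
  bits <- function(v, n) t(vapply(v, function(x) (x %/% 2^(0:(n - 1))) %% 2,
                                  numeric(n)))
  for (ci in seq_along(keep)) {
    from <- (ci - 1) * chunk
    P <- bits(from:min(from + chunk - 1, total - 1), n)
    S1 <- P %*% adj                              # action-1 neighbour counts
    SAME <- P * S1 + (1 - P) * sweep(-S1, 2, deg, "+")
    LIKED <- SAME
    LIKED[, types == 1L] <- sweep(-SAME[, types == 1L, drop = FALSE], 2,
                                  deg[types == 1L], "+")
    ok <- 2 * LIKED >= matrix(deg, nrow(P), n, byrow = TRUE)
    keep[[ci]] <- P[rowSums(ok) == n, , drop = FALSE]
  }
  eq <- do.call(rbind, keep)
  storage.mode(eq) <- "integer"
  colnames(eq) <- paste0("agent_", 0:(n - 1))
  eq
}
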