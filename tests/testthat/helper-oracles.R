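# Naive, loop-based oracles kept deliberately independent of the package's
# vectorised / compiled paths.

naive_profile <- function(state) {
  net <- state$network
  n <- net$n_agents
  out <- data.frame(liked = integer(n), degree = integer(n),
                    satisfaction = numeric(n), satisfied = logical(n))
  for (i in seq_len(n)) {
    nb <- net$neighbors[[i]]
    deg <- length(nb)
    liked <- 0L
    for (j in nb) {
      same <- state$actions[j + 1L] == state$actions[i]
      liked <- liked + if (state$types[i] == 0L) same else !same
    }
    out$liked[i] <- liked
    out$degree[i] <- deg
    out$satisfaction[i] <- if (deg == 0L) 1 else liked / deg
    out$satisfied[i] <- if (deg == 0L) TRUE else liked / deg >= 0.5
  }
  out
}

naive_indices <- function(state) {
  pr <- naive_profile(state)
  list(cooperation_degree = mean(pr$satisfied),
       average_satisfaction = mean(pr$satisfaction),
       complete_ratio = mean(pr$satisfaction == 1),
       is_pure_nash = all(pr$satisfied))
}

# Erdos-Renyi-ish random simple network for property tests
random_network <- function(n, p_edge = 0.4) {
  pairs <- t(utils::combn(0:(n - 1L), 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  make_network(n, pairs[keep, , drop = FALSE])
}

random_state <- function(net, r = 0.5) {
  make_state(net,
             as.integer(stats::runif(net$n_agents) < r),
             as.integer(stats::runif(net$n_agents) < 0.5))
}

# profile-by-profile equilibrium check used against the chunked enumerator
naive_equilibria <- function(net, types) {
  n <- net$n_agents
  keep <- list()
  for (v in 0:(2^n - 1)) {
    a <- as.integer(intToBits(v)[1:n])
    st <- make_state(net, types, a)
    if (naive_indices(st)$is_pure_nash) keep[[length(keep) + 1L]] <- a
  }
  do.call(rbind, keep)
}
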