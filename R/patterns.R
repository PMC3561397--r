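# ---- Lattice pattern statistics -----------------------------------------

#' Decompose a configuration into continents
#'
#' A continent is a maximal set of agents that are connected through the
#' game's own adjacency and share one action. Any configuration
#' partitions the agent set into continents; component labels are
#' deterministic (the smallest agent id in each component).
#'
#' @param state A `fashion_state`.
#' @return A list of class `fashion_continents` with `membership`
#'   (per-agent component label, ordered by agent id) and `components`
#'   (tibble: `component`, `size`, `action`).
#' @export
continents <- function(state) {
  stopifnot(inherits(state, "fashion_state"))
  net <- state$network
  a <- state$actions
  e <- net$edges
  same <- e[a[e[, 1] + 1L] == a[e[, 2] + 1L], , drop = FALSE]
  g <- igraph::make_empty_graph(n = net$n_agents, directed = FALSE)
  if (nrow(same) > 0) g <- igraph::add_edges(g, t(same) + 1L)
  comp <- igraph::components(g)$membership
  # relabel by smallest agent id in each component
  first <- tapply(seq_along(comp) - 1L, comp, min)
  membership <- as.integer(first[comp])
  sizes <- table(membership)
  comps <- tibble::tibble(
    component = as.integer(names(sizes)),
    size = as.integer(sizes)
  )
  comps$action <- a[comps$component + 1L]
  structure(list(membership = membership, components = comps),
            class = "fashion_continents")
}

#' @export
print.fashion_continents <- function(x, ...) {
  cat(sprintf("<fashion_continents> %d continent(s); largest %d agent(s)\n",
              nrow(x$components), max(x$components$size)))
  invisible(x)
}

#' Fraction of interior (non-coastline) agents
#'
#' An agent is interior when all of her neighbours belong to her own
#' continent. For all-conformist configurations this is exactly the set
#' of completely satisfied agents, so the value equals the complete
#' ratio; the function therefore refuses states containing rebels, for
#' which the equivalence does not hold.
#'
#' @param state An all-conformist `fashion_state`.
#' @param decomposition Optional precomputed [continents()] result.
#' @return A proportion in `[0, 1]`.
#' @export
interior_fraction <- function(state, decomposition = NULL) {
  stopifnot(inherits(state, "fashion_state"))
  if (any(state$types == 1L))
    abort("interior_fraction is defined for all-conformist states only.")
  if (is.null(decomposition)) decomposition <- continents(state)
  memb <- decomposition$membership
  nb <- state$network$neighbors
  interior <- vapply(seq_along(memb), function(i) {
    all(memb[nb[[i]] + 1L] == memb[i])
  }, logical(1))
  mean(interior)
}

#' Fraction of agents on maze "streets"
#'
#' A street agent of an all-rebel torus maze has exactly two same-action
#' neighbours (and six opposite ones on the degree-8 torus, giving
#' satisfaction 0.75). The statistic — the fraction of agents with
#' exactly two same-action neighbours — is computable on any network but
#' is meaningful chiefly for degree-8 torus configurations.
#'
#' @param state A `fashion_state`.
#' @return A proportion in `[0, 1]`.
#' @export
street_fraction <- function(state) {
  stopifnot(inherits(state, "fashion_state"))
  net <- state$network
  same <- same_counts_cpp(net$csr_ptr, net$csr_idx, state$actions)
  mean(same == 2L)
}
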