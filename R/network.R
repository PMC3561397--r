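#' @useDynLib fashiongame, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom rlang abort .data
NULL

# ---- SocialNetwork container --------------------------------------------

#' Build a social network from an explicit edge list
#'
#' Networks are undirected simple graphs over agents labelled `0 ...
#' n_agents - 1`. The object stores the edge list (in construction order,
#' which is the order the rewiring routine walks), per-agent sorted
#' neighbour lists and degrees, plus a CSR index used by the simulation
#' core.
#'
#' @param n_agents Number of agents (positive integer).
#' @param edges Two-column integer matrix of 0-based agent ids, one edge
#'   per row. No self-loops or parallel edges.
#' @param rows,cols Optional lattice dimensions, kept so torus states can be
#'   rendered as a grid.
#' @return An object of class `fashion_network`.
#' @examples
#' net <- make_network(3, rbind(c(0, 1), c(1, 2)))
#' net$degrees
#' @export
make_network <- function(n_agents, edges, rows = NULL, cols = NULL) {
  n_agents <- as.integer(n_agents)
  if (is.na(n_agents) || n_agents < 1) abort("`n_agents` must be a positive integer.")
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (anyNA(edges) || any(edges < 0L) || any(edges >= n_agents))
      abort("edge endpoints must be agent ids in [0, n_agents).")
    if (any(edges[, 1] == edges[, 2])) abort("self-loops are not allowed.")
    k <- pmin(edges[, 1], edges[, 2]) * n_agents + pmax(edges[, 1], edges[, 2])
    if (anyDuplicated(k)) abort("parallel edges are not allowed.")
  }
  net <- structure(
    list(n_agents = n_agents, edges = edges, rows = rows, cols = cols),
    class = "fashion_network"
  )
  net <- add_adjacency(net)
  net
}

# CSR + neighbour lists from the edge matrix (0-based throughout).
add_adjacency <- function(net) {
  n <- net$n_agents
  e <- net$edges
  src <- c(e[, 1], e[, 2])
  dst <- c(e[, 2], e[, 1])
  o <- order(src, dst)
  src <- src[o]; dst <- dst[o]
  deg <- tabulate(src + 1L, nbins = n)
  net$degrees <- deg
  net$csr_ptr <- c(0L, cumsum(deg))
  net$csr_idx <- dst
  net$neighbors <- split(dst, factor(src, levels = 0:(n - 1L)))
  names(net$neighbors) <- NULL
  net
}

#' @export
print.fashion_network <- function(x, ...) {
  cat(sprintf("<fashion_network> %d agents, %d edges", x$n_agents, nrow(x$edges)))
  if (!is.null(x$rows)) cat(sprintf(" (%d x %d torus layout)", x$rows, x$cols))
  cat(sprintf("\n  degrees: min %d / mean %.2f / max %d\n",
              min(x$degrees), mean(x$degrees), max(x$degrees)))
  invisible(x)
}

#' Check the structural invariants of a network
#'
#' Verifies symmetry of the adjacency, absence of self-loops and parallel
#' edges, and the handshake identity (sum of degrees equals twice the edge
#' count). Errors on violation, otherwise returns the network invisibly.
#'
#' @param net A `fashion_network`.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "fashion_network"))
  n <- net$n_agents
  e <- net$edges
  if (nrow(e) > 0 && (any(e < 0L) || any(e >= n))) abort("agent id out of range.")
  if (any(e[, 1] == e[, 2])) abort("self-loop present.")
  k <- pmin(e[, 1], e[, 2]) * n + pmax(e[, 1], e[, 2])
  if (anyDuplicated(k)) abort("parallel edge present.")
  if (sum(net$degrees) != 2L * nrow(e)) abort("degree sum != 2 |E|.")
  for (i in seq_len(n)) {
    for (j in net$neighbors[[i]]) {
      if (!((i - 1L) %in% net$neighbors[[j + 1L]])) abort("adjacency not symmetric.")
    }
  }
  invisible(net)
}

# ---- Generators ----------------------------------------------------------

#' Torus lattice with Moore (8-cell) neighbourhoods
#'
#' Every agent sits on a `rows` x `cols` grid with wraparound in both
#' dimensions and is adjacent to the eight touching cells, so the network
#' is 8-regular with `4 * rows * cols` edges. Cell `(row, col)` (0-based)
#' is agent `row * cols + col`.
#'
#' @param rows,cols Lattice dimensions, each at least 3 (so the eight
#'   Moore neighbours are distinct under wraparound).
#' @return A `fashion_network`.
#' @examples
#' net <- make_torus_moore(5, 5)
#' all(net$degrees == 8)
#' @export
make_torus_moore <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 3L || cols < 3L)
    abort("`rows` and `cols` must both be at least 3.")
  id <- function(r, c) (r %% rows) * cols + (c %% cols)
  r <- rep(0:(rows - 1L), each = cols)
  c <- rep(0:(cols - 1L), times = rows)
  # one representative of each opposite-offset pair; grouped by offset then id
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  edges <- do.call(rbind, lapply(offs, function(o) {
    cbind(id(r, c), id(r + o[1], c + o[2]))
  }))
  make_network(rows * cols, edges, rows = rows, cols = cols)
}

#' Ring lattice (the Watts-Strogatz benchmark network)
#'
#' Agent `i` is adjacent to the `d/2` nearest agents on each side of the
#' ring (indices mod `n`), giving a `d`-regular network.
#'
#' @param n Number of agents.
#' @param d Even degree, `0 < d < n`.
#' @return A `fashion_network`.
#' @export
make_ring_lattice <- function(n, d) {
  n <- as.integer(n); d <- as.integer(d)
  if (is.na(n) || is.na(d) || d <= 0L || d %% 2L != 0L || d >= n)
    abort("`d` must be even with 0 < d < n.")
  i <- 0:(n - 1L)
  edges <- do.call(rbind, lapply(seq_len(d %/% 2L), function(k) {
    cbind(i, (i + k) %% n)
  }))
  make_network(n, edges)
}

#' Rewire a fraction of edges, Watts-Strogatz style
#'
#' Each edge is independently selected with probability `q`, walking edges
#' in their stored construction order (lattice edges grouped by
#' neighbour-rank, then agent id). A selected edge keeps its smaller
#' endpoint; the other endpoint is redrawn uniformly over all agents,
#' rejecting self-loops and duplicates of existing edges. After
#' `max_retry` rejections (e.g. the kept endpoint is saturated) the edge
#' is left in place. The edge count is conserved exactly; degrees may
#' change. Uses the current R random stream.
#'
#' @param net A `fashion_network`.
#' @param q Rewiring probability in `[0, 1]`.
#' @param max_retry Bound on rejection resampling per edge.
#' @return A rewired `fashion_network`.
#' @export
rewire_ws <- function(net, q, max_retry = 100L) {
  stopifnot(inherits(net, "fashion_network"))
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    abort("`q` must be a probability in [0, 1].")
  edges <- rewire_cpp(net$n_agents, net$edges, q, as.integer(max_retry))
  make_network(net$n_agents, edges, rows = net$rows, cols = net$cols)
}

#' Small-world network generator
#'
#' Composes a regular benchmark network with Watts-Strogatz rewiring under
#' a seeded random stream. `base = "ring"` is the original construction
#' (ring lattice of size `n`, density `d`); `base = "torus"` is the
#' modified family that instead rewires the Moore-neighbourhood torus
#' (defaults to 21 x 21, i.e. 441 agents, density 8).
#'
#' @param base `"ring"` or `"torus"`.
#' @param n,d Ring size and (even) density, used when `base = "ring"`.
#' @param rows,cols Torus dimensions, used when `base = "torus"`.
#' @param q Rewiring probability.
#' @param seed Optional integer seed; when given, the same arguments always
#'   produce the same network and the caller's RNG state is untouched.
#' @return A `fashion_network`.
#' @examples
#' net <- make_small_world("ring", n = 50, d = 4, q = 0.1, seed = 1)
#' @export
make_small_world <- function(base = c("ring", "torus"), n = 200L, d = 8L,
                             rows = 21L, cols = 21L, q = 0, seed = NULL) {
  base <- match.arg(base)
  build <- function() {
    bench <- if (base == "ring") make_ring_lattice(n, d) else make_torus_moore(rows, cols)
    rewire_ws(bench, q)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# ---- Edge-list I/O and igraph bridge ------------------------------------

#' Read / write plain edge-list files
#'
#' The format is two whitespace-separated 0-based integer columns, one
#' edge per line, no header. The reader validates simplicity (no
#' self-loops or parallel edges).
#'
#' @param path File path.
#' @param n_agents Agent count; defaults to `max(id) + 1`.
#' @return `read_edgelist()` returns a `fashion_network`;
#'   `write_edgelist()` returns `path` invisibly.
#' @export
read_edgelist <- function(path, n_agents = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "integer"))
  if (ncol(m) != 2L) abort("edge-list file must have exactly two columns.")
  if (is.null(n_agents)) n_agents <- max(m) + 1L
  make_network(n_agents, m)
}

#' @rdname read_edgelist
#' @param net A `fashion_network`.
#' @export
write_edgelist <- function(net, path) {
  utils::write.table(net$edges, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert to an igraph object
#'
#' Vertex names keep the package's 0-based agent ids.
#'
#' @param net A `fashion_network`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "fashion_network"))
  g <- igraph::make_empty_graph(n = net$n_agents, directed = FALSE)
  if (nrow(net$edges) > 0) g <- igraph::add_edges(g, t(net$edges) + 1L)
  igraph::set_vertex_attr(g, "name", value = as.character(0:(net$n_agents - 1L)))
}

#' Export a network as GraphML
#'
#' @param net A `fashion_network`.
#' @param path Output file path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
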