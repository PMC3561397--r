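# ---- State snapshots -----------------------------------------------------

#' Read / write state snapshots as CSV
#'
#' The snapshot schema is `agent_id,type,action` with 0-based agent ids,
#' `type` in `{C, R}` and `action` in `{0, 1}`.
#'
#' @param state A `fashion_state`.
#' @param path File path.
#' @param network Network to attach on read (the CSV stores no edges).
#' @return `write_state()` returns `path` invisibly; `read_state()` a
#'   `fashion_state`.
#' @export
write_state <- function(state, path) {
  stopifnot(inherits(state, "fashion_state"))
  df <- data.frame(agent_id = 0:(state$network$n_agents - 1L),
                   type = type_labels(state$types),
                   action = state$actions)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path, network) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("agent_id", "type", "action")
  if (!all(need %in% names(df)))
    abort("state CSV must have columns agent_id,type,action.")
  df <- df[order(df$agent_id), ]
  if (!identical(as.integer(df$agent_id), 0:(network$n_agents - 1L)))
    abort("agent ids must be exactly 0 .. n_agents-1.")
  make_state(network, df$type, df$action)
}

#' Render / parse a torus state as a character grid
#'
#' One string per lattice row; characters `c`/`r` are conformists/rebels
#' with action 0, `C`/`R` the same types with action 1.
#'
#' @param state A `fashion_state` whose network carries a torus layout.
#' @return `state_to_grid()`: a character vector, one element per lattice
#'   row.
#' @export
state_to_grid <- function(state) {
  stopifnot(inherits(state, "fashion_state"))
  net <- state$network
  if (is.null(net$rows)) abort("state's network has no torus layout.")
  ch <- c("c", "r")[state$types + 1L]
  ch[state$actions == 1L] <- toupper(ch[state$actions == 1L])
  apply(matrix(ch, net$rows, net$cols, byrow = TRUE), 1, paste, collapse = "")
}

#' @rdname state_to_grid
#' @param grid Character vector as produced by `state_to_grid()`.
#' @export
grid_to_state <- function(grid) {
  rows <- length(grid)
  cols <- unique(nchar(grid))
  if (length(cols) != 1L) abort("all grid rows must have equal length.")
  ch <- unlist(strsplit(grid, ""))
  if (!all(ch %in% c("c", "C", "r", "R")))
    abort("grid characters must be in {c,C,r,R}.")
  net <- make_torus_moore(rows, cols)
  # unlist(strsplit(...)) walks rows left-to-right, matching id = row*cols+col
  types <- as.integer(ch %in% c("r", "R"))
  actions <- as.integer(ch %in% c("C", "R"))
  make_state(net, types, actions)
}

# ---- Configuration files -------------------------------------------------

#' Load an experiment configuration
#'
#' Reads a YAML (or JSON) file describing either a sweep / phase scan
#' (returned as a [sweep_spec()]) or a single simulation (returned as a
#' named parameter list). Unknown keys and out-of-range values produce
#' errors naming the offending field. Defaults follow the simulation
#' protocol: 500 steps, 10 replicates, 41 x 41 torus.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A `sweep_spec`, or for `kind: simulate` a list of class
#'   `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file `%s` not found.", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(cfg)) abort("config must be a mapping of fields.")
  kind <- cfg$kind %||% "sweep"
  cfg$kind <- NULL
  if (kind == "simulate") {
    allowed <- c("network", "rows", "cols", "n", "density", "rewire_q",
                 "rebel_r", "p", "max_steps", "seed")
    unknown <- setdiff(names(cfg), allowed)
    if (length(unknown) > 0)
      abort(sprintf("unknown config field(s): %s.",
                    paste(unknown, collapse = ", ")))
    out <- utils::modifyList(
      list(network = "torus", rows = 41L, cols = 41L, n = 200L,
           density = 8L, rewire_q = 0, rebel_r = 0.5, p = 0.5,
           max_steps = 500L, seed = 1L),
      cfg)
    if (out$p <= 0 || out$p > 1)
      abort("field `p` must lie in (0, 1].")
    if (out$rebel_r < 0 || out$rebel_r > 1)
      abort("field `rebel_r` must lie in [0, 1].")
    class(out) <- "sim_config"
    return(out)
  }
  if (!kind %in% c("sweep", "phase_scan"))
    abort("field `kind` must be one of simulate, sweep, phase_scan.")
  allowed <- c("network_family", "rows", "cols", "n", "density", "rewire_q",
               "r_grid", "p_grid", "replicates", "max_steps", "master_seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    abort(sprintf("unknown config field(s): %s.",
                  paste(unknown, collapse = ", ")))
  defaults <- list(network_family = "torus", max_steps = 500L,
                   replicates = 10L)
  if (kind == "phase_scan")
    defaults <- utils::modifyList(defaults,
                                  list(max_steps = 5000L, r_grid = 1,
                                       p_grid = seq(0.8, 1, by = 0.005)))
  do.call(sweep_spec, utils::modifyList(defaults, cfg))
}

#' @rdname load_config
#' @param spec A `sweep_spec` to serialise.
#' @export
write_config <- function(spec, path) {
  stopifnot(inherits(spec, "sweep_spec"))
  yaml::write_yaml(c(list(kind = "sweep"), unclass(spec)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Run manifests -------------------------------------------------------

#' Write a reproducibility manifest for a sweep
#'
#' Records the configuration echo, package version, master seed, every
#' replicate seed appearing in the results table, a timestamp, and the
#' output paths — enough to regenerate the results file exactly.
#'
#' @param spec The `sweep_spec` that was run.
#' @param records The resulting sweep tibble.
#' @param outputs Character vector of output file paths.
#' @param path Manifest destination (JSON).
#' @export
write_manifest <- function(spec, records, outputs, path) {
  manifest <- list(
    package = "fashiongame",
    version = as.character(utils::packageVersion("fashiongame")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(spec),
    master_seed = spec$master_seed,
    replicate_seeds = records$seed,
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# ---- Canonical tiny fixtures --------------------------------------------

#' Deterministic tiny instances with known equilibrium structure
#'
#' * `cc_dyad`: two linked conformists — equilibria `(0,0)` and `(1,1)`.
#' * `cr_dyad`: conformist-rebel pair — matching pennies, no pure
#'   equilibrium.
#' * `rr_dyad`: two rebels — equilibria `(0,1)` and `(1,0)`.
#' * `rr_triangle`: all-rebel odd cycle — equilibria exist, but none with
#'   every agent completely satisfied (the graph is non-bipartite).
#' * `torus3`: all-conformist 3 x 3 Moore torus (the complete graph on 9
#'   agents), uniform action — a pure Nash equilibrium.
#' * `striped8`: all-rebel 8 x 8 torus with alternating action columns —
#'   every agent has exactly two same-action neighbours (street fraction
#'   1), a maze-like equilibrium.
#'
#' @return A named list of `fashion_state` objects.
#' @export
make_fixtures <- function() {
  dyad <- make_network(2, rbind(c(0L, 1L)))
  triangle <- make_network(3, rbind(c(0L, 1L), c(1L, 2L), c(0L, 2L)))
  torus3 <- make_torus_moore(3, 3)
  torus8 <- make_torus_moore(8, 8)
  col_of <- (0:63) %% 8L
  list(
    cc_dyad = make_state(dyad, c(0L, 0L), c(0L, 0L)),
    cr_dyad = make_state(dyad, c(0L, 1L), c(0L, 0L)),
    rr_dyad = make_state(dyad, c(1L, 1L), c(0L, 1L)),
    rr_triangle = make_state(triangle, rep(1L, 3), c(0L, 1L, 0L)),
    torus3 = make_state(torus3, rep(0L, 9), rep(1L, 9)),
    striped8 = make_state(torus8, rep(1L, 64), as.integer(col_of %% 2L))
  )
}
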