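# ---- Sweep specification -------------------------------------------------

#' Specify a parameter sweep
#'
#' Describes a full experiment: a network family with its parameters, the
#' rebel-ratio and updating-probability grids, the number of replicates
#' per parameter combination, the per-run step budget, and the master
#' seed from which every replicate seed is derived.
#'
#' Families:
#' * `"torus"`: the `rows` x `cols` Moore-neighbourhood torus, built once
#'   and shared by all runs (it is deterministic).
#' * `"smallworld"`: Watts-Strogatz networks from a ring lattice of size
#'   `n`, one per replicate, over the `density` x `rewire_q` grid.
#' * `"modified"`: small-world networks rewired from the `rows` x `cols`
#'   Moore torus (density 8 by construction), one per replicate, over the
#'   `rewire_q` grid.
#'
#' @param network_family `"torus"`, `"smallworld"` or `"modified"`.
#' @param rows,cols Torus dimensions (torus and modified families).
#' @param n Ring size (smallworld family).
#' @param density Even ring degrees to sweep (smallworld family).
#' @param rewire_q Rewiring probabilities to sweep (smallworld/modified).
#' @param r_grid Rebel ratios in `[0, 1]`.
#' @param p_grid Updating probabilities in `(0, 1]`.
#' @param replicates Independent runs per parameter combination.
#' @param max_steps Step budget per run.
#' @param master_seed Integer master seed.
#' @return A validated `sweep_spec` object.
#' @examples
#' sweep_spec("torus", rows = 11, cols = 11, r_grid = c(0, 1),
#'            p_grid = 0.5, replicates = 2, master_seed = 1)
#' @export
sweep_spec <- function(network_family = c("torus", "smallworld", "modified"),
                       rows = 41L, cols = 41L, n = 200L,
                       density = c(8L, 18L, 28L, 38L, 48L, 58L),
                       rewire_q = seq(0, 1, by = 0.1),
                       r_grid = seq(0, 1, by = 0.05),
                       p_grid = seq(0.05, 1, by = 0.05),
                       replicates = 10L, max_steps = 500L,
                       master_seed = 1L) {
  network_family <- match.arg(network_family)
  chk_prob <- function(x, nm, open_left = FALSE) {
    if (length(x) < 1L || anyNA(x) || any(x < 0) || any(x > 1) ||
        (open_left && any(x <= 0)))
      abort(sprintf("`%s` must be probabilities in %s.", nm,
                    if (open_left) "(0, 1]" else "[0, 1]"))
  }
  chk_prob(r_grid, "r_grid")
  chk_prob(p_grid, "p_grid", open_left = TRUE)
  if (network_family %in% c("smallworld", "modified")) chk_prob(rewire_q, "rewire_q")
  replicates <- as.integer(replicates)
  max_steps <- as.integer(max_steps)
  if (is.na(replicates) || replicates < 1L) abort("`replicates` must be >= 1.")
  if (is.na(max_steps) || max_steps < 1L) abort("`max_steps` must be >= 1.")
  if (network_family == "smallworld" &&
      (anyNA(density) || any(density %% 2 != 0) || any(density <= 0) ||
       any(density >= n)))
    abort("`density` values must be even with 0 < d < n.")
  structure(
    list(network_family = network_family, rows = as.integer(rows),
         cols = as.integer(cols), n = as.integer(n),
         density = as.integer(density), rewire_q = as.numeric(rewire_q),
         r_grid = as.numeric(r_grid), p_grid = as.numeric(p_grid),
         replicates = replicates, max_steps = max_steps,
         master_seed = as.integer(master_seed)),
    class = "sweep_spec"
  )
}

#' @export
print.sweep_spec <- function(x, ...) {
  combos <- nrow(sweep_grid(x))
  cat(sprintf(
    "<sweep_spec> %s family; %d parameter combination(s) x %d replicate(s) = %d run(s); %d steps each; master seed %d\n",
    x$network_family, combos, x$replicates, combos * x$replicates,
    x$max_steps, x$master_seed))
  invisible(x)
}

sweep_grid <- function(spec) {
  switch(spec$network_family,
    torus = tidyr::expand_grid(rebel_r = spec$r_grid, update_p = spec$p_grid),
    smallworld = tidyr::expand_grid(density = spec$density,
                                    rewire_q = spec$rewire_q,
                                    rebel_r = spec$r_grid,
                                    update_p = spec$p_grid),
    modified = tidyr::expand_grid(rewire_q = spec$rewire_q,
                                  rebel_r = spec$r_grid,
                                  update_p = spec$p_grid)
  )
}

# Replicate seeds come from the master seed; each replicate seed is then
# split into four sub-seeds (network draw, type init, action init, flip
# stream) so any single run can be regenerated from its table row.
derive_seeds <- function(master_seed, n_runs) {
  withr::with_seed(master_seed, sample.int(2147483647L, n_runs))
}

split_seed <- function(seed) {
  withr::with_seed(seed, sample.int(2147483647L, 4L))
}

# ---- Sweep driver --------------------------------------------------------

#' Run a parameter sweep
#'
#' For every parameter combination in the spec's grid, runs `replicates`
#' independent simulations (fresh random network per replicate for the
#' small-world families; fresh type/action initialization always) of the
#' stochastic best-response dynamic, recording the final-step indices of
#' each run. Bit-identical output for equal specs.
#'
#' @param spec A [sweep_spec()].
#' @param progress Print a line every few hundred runs.
#' @return A `fashion_sweep` tibble, one row per run, with columns
#'   `family, n, rows, cols, density, rewire_q, rebel_r, update_p,
#'   replicate, seed, steps_run, reached_nash, cooperation_degree,
#'   avg_satisfaction, complete_ratio`.
#' @export
run_sweep <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- sweep_grid(spec)
  n_combo <- nrow(grid)
  n_runs <- n_combo * spec$replicates
  seeds <- derive_seeds(spec$master_seed, n_runs)
  withr::local_preserve_seed()

  fixed_torus <- spec$network_family == "torus"
  base_net <- if (spec$network_family != "smallworld")
    make_torus_moore(spec$rows, spec$cols) else NULL
  ring_cache <- new.env(parent = emptyenv())

  steps_run <- integer(n_runs); reached <- logical(n_runs)
  coop <- numeric(n_runs); avgsat <- numeric(n_runs); comp <- numeric(n_runs)
  net_n <- integer(n_runs)

  run_i <- 0L
  for (g in seq_len(n_combo)) {
    r <- grid$rebel_r[g]; p <- grid$update_p[g]
    q <- if ("rewire_q" %in% names(grid)) grid$rewire_q[g] else NA_real_
    d <- if ("density" %in% names(grid)) grid$density[g] else NA_integer_
    for (rep in seq_len(spec$replicates)) {
      run_i <- run_i + 1L
      set.seed(seeds[run_i])
      ss <- sample.int(2147483647L, 4L)
      if (fixed_torus) {
        nn <- base_net$n_agents
        csr <- list(ptr = base_net$csr_ptr, idx = base_net$csr_idx)
      } else {
        bench <- if (spec$network_family == "modified") base_net
        else {
          key <- as.character(d)
          ring <- get0(key, envir = ring_cache)
          if (is.null(ring)) {
            ring <- make_ring_lattice(spec$n, d)
            assign(key, ring, envir = ring_cache)
          }
          ring
        }
        nn <- bench$n_agents
        set.seed(ss[1])
        csr <- build_csr_cpp(nn, rewire_cpp(nn, bench$edges, q, 100L))
      }
      set.seed(ss[2]); types <- as.integer(stats::runif(nn) < r)
      set.seed(ss[3]); actions <- as.integer(stats::runif(nn) < 0.5)
      set.seed(ss[4])
      res <- run_dynamics_cpp(csr$ptr, csr$idx, types, actions, p,
                              spec$max_steps, TRUE, FALSE, FALSE)
      steps_run[run_i] <- res$steps_run
      reached[run_i] <- res$reached_nash
      coop[run_i] <- res$cooperation_degree
      avgsat[run_i] <- res$avg_satisfaction
      comp[run_i] <- res$complete_ratio
      net_n[run_i] <- nn
      if (progress && run_i %% 500L == 0L)
        message(sprintf("run %d / %d", run_i, n_runs))
    }
  }

  idx <- rep(seq_len(n_combo), each = spec$replicates)
  out <- tibble::tibble(
    family = spec$network_family,
    n = net_n,
    rows = if (spec$network_family != "smallworld") spec$rows else NA_integer_,
    cols = if (spec$network_family != "smallworld") spec$cols else NA_integer_,
    density = if ("density" %in% names(grid)) grid$density[idx] else 8L,
    rewire_q = if ("rewire_q" %in% names(grid)) grid$rewire_q[idx] else 0,
    rebel_r = grid$rebel_r[idx],
    update_p = grid$update_p[idx],
    replicate = rep(seq_len(spec$replicates), times = n_combo),
    seed = seeds,
    steps_run = steps_run,
    reached_nash = reached,
    cooperation_degree = coop,
    avg_satisfaction = avgsat,
    complete_ratio = comp
  )
  class(out) <- c("fashion_sweep", class(out))
  attr(out, "spec") <- spec
  out
}

# ---- Aggregation ---------------------------------------------------------

#' Average an index over groups of sweep records
#'
#' Computes the arithmetic mean of one index per parameter group (the
#' paper's "average of the 10 final values"), or the grand mean when no
#' grouping columns are given. Groups with no records are simply absent
#' from the output.
#'
#' @param records A sweep tibble from [run_sweep()].
#' @param index Index column name (e.g. `"cooperation_degree"`).
#' @param by Character vector of grouping columns (default none: grand
#'   mean).
#' @return A tibble with the grouping columns, `mean_value` and
#'   `n_records`.
#' @export
aggregate_indices <- function(records, index = "cooperation_degree",
                              by = character()) {
  if (!index %in% names(records)) abort(sprintf("no column `%s`.", index))
  if (!all(by %in% names(records)))
    abort("all `by` columns must exist in `records`.")
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(mean_value = mean(.data[[index]]),
                     n_records = dplyr::n(), .groups = "drop")
}

#' Fraction of runs that reached a pure Nash equilibrium
#'
#' Because Nash states are absorbing, "reached by the final step" and "the
#' final state is an equilibrium" coincide.
#'
#' @param records A non-empty subset of sweep records.
#' @return A proportion in `[0, 1]`.
#' @export
equilibrium_ratio <- function(records) {
  if (nrow(records) == 0L)
    abort("equilibrium ratio is undefined on an empty record set.")
  mean(records$reached_nash)
}

# ---- Phase transition scan ----------------------------------------------

#' Fine scan of the equilibrium-ratio phase transition
#'
#' Runs the torus experiment over a fine updating-probability grid with a
#' long step budget (the regime where synchronous all-rebel dynamics stop
#' converging), and reports the equilibrium ratio and mean final
#' cooperation degree per `(r, p)` cell.
#'
#' @param r_grid Rebel ratios.
#' @param p_grid Updating probabilities, sorted ascending.
#' @param replicates Runs per cell.
#' @param max_steps Step budget per run (long: the transition is sharp but
#'   convergence near it is slow).
#' @param master_seed Integer master seed.
#' @param rows,cols Torus dimensions.
#' @return A tibble with `rebel_r`, `update_p`, `equilibrium_ratio`,
#'   `mean_cooperation`.
#' @export
phase_scan <- function(r_grid = 1, p_grid = seq(0.8, 1, by = 0.005),
                       replicates = 10L, max_steps = 5000L,
                       master_seed = 1L, rows = 41L, cols = 41L) {
  if (is.unsorted(p_grid)) abort("`p_grid` must be sorted ascending.")
  spec <- sweep_spec("torus", rows = rows, cols = cols, r_grid = r_grid,
                     p_grid = p_grid, replicates = replicates,
                     max_steps = max_steps, master_seed = master_seed)
  records <- run_sweep(spec)
  records |>
    dplyr::group_by(.data$rebel_r, .data$update_p) |>
    dplyr::summarise(equilibrium_ratio = mean(.data$reached_nash),
                     mean_cooperation = mean(.data$cooperation_degree),
                     .groups = "drop")
}
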