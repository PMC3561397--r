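test_that("initialization honours the rebel ratio exactly at its extremes", {
  net <- make_torus_moore(5, 5)
  expect_true(all(init_state(net, 0, seed = 1)$types == 0L))
  expect_true(all(init_state(net, 1, seed = 1)$types == 1L))
  expect_error(init_state(net, 1.2), "probability")
})

test_that("rebel counts concentrate as a binomial across seeds", {
  net <- make_torus_moore(41, 41)
  n <- net$n_agents
  sdev <- sqrt(n * 0.25)
  inside <- vapply(1:40, function(s) {
    abs(sum(init_state(net, 0.5, seed = s)$types) - n / 2) <= 3 * sdev
  }, logical(1))
  expect_gte(mean(inside), 0.97)  # 3-sigma band holds for ~all seeds
})

test_that("a pure Nash state is a fixed point of the step map for any p", {
  fx <- make_fixtures()
  for (p in c(0.05, 0.5, 1)) {
    nxt <- withr::with_seed(3, br_step(fx$striped8, p))
    expect_identical(nxt$actions, fx$striped8$actions)
    nxt2 <- withr::with_seed(3, br_step(fx$torus3, p))
    expect_identical(nxt2$actions, fx$torus3$actions)
  }
  # ... including Nash states found by exhaustive enumeration
  withr::with_seed(53, {
    for (k in 1:10) {
      net <- random_network(6)
      types <- as.integer(stats::runif(6) < 0.5)
      eq <- enumerate_pure_equilibria(net, types)
      for (row in seq_len(nrow(eq))) {
        st <- make_state(net, types, eq[row, ])
        expect_identical(br_step(st, 1)$actions, st$actions)
      }
    }
  })
})

test_that("at p = 1 exactly the unsatisfied agents flip", {
  withr::with_seed(61, {
    for (k in 1:10) {
      net <- random_network(12)
      st <- random_state(net)
      unsat <- which(!tidy(st)$satisfied)
      nxt <- br_step(st, 1)
      expect_identical(which(nxt$actions != st$actions), unsat)
    }
  })
})

test_that("uniform all-rebel states oscillate with period 2 at p = 1", {
  net <- make_torus_moore(6, 6)
  st <- make_state(net, rep(1L, 36), rep(1L, 36))
  one <- br_step(st, 1)
  expect_true(all(one$actions == 0L))
  two <- br_step(one, 1)
  expect_identical(two$actions, st$actions)

  run <- run_dynamics(st, 1, max_steps = 100, seed = 1, stop_at_nash = TRUE)
  expect_false(run$reached_nash)
  cyc <- detect_limit_cycle(st)
  expect_equal(cyc$period, 2L)
})

test_that("the R step and the compiled runner draw identical trajectories", {
  net <- make_torus_moore(6, 6)
  st <- init_state(net, 0.5, seed = 9)
  p <- 0.37
  # single compiled step vs the reference R step, same stream
  cppstep <- withr::with_seed(101,
    run_dynamics(st, p, max_steps = 1, seed = NULL, stop_at_nash = FALSE))
  rstep <- withr::with_seed(101, br_step(st, p))
  expect_identical(cppstep$final_state$actions, rstep$actions)

  # multi-step: iterate the R step against one compiled run
  k <- 7
  cppk <- withr::with_seed(102,
    run_dynamics(st, p, max_steps = k, stop_at_nash = FALSE))
  ref <- st
  withr::with_seed(102, for (i in 1:k) ref <- br_step(ref, p))
  expect_identical(cppk$final_state$actions, ref$actions)
})

test_that("runs stop at absorption and are seed-deterministic", {
  fx <- make_fixtures()
  run0 <- run_dynamics(fx$striped8, 0.5, max_steps = 100, seed = 4)
  expect_equal(run0$steps_run, 0L)
  expect_true(run0$reached_nash)
  expect_equal(run0$first_nash_step, 0L)

  net <- make_torus_moore(10, 10)
  st <- init_state(net, 0.3, seed = 5)
  a <- run_dynamics(st, 0.4, max_steps = 200, seed = 6)
  b <- run_dynamics(st, 0.4, max_steps = 200, seed = 6)
  expect_identical(a$final_state$actions, b$final_state$actions)
  expect_identical(a$steps_run, b$steps_run)
  expect_identical(a$final_indices, b$final_indices)
  if (a$reached_nash) expect_true(a$final_indices$is_pure_nash)
})

test_that("recorded index series starts at the initial state and tracks steps", {
  net <- make_torus_moore(8, 8)
  st <- init_state(net, 0, seed = 13)
  run <- run_dynamics(st, 0.5, max_steps = 100, seed = 14,
                      record_series = TRUE)
  expect_equal(nrow(run$index_series), run$steps_run + 1L)
  expect_equal(run$index_series$cooperation_degree[1],
               compute_indices(st)$cooperation_degree)
  last <- run$index_series[nrow(run$index_series), ]
  expect_equal(last$cooperation_degree, run$final_indices$cooperation_degree)
})

test_that("homogeneous populations are potential games: sequential dynamics
           always absorb, with the edge-concordance potential increasing", {
  withr::with_seed(71, {
    for (r in c(0, 1)) {
      for (k in 1:5) {
        net <- random_network(15, p_edge = 0.3)
        st <- random_state(net, r = r)
        st$types <- rep(as.integer(r), 15)   # force homogeneity
        run <- run_dynamics(st, p = 0.5, max_steps = 10000, seed = k,
                            mode = "sequential")
        expect_true(run$reached_nash)
      }
    }
  })
  # one-flip moves strictly increase concordant (conformist) edge count
  net <- make_torus_moore(5, 5)
  st <- init_state(net, 0, seed = 15)
  concord <- function(s) {
    e <- s$network$edges
    sum(s$actions[e[, 1] + 1L] == s$actions[e[, 2] + 1L])
  }
  prev <- st
  for (i in 1:50) {
    nxt <- run_dynamics(prev, 0.5, max_steps = 1, seed = i,
                        mode = "sequential", stop_at_nash = TRUE)
    if (nxt$reached_nash && nxt$steps_run == 0L) break
    expect_gt(concord(nxt$final_state), concord(prev))
    prev <- nxt$final_state
  }
})

test_that("all-rebel synchronous dynamics reach limit cycles of period 1 or 2", {
  withr::with_seed(81, {
    for (k in 1:50) {
      n <- sample(5:12, 1)
      net <- random_network(n, p_edge = stats::runif(1, 0.2, 0.8))
      st <- random_state(net, r = 1)
      st$types <- rep(1L, n)
      cyc <- detect_limit_cycle(st, max_period = 4, max_steps = 4096)
      expect_true(cyc$period %in% c(1L, 2L))
    }
  })
})

test_that("the conformist-rebel dyad chases itself through all four profiles", {
  # matching pennies under synchronous best response: exactly one player is
  # unsatisfied at each profile, so the chase walks (0,0) -> (0,1) ->
  # (1,1) -> (1,0) -> (0,0): a limit cycle of period 4
  fx <- make_fixtures()
  cyc <- detect_limit_cycle(fx$cr_dyad)
  expect_equal(cyc$period, 4L)
  expect_equal(cyc$entered_at, 0L)
  expect_equal(nrow(cyc$states_in_cycle), 4L)
  expect_error(detect_limit_cycle(fx$cr_dyad, p = 0.5), "p = 1")
})
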