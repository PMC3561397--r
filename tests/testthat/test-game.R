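test_that("single-agent satisfaction matches the worked torus cases", {
  fx <- make_fixtures()

  # rebel on a maze street: 2 same-action of 8 neighbours -> liked 6
  street <- agent_satisfaction(fx$striped8, 0)
  expect_equal(street$liked, 6L)
  expect_equal(street$degree, 8L)
  expect_equal(street$satisfaction, 0.75)
  expect_true(street$satisfied)

  # conformist with all 8 neighbours agreeing is completely satisfied
  tor <- make_torus_moore(5, 5)
  all_same <- make_state(tor, rep(0L, 25), rep(1L, 25))
  expect_equal(agent_satisfaction(all_same, 12)$satisfaction, 1)

  # conformist on the 4-4 tie sits exactly at the satisfaction threshold
  acts <- rep(0L, 25)
  nb <- tor$neighbors[[13]]
  acts[nb[1:4] + 1L] <- 1L
  tie <- make_state(tor, rep(0L, 25), acts)
  a <- agent_satisfaction(tie, 12)
  expect_equal(a$satisfaction, 0.5)
  expect_true(a$satisfied)

  expect_error(agent_satisfaction(tie, 99), "unknown agent")
})

test_that("utility is liked minus hated and agrees with satisfaction", {
  withr::with_seed(11, {
    for (k in 1:10) {
      net <- random_network(8)
      st <- random_state(net)
      for (i in 0:7) {
        a <- agent_satisfaction(st, i)
        u <- utility(st, i)
        expect_identical(u, as.integer(2L * a$liked - a$degree))
        expect_identical(u >= 0L, a$satisfied)
        # parity of utility equals parity of degree
        expect_identical(u %% 2L, a$degree %% 2L)
      }
    }
  })
})

test_that("index computation agrees with a naive per-agent loop", {
  withr::with_seed(21, {
    for (k in 1:20) {
      net <- random_network(sample(4:12, 1), p_edge = stats::runif(1, 0.1, 0.9))
      st <- random_state(net, r = stats::runif(1))
      idx <- compute_indices(st)
      ref <- naive_indices(st)
      expect_equal(idx$cooperation_degree, ref$cooperation_degree)
      expect_equal(idx$average_satisfaction, ref$average_satisfaction)
      expect_equal(idx$complete_ratio, ref$complete_ratio)
      expect_identical(idx$is_pure_nash, ref$is_pure_nash)
      expect_identical(idx$is_pure_nash, idx$cooperation_degree == 1)
      expect_lte(idx$complete_ratio, idx$cooperation_degree)
    }
  })
})

test_that("uniform all-rebel configurations score zero on every index", {
  net <- make_torus_moore(5, 5)
  st <- make_state(net, rep(1L, 25), rep(0L, 25))
  idx <- compute_indices(st)
  expect_equal(idx$cooperation_degree, 0)
  expect_equal(idx$average_satisfaction, 0)
  expect_equal(idx$complete_ratio, 0)
  expect_false(idx$is_pure_nash)

  # and the all-conformist mirror image is perfect cooperation
  idx2 <- compute_indices(make_state(net, rep(0L, 25), rep(0L, 25)))
  expect_true(idx2$is_pure_nash)
  expect_equal(idx2$average_satisfaction, 1)
})

test_that("complementing every action leaves all indices unchanged", {
  withr::with_seed(31, {
    for (k in 1:15) {
      net <- random_network(10)
      st <- random_state(net)
      flipped <- make_state(net, st$types, 1L - st$actions)
      expect_equal(compute_indices(st), compute_indices(flipped))
    }
  })
})

test_that("expected initial indices match brute force over neighbour patterns", {
  net <- make_torus_moore(5, 5)
  # enumerate all 2^8 equally likely neighbour-match patterns of one agent
  matches <- rowSums(expand.grid(rep(list(0:1), 8)))
  expect_equal(mean(matches >= 4), 163 / 256)
  ei <- expected_initial_indices(net)
  expect_equal(ei$expected_cooperation, 163 / 256)
  expect_equal(ei$expected_avg_satisfaction, 0.5)
  expect_equal(ei$expected_complete_ratio, (1 / 2)^8)

  # heterogeneous degrees: the binomial tail is averaged per agent
  path3 <- make_network(3, rbind(c(0L, 1L), c(1L, 2L)))
  ei3 <- expected_initial_indices(path3)
  expect_equal(ei3$expected_cooperation, (0.5 + 0.75 + 0.5) / 3)
  expect_equal(ei3$expected_complete_ratio, (0.5 + 0.25 + 0.5) / 3)
})

test_that("expected initial indices match Monte-Carlo within 3 SE", {
  net <- make_torus_moore(7, 7)
  n_mc <- 10000L
  withr::with_seed(77, {
    sims <- vapply(seq_len(n_mc), function(i) {
      st <- init_state(net, 0.5)
      idx <- compute_indices(st)
      c(idx$cooperation_degree, idx$average_satisfaction, idx$complete_ratio)
    }, numeric(3))
  })
  mc <- rowMeans(sims)
  se <- apply(sims, 1, stats::sd) / sqrt(n_mc)
  ei <- unlist(expected_initial_indices(net, 0.5))
  expect_lt(abs(mc[1] - ei[1]), 3 * se[1])
  expect_lt(abs(mc[2] - ei[2]), 3 * se[2])
  expect_lt(abs(mc[3] - ei[3]), 3 * se[3])
})

test_that("equilibrium enumeration handles the three dyads exactly", {
  dyad <- make_network(2, rbind(c(0L, 1L)))
  expect_equal(nrow(enumerate_pure_equilibria(dyad, c("conformist", "rebel"))), 0)

  cc <- enumerate_pure_equilibria(dyad, c("conformist", "conformist"))
  expect_equal(unname(cc), rbind(c(0L, 0L), c(1L, 1L)))

  rr <- enumerate_pure_equilibria(dyad, c("rebel", "rebel"))
  expect_equal(unname(rr), rbind(c(1L, 0L), c(0L, 1L)))

  big <- make_ring_lattice(30, 2)
  expect_error(enumerate_pure_equilibria(big, rep(0L, 30)), "cap")
})

test_that("enumeration agrees with a per-profile satisfaction check", {
  withr::with_seed(41, {
    for (k in 1:8) {
      n <- sample(3:7, 1)
      net <- random_network(n, p_edge = 0.5)
      types <- as.integer(stats::runif(n) < 0.5)
      got <- enumerate_pure_equilibria(net, types)
      ref <- naive_equilibria(net, types)
      if (is.null(ref)) {
        expect_equal(nrow(got), 0)
      } else {
        expect_equal(unname(got), ref)
      }
    }
  })
})

test_that("completely satisfied all-rebel profiles exist iff bipartite", {
  # even cycle (bipartite): the alternating profile satisfies everyone fully
  c4 <- make_ring_lattice(4, 2)
  eq4 <- enumerate_pure_equilibria(c4, rep(1L, 4))
  full4 <- apply(eq4, 1, function(a) {
    compute_indices(make_state(c4, rep(1L, 4), a))$complete_ratio == 1
  })
  expect_true(any(full4))

  # triangle (odd cycle, non-bipartite): no profile is fully satisfying
  tri <- make_network(3, rbind(c(0L, 1L), c(1L, 2L), c(0L, 2L)))
  eq3 <- naive_equilibria(tri, rep(1L, 3))
  eq3_full <- enumerate_pure_equilibria(tri, rep(1L, 3))
  if (nrow(eq3_full) > 0) {
    full3 <- apply(eq3_full, 1, function(a) {
      compute_indices(make_state(tri, rep(1L, 3), a))$complete_ratio == 1
    })
    expect_false(any(full3))
  }
  # the Moore torus contains odd cycles: same conclusion
  k9 <- make_torus_moore(3, 3)
  eq9 <- enumerate_pure_equilibria(k9, rep(1L, 9))
  if (nrow(eq9) > 0) {
    full9 <- apply(eq9, 1, function(a) {
      compute_indices(make_state(k9, rep(1L, 9), a))$complete_ratio == 1
    })
    expect_false(any(full9))
  }
})
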