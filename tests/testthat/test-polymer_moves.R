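test_that("polymer initialization produces a valid self-avoiding chain", {
  p <- init_polymer(400, seed = 1)
  expect_equal(nrow(p), 400)
  d2 <- rowSums((p[-1, ] - p[-400, ])^2)
  expect_true(all(d2 == 1))          # straight-rod bonds survive pivots
  expect_false(oracle_has_collision(p))

  p1 <- init_polymer(1, seed = 3)
  expect_equal(nrow(p1), 1)

  for (s in 1:5) {
    q <- init_polymer(50, seed = s)
    expect_false(oracle_has_collision(q))
    expect_true(oracle_chain_connected(q))
  }
  expect_error(init_polymer(0), "n_nodes")
})

test_that("node affinities are uniform, reproducible draws in [0, 1]", {
  a <- assign_affinities(400, seed = 7)
  expect_true(all(a >= 0 & a <= 1))
  expect_identical(a, assign_affinities(400, seed = 7))
  big <- assign_affinities(1e5, seed = 11)
  se <- sqrt(1 / 12 / 1e5)
  expect_lt(abs(mean(big) - 0.5), 3 * se)
})

test_that("pivot proposals preserve bond lengths and the fixed arm", {
  poly <- init_polymer(30, seed = 2)
  # identity symmetry returns the input coordinates
  id <- cpp_propose_pivot(unclass(poly), 10L, 0L)
  expect_equal(id$coords, unclass(poly), ignore_attr = TRUE)
  expect_true(id$valid)

  pr <- propose_pivot(poly, pivot_index = 12, sym_index = 5)
  expect_equal(pr$coords[1:12, ], unclass(poly)[1:12, ],
               ignore_attr = TRUE)
  if (pr$valid) expect_true(oracle_chain_connected(pr$coords))
})

test_that("pivot validity flag agrees with the all-pairs collision oracle", {
  poly <- init_polymer(30, seed = 4)
  set.seed(99)
  for (i in 1:1000) {
    k <- sample.int(29, 1)
    s <- sample.int(47, 1)
    pr <- cpp_propose_pivot(unclass(poly), k, s)
    expect_identical(pr$valid, !oracle_has_collision(pr$coords))
    if (pr$valid && i %% 10 == 0) poly <- pr$coords  # walk the chain around
  }
})

test_that("single-site moves respect connectivity and excluded volume", {
  rod <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3, byrow = TRUE)
  # middle node of a straight trimer: the four lateral displacements give
  # sqrt(2) bonds to both neighbours; the two axial ones collide
  valid_dirs <- vapply(1:6, function(d)
    cpp_propose_local(rod, 1L, d - 1L)$valid, logical(1))
  expect_identical(valid_dirs, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))

  # chain end has more freedom than the blocked interior node
  end_valid <- sum(vapply(1:6, function(d)
    cpp_propose_local(rod, 2L, d - 1L)$valid, logical(1)))
  expect_gt(end_valid, sum(valid_dirs) - 1)

  # target site occupied by another node -> invalid
  pair <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_false(cpp_propose_local(pair, 0L, 0L)$valid)  # +x onto node 2

  expect_error(propose_local_move(init_polymer(5, 1), 9), "out of range")
})

test_that("move energies count broken bridge bonds additively", {
  p <- sim_params(n_nodes = 6, N_endog = 4, E_bond = 1)
  st <- new_sim_state(p, seed = 1)
  st$coords <- matrix(c(0:5, rep(0, 12)), 6, 3)  # straight rod
  # two binders on node 1, two on adjacent node 2, fully cross-bonded
  st$node <- c(1L, 1L, 2L, 2L)
  st$bonds <- rbind(c(1L, 3L), c(2L, 4L))
  st$nbonds <- c(1L, 1L, 1L, 1L)

  same <- st$coords
  expect_equal(as.numeric(move_energy_delta(st, same, p)), 0)

  # pull node 2 far from node 1: both bonds break
  apart <- st$coords
  apart[2:6, 1] <- apart[2:6, 1] + 10
  expect_equal(as.numeric(move_energy_delta(st, apart, p)), 2)

  # clusters of 5 and 3 molecules can hold at most min(5, 3) bonds
  st2 <- new_sim_state(sim_params(n_nodes = 6, N_endog = 8, E_bond = 1),
                       seed = 1)
  st2$coords <- st$coords
  st2$node <- c(rep(1L, 5), rep(2L, 3))
  st2$bonds <- rbind(c(1L, 6L), c(2L, 7L), c(3L, 8L))
  st2$nbonds <- c(1, 1, 1, 0, 0, 1, 1, 1)
  p2 <- sim_params(n_nodes = 6, N_endog = 8, E_bond = 1)
  expect_equal(as.numeric(move_energy_delta(st2, apart, p2)), 1 * 3)
})

test_that("Metropolis rule accepts downhill always and uphill at exp(-dE)", {
  expect_true(all(vapply(1:50, function(i)
    metropolis_accept(-abs(rnorm(1)), seed = i), logical(1))))
  expect_true(metropolis_accept(0))
  set.seed(123)
  acc <- mean(vapply(1:2e4, function(i) metropolis_accept(1), logical(1)))
  se <- sqrt(exp(-1) * (1 - exp(-1)) / 2e4)
  expect_lt(abs(acc - exp(-1)), 3 * se)
  expect_false(metropolis_accept(1e9, seed = 1))
})
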