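test_that("forced binding saturates a node at exactly N_max molecules", {
  p <- sim_params(n_nodes = 1, N_endog = 1000, k_a_endog = 1,
                  k_d_endog = 0, k_join = 0, model_variant = "baseline",
                  N_max = 15)
  st <- new_sim_state(p, seed = 1)
  bound <- integer(100)
  for (i in 1:100) {
    st <- binding_step(st, p)
    bound[i] <- sum(st$node > 0)
  }
  expect_equal(bound[100], 15)
  expect_true(all(diff(bound) >= 0))
  expect_true(all(bound <= 15))
})

test_that("an empty node with a full free pool binds at probability one", {
  p <- sim_params(n_nodes = 1, N_endog = 1, k_a_endog = 1, k_d_endog = 0)
  st <- new_sim_state(p, seed = 2)
  st$affinity[1] <- 1
  st <- binding_step(st, p)
  expect_equal(sum(st$node > 0), 1)
})

test_that("binders are conserved and caps/bonds stay consistent", {
  for (seed in 1:5) {
    p <- sim_params(n_nodes = 30, N_endog = 10, N_exog = 10,
                    model_variant = "capping_ML", k_a_endog = 0.02,
                    k_d_endog = 0.02, k_join = 0.2, k_break = 0.05,
                    n_steps = 10)
    st <- new_sim_state(p, seed = seed)
    for (i in 1:40) {
      st <- binding_step(st, p)
      st <- bridging_step(st, p)
      expect_equal(length(st$node), 20)            # molecules conserved
      expect_true(all(surfaces_free(st, p) >= 0))
      if (nrow(st$bonds)) {
        # bond symmetry: endpoints bound, at distinct nodes, counted once
        expect_true(all(st$node[st$bonds] > 0))
        expect_true(all(st$node[st$bonds[, 1]] != st$node[st$bonds[, 2]]))
        expect_false(anyDuplicated(st$bonds) > 0)
        # per-binder bond counts match the bond list
        tab <- tabulate(c(st$bonds), nbins = 20)
        expect_equal(st$nbonds, tab)
      }
    }
  }
})

test_that("caps equal Ph-ML cluster joins when nothing unbinds", {
  p <- sim_params(n_nodes = 10, N_endog = 8, N_exog = 8,
                  model_variant = "capping_ML", k_a_endog = 0.1,
                  k_d_endog = 0, k_join = 0, n_steps = 10)
  st <- new_sim_state(p, seed = 3)
  for (i in 1:60) st <- binding_step(st, p)
  expect_equal(sum(st$capped), st$n_capped)
  # every cap sits on a bound Ph co-clustered with at least one ML
  capped <- which(st$capped == 1)
  expect_true(all(st$species[capped] != 3))
  expect_true(all(st$node[capped] > 0))
})

test_that("a fully capped cluster admits no new members or bonds", {
  p <- sim_params(n_nodes = 4, N_endog = 2, N_exog = 4,
                  model_variant = "capping_ML", k_a_endog = 1,
                  k_d_endog = 0, k_join = 1, k_break = 0)
  st <- new_sim_state(p, seed = 4)
  # cluster on node 1: two Ph, both capped, plus the two capping MLs
  st$node <- c(1L, 1L, 1L, 1L, 0L, 0L)
  st$capped <- c(1L, 1L, 0L, 0L, 0L, 0L)
  st$n_capped <- 2L
  st$affinity[] <- 1
  before <- sum(st$node == 1)
  for (i in 1:50) {
    st <- binding_step(st, p)
    st <- bridging_step(st, p)
  }
  expect_equal(sum(st$node == 1), before)   # no new members
  # capped Ph and surface-less ML formed no bonds from node 1
  if (nrow(st$bonds))
    expect_false(any(st$bonds <= 4))
})

test_that("bridging respects the spatial gate and surface bookkeeping", {
  p <- sim_params(n_nodes = 10, N_endog = 2, k_join = 1, k_break = 0,
                  k_d_endog = 0)
  st <- new_sim_state(p, seed = 5)
  st$coords <- cbind(0:9, 0L, 0L)
  st$node <- c(1L, 5L)               # distance 4 > sqrt(3)
  st <- bridging_step(st, p)
  expect_equal(nrow(st$bonds), 0)

  st$node <- c(1L, 2L)               # adjacent nodes, free surfaces
  st <- bridging_step(st, p)
  expect_equal(nrow(st$bonds), 1)
  expect_equal(sort(st$bonds[1, ]), c(1, 2))
  expect_true(all(surfaces_free(st, p) == 0))  # one surface each, consumed
})

test_that("single-node occupancy matches the exact birth-death chain", {
  # chain semantics: deaths ~ Binomial(n, k_d / n) per molecule with
  # occupancy-stabilized dissociation, then one association attempt by each
  # of the F free molecules with hazard min(1, k_a * A * (1 + n')), blocked
  # at N_max. With one node and pool P the occupancy is a Markov chain on
  # {0..N_max}; its stationary law is computed here by linear algebra and
  # compared with the simulated time-average.
  ka <- 0.002
  kd <- 0.1
  Nmax <- 15
  P <- 20
  p <- sim_params(n_nodes = 1, N_endog = P, k_a_endog = ka, k_d_endog = kd,
                  k_join = 0, N_max = Nmax)
  st <- new_sim_state(p, seed = 8)
  st$affinity[1] <- 1

  # exact transition matrix: deaths first, then binomial joins truncated
  # at the cap (joins from F draws at hazard h(n') frozen at post-death n)
  death_mat <- matrix(0, Nmax + 1, Nmax + 1)
  for (n in 0:Nmax) for (d in 0:n)
    death_mat[n + 1, n - d + 1] <- stats::dbinom(d, n, min(1, kd / max(n, 1)))
  join_mat <- matrix(0, Nmax + 1, Nmax + 1)
  for (n in 0:Nmax) {
    f <- P - n
    h <- min(1, ka * (1 + n))
    probs <- stats::dbinom(0:f, f, h)
    for (j in 0:f) {
      n2 <- min(Nmax, n + j)
      join_mat[n + 1, n2 + 1] <- join_mat[n + 1, n2 + 1] + probs[j + 1]
    }
  }
  trans <- death_mat %*% join_mat
  ev <- eigen(t(trans))
  stat <- abs(Re(ev$vectors[, which.max(Re(ev$values))]))
  stat <- stat / sum(stat)

  n_steps <- 2e4
  occ <- integer(n_steps)
  for (i in seq_len(n_steps)) {
    st <- binding_step(st, p)
    occ[i] <- sum(st$node > 0)
  }
  emp <- tabulate(occ + 1, nbins = Nmax + 1) / n_steps
  # autocorrelation-adjusted effective sample size (relaxation ~ 1/k_d)
  n_eff <- n_steps / (2 / kd)
  for (n in 0:Nmax) {
    se <- sqrt(stat[n + 1] * (1 - stat[n + 1]) / n_eff)
    expect_lt(abs(emp[n + 1] - stat[n + 1]), max(3 * se, 0.02))
  }
})
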