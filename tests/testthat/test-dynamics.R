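test_that("the origin is an equilibrium and derivative components sum to zero", {
  net <- two_pool_minimal()
  expect_equal(unname(vector_field(net, numeric(6))), numeric(6))
  set.seed(7)
  for (i in 1:10) {
    st <- random_interior_state(net)
    expect_equal(sum(vector_field(net, st)), 0, tolerance = 1e-14)
  }
})

test_that("vector field matches a hand evaluation term by term", {
  net <- two_pool_minimal()
  st <- network_state(net, sites = list(X1 = c(0.5, 0.5), Y1 = c(0.5, 0.5)),
                      pools = c(I = 0.5, II = 0.5))
  f <- vector_field(net, st)
  # entry flux 0.8*tanh(0.5)*(1-0.5) minus internal flux 1*0.5*(1-0.5)
  expect_equal(unname(f["X1.x1"]), 0.8 * tanh(0.5) * 0.5 - 0.25,
               tolerance = 1e-12)
  expect_equal(unname(f["X1.x2"]), 0.25 - 1.2 * 0.5, tolerance = 1e-12)
  expect_equal(unname(f["Y1.x1"]), 1 * 0.5 * 0.5 - 2 * 0.25, tolerance = 1e-12)
  expect_equal(unname(f["pool.I"]), 1 * 0.5 - 0.8 * tanh(0.5) * 0.5,
               tolerance = 1e-12)
})

test_that("the printed steady state annihilates the vector field", {
  net <- two_pool_minimal()
  f <- vector_field(net, two_pool_minimal_e)
  expect_lt(max(abs(f)), 5e-4)
})

test_that("analytic Jacobian agrees with finite differences and is Metzler", {
  set.seed(11)
  nets <- c(list(two_pool_minimal(), three_pool_ring()),
            replicate(3, random_two_pool(), simplify = FALSE))
  for (net in nets) {
    for (k in 1:4) {
      st <- random_interior_state(net)
      J <- network_jacobian(net, st)
      # cooperative: off-diagonal entries non-negative
      expect_true(all(J[row(J) != col(J)] >= 0))
      # conservation differential: columns sum to zero
      expect_lt(max(abs(colSums(J))), 1e-12)
      # finite-difference check
      h <- 1e-6
      Jfd <- sapply(seq_len(net$s), function(j) {
        ep <- st; em <- st
        ep[j] <- ep[j] + h; em[j] <- em[j] - h
        (vector_field(net, ep) - vector_field(net, em)) / (2 * h)
      })
      expect_lt(max(abs(J - Jfd)) / max(1, max(abs(J))), 1e-6)
    }
  }
})

test_that("integration conserves the first integral and stays in the state space", {
  net <- two_pool_minimal()
  init <- network_state(net, sites = list(X1 = c(0.5, 0.5), Y1 = c(0.5, 0.5)))
  traj <- integrate_network(net, init, t_final = 50)
  expect_lt(traj$conservation_drift, 1e-8 * 2)
  m <- as.matrix(traj$states[, -1])
  sites <- m[, 1:4]
  pools <- m[, 5:6]
  expect_true(all(sites >= -1e-9 & sites <= 1 + 1e-9))
  expect_true(all(pools >= -1e-9))
  # persistence: uniformly inside the boundary after t >= 1
  late <- m[traj$states$time >= 1, ]
  expect_true(all(late[, 1:4] > 0 & late[, 1:4] < 1))
  expect_true(all(late[, 5:6] > 0))
})

test_that("trajectories from different states in a level set share one limit", {
  net <- two_pool_minimal()
  a1 <- network_state(net, sites = list(X1 = c(0.5, 0.5), Y1 = c(0.5, 0.5)))
  a2 <- network_state(net, pools = c(I = 1, II = 1))
  s1 <- find_steady_state(net, initial = a1)
  s2 <- find_steady_state(net, initial = a2)
  expect_lt(max(abs(s1$state - s2$state)), 1e-8)
  expect_equal(unname(round(s1$state, 4)), two_pool_minimal_e)
})

test_that("starting at the steady state the trajectory stays put", {
  net <- two_pool_minimal()
  ss <- find_steady_state(net, r = 2)
  traj <- integrate_network(net, ss$state, t_final = 10)
  m <- as.matrix(traj$states[, -1])
  expect_lt(max(abs(sweep(m, 2, ss$state))), 1e-8)
})

test_that("the zero level set has the zero steady state", {
  net <- two_pool_minimal()
  ss <- find_steady_state(net, r = 0)
  expect_equal(unname(ss$state), numeric(6))
  expect_equal(ss$residual, 0)
})

test_that("steady states are strictly ordered in the level-set value", {
  net <- two_pool_minimal()
  states <- lapply(c(0.5, 1, 2, 4), function(r) find_steady_state(net, r)$state)
  for (i in 1:3) {
    expect_true(all(states[[i + 1]] > states[[i]]))
  }
})

test_that("steady-state flux identities hold along chains and across pools", {
  for (net in list(two_pool_minimal(), three_pool_ring())) {
    r <- if (net$s == 6) 2 else 4
    ss <- find_steady_state(net, r = r)
    sp <- split_state(net, ss$state)
    flux_in <- flux_out <- stats::setNames(numeric(length(net$pools)),
                                           net$pools)
    for (ch in net$chains) {
      x <- sp$sites[[ch$id]]
      lam <- ch$rates
      n <- ch$n_sites
      eff <- lam[1] * eval_input_fn(ch$input_fn, sp$pools[[ch$source_pool]])
      flux <- c(eff * (1 - x[1]),
                if (n > 1) lam[2:n] * x[1:(n - 1)] * (1 - x[2:n]),
                lam[n + 1] * x[n])
      # within-chain fluxes equal
      expect_lt(max(abs(flux - flux[1])), 1e-9)
      flux_out[ch$source_pool] <- flux_out[ch$source_pool] + flux[1]
      flux_in[ch$sink_pool] <- flux_in[ch$sink_pool] + flux[n + 1]
    }
    # per-pool inbound flux equals outbound flux
    expect_lt(max(abs(flux_in - flux_out)), 1e-9)
  }
})

test_that("conservation drift is reported and stays tiny even at loose tolerances", {
  # the field is structurally conservative (each flux enters with both
  # signs), so even a loose integration keeps Q essentially exact; the
  # drift monitor reports the realised value
  net <- two_pool_minimal()
  init <- network_state(net, pools = c(I = 1, II = 1))
  traj <- integrate_network(net, init, t_final = 50, rtol = 1e-6, atol = 1e-8)
  expect_true(is.finite(traj$conservation_drift))
  expect_lt(traj$conservation_drift, 1e-8)
})
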