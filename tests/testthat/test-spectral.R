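test_that("Jacobi matrices have the reciprocal-square-root band structure", {
  A <- jacobi_matrix(c(1, 1))
  expect_equal(A, matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3))
  B <- jacobi_matrix(c(4, 1))
  expect_equal(B[1, 2], 0.5)
  expect_equal(B[2, 3], 1)
  expect_equal(B, t(B))
  expect_true(all(diag(B) == 0))
  expect_error(jacobi_matrix(c(1, 0)), "positive")
})

test_that("Perron eigenpair matches closed forms for uniform chains", {
  # n = 1, rates (1, 1): sigma solves sigma(sigma^2 - 2) = 0 -> sqrt(2)
  sp <- perron_eigenpair(jacobi_matrix(c(1, 1)))
  expect_equal(sp$sigma, sqrt(2), tolerance = 1e-12)
  expect_true(all(sp$zeta > 0))
  expect_equal(sum(sp$zeta^2), 1)
  # uniform rates, dimension n: sigma = 2 cos(pi / (n + 3))
  for (n in c(1, 2, 5, 10)) {
    spn <- perron_eigenpair(jacobi_matrix(rep(1, n + 1)))
    expect_equal(spn$sigma, 2 * cos(pi / (n + 3)), tolerance = 1e-12)
    expect_true(all(spn$zeta > 0))
  }
})

test_that("chain densities from the eigenvector satisfy the flux relations", {
  # single site, rates (1, 1): balance lambda0 (1 - e) = lambda1 e -> 1/2
  css <- chain_steady_state(c(1, 1))
  expect_equal(css$densities, 0.5, tolerance = 1e-12)
  set.seed(3)
  for (k in 1:10) {
    n <- sample(1:8, 1)
    rates <- stats::runif(n + 1, 0.1, 5)
    css <- chain_steady_state(rates)
    e <- css$densities
    expect_true(all(e > 0 & e < 1))
    # flux through every link equals 1/sigma^2
    flux <- c(rates[1] * (1 - e[1]),
              if (n > 1) rates[2:n] * e[1:(n - 1)] * (1 - e[2:n]),
              rates[n + 1] * e[n])
    expect_lt(max(abs(flux - 1 / css$sigma^2)), 1e-10)
    expect_equal(steady_state_output_rate(css$sigma), css$flux)
  }
})

test_that("output rate follows 1/sigma^2 and is monotone in the rates", {
  expect_equal(steady_state_output_rate(sqrt(2)), 0.5)
  expect_equal(steady_state_output_rate(2 * cos(pi / 5)),
               1 / (4 * cos(pi / 5)^2))
  # lowering any one rate lowers the steady-state flux
  rates <- c(1, 2, 0.8, 1.5)
  R0 <- chain_steady_state(rates)$flux
  for (k in seq_along(rates)) {
    slow <- rates; slow[k] <- slow[k] * 0.5
    expect_lt(chain_steady_state(slow)$flux, R0)
  }
})

test_that("empty-pool entry yields the all-zero chain profile", {
  css <- chain_steady_state(c(1, 2, 3), effective_entry = 0)
  expect_equal(css$densities, c(0, 0))
  expect_equal(css$flux, 0)
})

test_that("spectral pool balance reproduces the reference steady states", {
  net <- two_pool_minimal()
  ss <- solve_pool_balance(net, 2)
  expect_equal(unname(round(ss$state, 4)), two_pool_minimal_e)
  expect_lt(ss$residual, 1e-10)
  expect_lt(abs(sum(ss$state) - 2), 1e-10)
  # effective X entry reproduces the printed first-site flux balance
  ez1 <- ss$state[["pool.I"]]
  cssx <- chain_steady_state(c(0.8, 1, 1.2),
                             effective_entry = 0.8 * tanh(ez1))
  expect_equal(unname(round(cssx$densities, 4)), c(0.3589, 0.2302))
  # three pools via the general path
  net3 <- three_pool_ring()
  ss3 <- solve_pool_balance(net3, 4)
  expect_lt(max(abs(ss3$state - three_pool_ring_e)), 6e-5)
  expect_equal(unname(solve_pool_balance(net, 0)$state), numeric(6))
})

test_that("spectral and ODE routes agree on random two-pool networks", {
  set.seed(23)
  rs <- c(0.5, 2, 5)
  for (k in 1:20) {
    net <- random_two_pool()
    r <- rs[(k %% 3) + 1]
    sp <- solve_pool_balance(net, r)
    od <- find_steady_state(net, r = r)
    expect_lt(max(abs(sp$state - od$state)), 1e-6)
  }
})

test_that("a symmetric network equalises the two pool levels", {
  set.seed(5)
  for (k in 1:5) {
    n <- sample(2:5, 1)
    rates <- stats::runif(n + 1, 0.2, 4)
    gname <- sample(c("identity", "tanh"), 1)
    net <- pool_network(
      c("I", "II"),
      list(chain_spec("X1", n, rates, "I", "II", input_fn(gname)),
           chain_spec("Y1", n, rates, "II", "I", input_fn(gname)))
    )
    ss <- solve_pool_balance(net, 3)
    expect_lt(abs(ss$state[["pool.I"]] - ss$state[["pool.II"]]), 1e-9)
    # the two mirrored chains carry identical profiles
    sp <- split_state(net, ss$state)
    expect_lt(max(abs(sp$sites$X1 - sp$sites$Y1)), 1e-9)
  }
})

test_that("m identical lanes reduce to one lane with scaled entry and pools", {
  # degree-one homogeneous pool outflow: m copies at total r match a
  # single copy with entry rates m*lambda0, m*eta0 at total r/m, pools
  # scaled by m
  lam <- c(0.9, 1.5, 0.7)
  eta <- c(1.1, 0.8, 2)
  for (m in 2:3) {
    xs <- lapply(seq_len(m), function(i)
      chain_spec(paste0("X", i), 2, lam, "I", "II"))
    ys <- lapply(seq_len(m), function(i)
      chain_spec(paste0("Y", i), 2, eta, "II", "I"))
    net_m <- pool_network(c("I", "II"), c(xs, ys))
    r <- 3
    e_m <- solve_pool_balance(net_m, r)
    net_1 <- pool_network(
      c("I", "II"),
      list(chain_spec("X1", 2, c(m * lam[1], lam[-1]), "I", "II"),
           chain_spec("Y1", 2, c(m * eta[1], eta[-1]), "II", "I"))
    )
    e_1 <- solve_pool_balance(net_1, r / m)
    sp_m <- split_state(net_m, e_m$state)
    sp_1 <- split_state(net_1, e_1$state)
    for (i in seq_len(m)) {
      expect_equal(sp_m$sites[[paste0("X", i)]], sp_1$sites$X1,
                   tolerance = 1e-8)
      expect_equal(sp_m$sites[[paste0("Y", i)]], sp_1$sites$Y1,
                   tolerance = 1e-8)
    }
    expect_equal(unname(sp_m$pools), unname(m * sp_1$pools),
                 tolerance = 1e-8)
  }
})
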