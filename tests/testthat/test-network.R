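test_that("network construction validates wiring and rates", {
  net <- two_pool_minimal()
  expect_s3_class(net, "rfm_network")
  expect_equal(net$s, 6)
  expect_equal(length(net$pools), 2)

  # a pool with inbound chains but no outbound chain is rejected
  expect_error(
    pool_network(
      pools = c("I", "II", "III"),
      chains = list(
        chain_spec("X1", 2, c(1, 1, 1), "I", "II"),
        chain_spec("Y1", 2, c(1, 1, 1), "II", "I"),
        chain_spec("Z1", 2, c(1, 1, 1), "I", "III")
      )
    ),
    "no outbound"
  )
  expect_error(
    pool_network("I", list(chain_spec("X1", 2, c(1, 1, 1), "I", "Q"))),
    "unknown pool"
  )
  expect_error(chain_spec("X1", 2, c(1, -1, 1), "I", "II"), "positive")
  expect_error(chain_spec("X1", 0, c(1), "I", "II"), "positive integer")
  expect_error(chain_spec("X1", 2, c(1, 1), "I", "II"), "length")
  # duplicate ids
  expect_error(
    pool_network(c("I", "II"), list(
      chain_spec("X1", 1, c(1, 1), "I", "II"),
      chain_spec("X1", 1, c(1, 1), "II", "I")
    )),
    "unique"
  )
})

test_that("self-loop chains are allowed with a warning", {
  expect_warning(
    net <- pool_network("P", list(
      chain_spec("C1", 2, c(1, 1, 1), "P", "P")
    )),
    "own source pool"
  )
  expect_equal(net$s, 3)
  expect_error(
    pool_network("P", list(chain_spec("C1", 2, c(1, 1, 1), "P", "P")),
                 allow_self_loops = FALSE),
    "self-loop"
  )
})

test_that("total occupancy is linear and layout-invariant", {
  net <- two_pool_minimal()
  expect_equal(total_occupancy(net, numeric(6)), 0)
  init <- network_state(net, sites = list(X1 = c(0.5, 0.5), Y1 = c(0.5, 0.5)))
  expect_equal(total_occupancy(net, init), 2)
  expect_equal(total_occupancy(net, two_pool_minimal_e), 2,
               tolerance = 5e-4 / 2)
  # permuting chain declaration order leaves Q unchanged
  net_rev <- pool_network(
    pools = c("I", "II"),
    chains = list(
      chain_spec("Y1", 2, c(1, 2, 1), "II", "I", input_fn("identity")),
      chain_spec("X1", 2, c(0.8, 1, 1.2), "I", "II", input_fn("tanh"))
    )
  )
  init_rev <- network_state(net_rev,
                            sites = list(Y1 = c(0.5, 0.5), X1 = c(0.5, 0.5)))
  expect_equal(total_occupancy(net_rev, init_rev), total_occupancy(net, init))
  # linearity
  set.seed(1)
  a <- random_interior_state(net)
  b <- random_interior_state(net)
  expect_equal(total_occupancy(net, 0.3 * a + 0.7 * b),
               0.3 * total_occupancy(net, a) + 0.7 * total_occupancy(net, b))
})

test_that("state packing validates ranges and names", {
  net <- two_pool_minimal()
  expect_error(network_state(net, sites = list(X1 = c(1.5, 0))), "\\[0, 1\\]")
  expect_error(network_state(net, pools = c(I = -1)), "non-negative")
  expect_error(network_state(net, sites = list(Q = c(0, 0))), "unknown chain")
  st <- network_state(net, sites = list(X1 = c(0.1, 0.2)), pools = c(II = 3))
  sp <- split_state(net, st)
  expect_equal(sp$sites$X1, c(0.1, 0.2))
  expect_equal(sp$sites$Y1, c(0, 0))
  expect_equal(sp$pools, c(I = 0, II = 3))
})

test_that("multigraph export preserves pools, edges and degree condition", {
  net <- three_pool_ring()
  g <- as_igraph(net)
  expect_equal(sort(igraph::V(g)$name), sort(net$pools))
  expect_equal(igraph::ecount(g), length(net$chains))
  expect_true(all(igraph::degree(g, mode = "in") >= 1))
  expect_true(all(igraph::degree(g, mode = "out") >= 1))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, path)
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g2), 3)
  expect_setequal(igraph::edge_attr(g2, "chain_id"), names(net$chains))
})

test_that("config files round-trip through YAML and JSON", {
  net <- two_pool_minimal()
  init <- network_state(net, sites = list(X1 = c(0.5, 0.5), Y1 = c(0.5, 0.5)))
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_network_config(net, path, initial_state = init, r = 2)
    cfg <- read_network_config(path)
    expect_equal(cfg$network$s, net$s)
    expect_equal(cfg$r, 2)
    expect_equal(unname(cfg$initial_state), unname(init))
    for (id in names(net$chains)) {
      expect_equal(cfg$network$chains[[id]]$rates, net$chains[[id]]$rates)
      expect_equal(cfg$network$chains[[id]]$input_fn$name,
                   net$chains[[id]]$input_fn$name)
    }
  }
})

test_that("packaged fixture configs load and carry printed reference data", {
  cfg <- read_network_config(
    system.file("extdata", "two_pool_minimal.yaml", package = "poolflow")
  )
  expect_equal(cfg$network$s, 6)
  expect_equal(cfg$r, 2)
  expect_equal(sum(cfg$initial_state), 2)
  cfg3 <- read_network_config(
    system.file("extdata", "three_pool_ring.yaml", package = "poolflow")
  )
  expect_equal(cfg3$network$s, 9)
  expect_equal(cfg3$r, 4)
})

test_that("schema violations name the offending field", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "pools: [I, II]",
    "chains:",
    "  - id: X1",
    "    n_sites: 2",
    "    source_pool: I",
    "    sink_pool: II",
    "  - id: Y1",
    "    n_sites: 2",
    "    rates: [1, 1, 1]",
    "    source_pool: II",
    "    sink_pool: I"
  ), path)
  expect_error(read_network_config(path), "X1.*rates|rates.*X1")
})
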