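# Reference networks used across the suite, built in code.

ones_rates <- function(n) rep(1, n + 1)

# minimal two-pool network: X1 (2 sites, tanh-fed) and Y1 (2 sites,
# identity-fed); at r = 2 its steady state is known to 4 decimals
two_pool_minimal <- function() {
  pool_network(
    pools = c("I", "II"),
    chains = list(
      chain_spec("X1", 2, c(0.8, 1, 1.2), "I", "II", input_fn("tanh")),
      chain_spec("Y1", 2, c(1, 2, 1), "II", "I", input_fn("identity"))
    )
  )
}

two_pool_minimal_e <- c(0.3589, 0.2302, 0.1909, 0.2763, 0.6023, 0.3414)

# three-pool directed ring, one 2-site lane per edge; reference steady
# state at r = 4
three_pool_ring <- function() {
  pool_network(
    pools = c("P1", "P2", "P3"),
    chains = list(
      chain_spec("R1", 2, c(0.8, 1, 2), "P1", "P2", input_fn("tanh")),
      chain_spec("R2", 2, c(1, 1.2, 0.1), "P2", "P3", input_fn("tanh")),
      chain_spec("R3", 2, c(0.1, 0.5, 1), "P3", "P1", input_fn("identity"))
    )
  )
}

three_pool_ring_e <- c(0.09514, 0.04541, 0.8249, 0.9082, 0.1998, 0.0908,
                       0.12613, 0.5745, 1.1350)

# periodically forced network: 3-site X lane and 2-site Y lane with
# sinusoidal rates of common period 1
periodic_network <- function() {
  pool_network(
    pools = c("I", "II"),
    chains = list(
      chain_spec("X1", 3, c(0.8, 3, 3, 3), "I", "II", input_fn("identity")),
      chain_spec("Y1", 2, c(1.2, 4, 1), "II", "I", input_fn("identity"))
    )
  )
}

periodic_rates <- function(net, freq = 1) {
  time_varying_rates(
    fns = list(
      X1 = function(t) c(0.8, 3, 3 + 2 * sin(2 * pi * freq * t),
                         3 - 2 * sin(2 * pi * freq * t)),
      Y1 = function(t) c(1.2, 4 - 2 * sin(2 * pi * freq * t), 1)
    ),
    period = 1 / freq, network = net
  )
}

# bottleneck scenarios for the rate-perturbation classification:
# (a) single 10-site X lane, two 5-site Y lanes, all rates 1 (r = 0.4)
sweep_net_free <- function() {
  pool_network(
    pools = c("I", "II"),
    chains = list(
      chain_spec("X1", 10, ones_rates(10), "I", "II"),
      chain_spec("Y1", 5, ones_rates(5), "II", "I"),
      chain_spec("Y2", 5, ones_rates(5), "II", "I")
    )
  )
}

# (b) 20-site X lane with a slow site 7 (rate 0.1), 10-site Y lane (r = 8)
sweep_net_bottleneck <- function() {
  rx <- ones_rates(20)
  rx[8] <- 0.1
  pool_network(
    pools = c("I", "II"),
    chains = list(
      chain_spec("X1", 20, rx, "I", "II"),
      chain_spec("Y1", 10, ones_rates(10), "II", "I")
    )
  )
}

# (c) two X lanes (10 sites with slow site 7, and 5 sites), two 5-site Y
# lanes (r = 8)
sweep_net_two_x <- function() {
  rx <- ones_rates(10)
  rx[8] <- 0.1
  pool_network(
    pools = c("I", "II"),
    chains = list(
      chain_spec("X1", 10, rx, "I", "II"),
      chain_spec("X2", 5, ones_rates(5), "I", "II"),
      chain_spec("Y1", 5, ones_rates(5), "II", "I"),
      chain_spec("Y2", 5, ones_rates(5), "II", "I")
    )
  )
}

# mixed-length two-pool network with jittered rates for MC validation:
# two X lanes (10 and 15 sites), one 15-site Y lane, identity pool
# outflow, 7 particles
mc_validation_network <- function(seed = 101) {
  set.seed(seed)
  pool_network(
    pools = c("I", "II"),
    chains = list(
      chain_spec("X1", 10, c(1, 1 + stats::runif(10)), "I", "II"),
      chain_spec("X2", 15, c(1, 2 + stats::runif(15)), "I", "II"),
      chain_spec("Y1", 15, c(1, 5 + stats::runif(15)), "II", "I")
    )
  )
}

# random small two-pool network for property ensembles
random_two_pool <- function(n_chains_each = NULL) {
  m <- if (is.null(n_chains_each)) sample(1:2, 1) else n_chains_each
  n <- if (is.null(n_chains_each)) sample(1:2, 1) else n_chains_each
  mk <- function(id, src, snk) {
    len <- sample(2:6, 1)
    chain_spec(id, len, stats::runif(len + 1, 0.1, 5), src, snk,
               input_fn(sample(c("identity", "tanh"), 1)))
  }
  chains <- c(
    lapply(seq_len(m), function(i) mk(paste0("X", i), "I", "II")),
    lapply(seq_len(n), function(i) mk(paste0("Y", i), "II", "I"))
  )
  pool_network(c("I", "II"), chains)
}

# a random interior state on a given network
random_interior_state <- function(net) {
  n_sites <- net$s - length(net$pools)
  st <- c(stats::runif(n_sites, 0.05, 0.95),
          stats::runif(length(net$pools), 0.1, 2))
  stats::setNames(st, net$state_names)
}
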