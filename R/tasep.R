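#' Stochastic exclusion-process simulation of a pool network
#'
#' Simulates the network as a continuous-time exclusion process: each
#' site holds at most one particle, a particle hops to the next site
#' only when that site is empty (waiting times exponential with the
#' chain's transition rates), the exit of a chain's last site deposits
#' the particle in the sink pool, and entry onto a chain's first site
#' consumes a particle from the source pool at rate
#' `lambda_0 * G(z)` with `z` the integer number of particles currently
#' in the pool. The mean-field (ODE) model is the deterministic
#' approximation of this process, so time-averaged site occupancies from
#' long runs should track the ODE steady-state profile.
#'
#' The run starts with all particles in the pools and empty chains,
#' executes `n_steps` events, discards the first `burn_in` events, and
#' time-averages occupancies over the remainder (occupied duration
#' divided by retained duration). Runs are reproducible for a fixed
#' seed.
#'
#' @inheritParams network_state
#' @param total_particles Non-negative integer particle count; a
#'   fractional value is rounded to the nearest integer with a warning.
#' @param n_steps Number of events to simulate.
#' @param burn_in Events discarded before averaging.
#' @param seed Optional integer seed.
#' @param initial_pools Optional named integer vector of initial pool
#'   counts summing to `total_particles`; defaults to an even split
#'   (remainder to the first pools).
#' @return An object of class `rfm_mc` with `site_means` (tibble:
#'   `chain`, `site`, `occupancy`), `pool_means` (named vector),
#'   `n_events` and `total_particles`.
#' @export
simulate_exclusion <- function(network, total_particles, n_steps = 1e7,
                               burn_in = 1e4, seed = NULL,
                               initial_pools = NULL) {
  stopifnot(inherits(network, "rfm_network"), burn_in < n_steps)
  if (abs(total_particles - round(total_particles)) > 0) {
    warning("`total_particles` rounded to the nearest integer.")
  }
  q <- as.integer(round(total_particles))
  if (q < 0) stop("`total_particles` must be non-negative.")
  M <- length(network$pools)
  if (is.null(initial_pools)) {
    base <- q %/% M
    extra <- q %% M
    pool_init <- rep(base, M) + c(rep(1L, extra), rep(0L, M - extra))
  } else {
    pool_init <- as.integer(initial_pools[network$pools])
    if (anyNA(pool_init) || sum(pool_init) != q || any(pool_init < 0)) {
      stop("`initial_pools` must be non-negative integers over all pools, ",
           "summing to `total_particles`.")
    }
  }
  chains <- network$chains
  ns <- vapply(chains, `[[`, integer(1), "n_sites")
  gtype <- vapply(chains, function(ch) {
    switch(ch$input_fn$name,
           identity = 0L, tanh = 1L, scaled_identity = 2L,
           stop("MC simulation supports identity, tanh and scaled_identity ",
                "input functions."))
  }, integer(1))
  gparam <- vapply(chains, function(ch) {
    if (ch$input_fn$name == "scaled_identity") ch$input_fn$params$c else 0
  }, numeric(1))
  pool_of <- stats::setNames(seq_along(network$pools) - 1L, network$pools)
  if (!is.null(seed)) set.seed(seed)
  res <- tasep_mc_run(
    ns = unname(ns),
    rates = unlist(lapply(chains, `[[`, "rates"), use.names = FALSE),
    rate_offset = c(0L, cumsum(ns + 1L))[seq_along(ns)],
    site_offset = c(0L, cumsum(ns))[seq_along(ns)],
    src = unname(pool_of[vapply(chains, `[[`, character(1), "source_pool")]),
    snk = unname(pool_of[vapply(chains, `[[`, character(1), "sink_pool")]),
    gtype = unname(gtype), gparam = unname(gparam),
    pool_init = pool_init,
    n_steps = n_steps, burn_in = burn_in
  )
  site_means <- tibble::tibble(
    chain = rep(names(chains), ns),
    site = unlist(lapply(ns, seq_len), use.names = FALSE),
    occupancy = res$site_means
  )
  structure(
    list(site_means = site_means,
         pool_means = stats::setNames(res$pool_means, network$pools),
         n_events = res$n_events,
         total_particles = q,
         network = network),
    class = "rfm_mc"
  )
}

#' @export
print.rfm_mc <- function(x, ...) {
  cat("<rfm_mc: ", x$total_particles, " particles, ",
      format(x$n_events, big.mark = ","), " events>\n", sep = "")
  invisible(x)
}

#' Correlate Monte Carlo occupancies with the mean-field steady state
#'
#' Pearson correlation (with p-value) between the flattened per-site
#' time-averaged occupancies of an exclusion-process run and the
#' site densities of an ODE/spectral steady state on the same network.
#'
#' @param mc An `rfm_mc` result.
#' @param ss An `rfm_steady_state` for the same network.
#' @return A tibble with `estimate` (Pearson r), `p.value`, `n` (number
#'   of sites) and `max_abs_diff`.
#' @export
compare_to_ode <- function(mc, ss) {
  stopifnot(inherits(mc, "rfm_mc"), inherits(ss, "rfm_steady_state"))
  network <- mc$network
  if (length(ss$state) != network$s) {
    stop("steady state does not match the MC network shape.")
  }
  sp <- split_state(network, ss$state)
  ode_dens <- unlist(sp$sites, use.names = FALSE)
  mc_dens <- mc$site_means$occupancy
  if (length(ode_dens) != length(mc_dens)) {
    stop("mismatched site counts.")
  }
  if (stats::sd(mc_dens) == 0 || stats::sd(ode_dens) == 0) {
    stop("zero-variance densities; correlation undefined.")
  }
  ct <- stats::cor.test(mc_dens, ode_dens, method = "pearson")
  tibble::tibble(
    estimate = unname(ct$estimate),
    p.value = ct$p.value,
    n = length(mc_dens),
    max_abs_diff = max(abs(mc_dens - ode_dens))
  )
}
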