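#' Generate a random pool network
#'
#' Builds the randomised benchmark topologies used for validation
#' ensembles. For `n_pools >= 3` the chains form a directed ring: chain
#' `i` runs from pool `i` to pool `i + 1` (mod `M`). For `n_pools == 2`
#' the chains alternate direction (odd chains pool 1 -> pool 2, even
#' chains pool 2 -> pool 1), giving the bipartite two-pool wiring; at
#' least two chains are then required so each pool has traffic both
#' ways.
#'
#' Entry rates are `entry_rates` (recycled, default 1); every internal
#' and exit rate of chain `i` is drawn as `base_rates[i] + U(0, 1)`, so
#' all generated rates lie in `[base, base + 1)`. Identical seeds give
#' identical networks.
#'
#' @param n_pools Number of pools (`M >= 2`).
#' @param chain_dims Integer vector of chain lengths (one chain each).
#' @param base_rates Per-chain base value `b_i` for the jittered rates
#'   (recycled).
#' @param entry_rates Per-chain entry rate `lambda_0` (recycled).
#' @param input_fn_name Pool outflow function for every chain.
#' @param seed Optional integer seed.
#' @return A [pool_network()].
#' @examples
#' net <- random_pool_network(3, c(20, 30, 40), c(0.5, 2, 1), seed = 1)
#' @export
random_pool_network <- function(n_pools, chain_dims, base_rates,
                                entry_rates = 1,
                                input_fn_name = "identity", seed = NULL) {
  stopifnot(n_pools >= 2, all(chain_dims >= 1))
  if (n_pools == 2 && length(chain_dims) < 2) {
    stop("a two-pool network needs at least two chains.")
  }
  if (n_pools > 2 && length(chain_dims) != n_pools) {
    stop("ring wiring requires one chain per pool.")
  }
  if (!is.null(seed)) set.seed(seed)
  base_rates <- rep_len(base_rates, length(chain_dims))
  entry_rates <- rep_len(entry_rates, length(chain_dims))
  pools <- paste0("P", seq_len(n_pools))
  chains <- lapply(seq_along(chain_dims), function(i) {
    n <- chain_dims[i]
    rates <- c(entry_rates[i], base_rates[i] + stats::runif(n))
    if (n_pools == 2) {
      src <- pools[if (i %% 2 == 1) 1L else 2L]
      snk <- pools[if (i %% 2 == 1) 2L else 1L]
    } else {
      src <- pools[i]
      snk <- pools[(i %% n_pools) + 1L]
    }
    chain_spec(paste0("C", i), n, rates, src, snk, input_fn(input_fn_name))
  })
  pool_network(pools, chains)
}
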