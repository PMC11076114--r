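#' Specify one excluded-flow lane (RFM chain)
#'
#' A chain is a lattice of `n_sites` sites along which particles flow
#' unidirectionally under simple exclusion, the mean-field picture of a
#' TASEP lane. It is characterised by `n_sites + 1` positive transition
#' rates (units 1/time): the entry rate `rates[1]`, the site-to-site rates,
#' and the exit rate `rates[n_sites + 1]`. The chain draws its entering
#' particles from `source_pool` — the actual entry flux is
#' `rates[1] * G(z_source) * (1 - x_1)` — and deposits its output into
#' `sink_pool`.
#'
#' @param id Chain identifier (string, unique within a network).
#' @param n_sites Number of sites (positive integer).
#' @param rates Numeric vector of `n_sites + 1` strictly positive rates.
#' @param source_pool,sink_pool Pool identifiers.
#' @param input_fn An [input_fn()] object giving the pool outflow function
#'   `G` of the source pool as seen by this chain.
#' @return An object of class `rfm_chain`.
#' @examples
#' chain_spec("X1", 2, c(0.8, 1, 1.2), "I", "II", input_fn("tanh"))
#' @export
chain_spec <- function(id, n_sites, rates, source_pool, sink_pool,
                       input_fn = poolflow::input_fn("identity")) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.numeric(n_sites) || length(n_sites) != 1L || n_sites < 1 ||
      n_sites != round(n_sites)) {
    stop("`n_sites` must be a positive integer.")
  }
  n_sites <- as.integer(n_sites)
  if (!is.numeric(rates) || length(rates) != n_sites + 1L) {
    stop("chain `", id, "`: `rates` must have length n_sites + 1 (",
         n_sites + 1L, ").")
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("chain `", id, "`: all transition rates must be strictly positive.")
  }
  stopifnot(inherits(input_fn, "rfm_input_fn"))
  structure(
    list(id = id, n_sites = n_sites, rates = as.numeric(rates),
         source_pool = as.character(source_pool),
         sink_pool = as.character(sink_pool),
         input_fn = input_fn),
    class = "rfm_chain"
  )
}

#' Build a pool network of excluded-flow lanes
#'
#' Assembles `M` pools and `N` chains into a closed network, represented
#' as a directed multigraph whose nodes are pools and whose edges are
#' chains. Every pool must feed at least one chain and receive the output
#' of at least one chain, so that particles keep circulating; the total
#' number of particles (pool occupancies plus site densities) is conserved
#' by the dynamics.
#'
#' Declaration order fixes the state-vector layout: the sites of each
#' chain in order, chain by chain, followed by the pool levels in order.
#'
#' @param pools Character vector of pool identifiers (unique).
#' @param chains List of [chain_spec()] objects (unique ids).
#' @param allow_self_loops A chain whose source and sink coincide is a
#'   self-loop edge of the multigraph; it is accepted with a warning by
#'   default, or rejected when `FALSE`.
#' @return An object of class `rfm_network` with elements `pools`,
#'   `chains`, `n_sites` (per chain), `s` (state dimension) and
#'   `state_names`.
#' @examples
#' net <- pool_network(
#'   pools = c("I", "II"),
#'   chains = list(
#'     chain_spec("X1", 2, c(0.8, 1, 1.2), "I", "II", input_fn("tanh")),
#'     chain_spec("Y1", 2, c(1, 2, 1), "II", "I", input_fn("identity"))
#'   )
#' )
#' net$s # 6 state variables
#' @export
pool_network <- function(pools, chains, allow_self_loops = TRUE) {
  stopifnot(is.character(pools), length(pools) >= 1L)
  if (anyDuplicated(pools)) stop("pool identifiers must be unique.")
  if (!is.list(chains) || !length(chains) ||
      !all(vapply(chains, inherits, logical(1), "rfm_chain"))) {
    stop("`chains` must be a non-empty list of chain_spec objects.")
  }
  ids <- vapply(chains, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("chain identifiers must be unique.")
  src <- vapply(chains, `[[`, character(1), "source_pool")
  snk <- vapply(chains, `[[`, character(1), "sink_pool")
  bad <- setdiff(c(src, snk), pools)
  if (length(bad)) {
    stop("unknown pool reference: ", paste(unique(bad), collapse = ", "))
  }
  loops <- src == snk
  if (any(loops)) {
    if (!allow_self_loops) {
      stop("self-loop chain (source == sink): ",
           paste(ids[loops], collapse = ", "))
    }
    warning("chain(s) ", paste(ids[loops], collapse = ", "),
            " feed back into their own source pool.")
  }
  no_out <- setdiff(pools, src)
  if (length(no_out)) {
    stop("pool(s) with no outbound chain: ", paste(no_out, collapse = ", "))
  }
  no_in <- setdiff(pools, snk)
  if (length(no_in)) {
    stop("pool(s) with no inbound chain: ", paste(no_in, collapse = ", "))
  }
  n_sites <- vapply(chains, `[[`, integer(1), "n_sites")
  names(chains) <- ids
  state_names <- c(
    unlist(lapply(chains, function(ch) {
      paste0(ch$id, ".x", seq_len(ch$n_sites))
    }), use.names = FALSE),
    paste0("pool.", pools)
  )
  structure(
    list(pools = pools, chains = chains,
         n_sites = stats::setNames(n_sites, ids),
         s = sum(n_sites) + length(pools),
         state_names = state_names),
    class = "rfm_network"
  )
}

#' @export
print.rfm_network <- function(x, ...) {
  cat("<rfm_network: ", length(x$pools), " pools, ", length(x$chains),
      " chains, ", x$s, " state variables>\n", sep = "")
  for (ch in x$chains) {
    cat("  ", ch$id, ": ", ch$source_pool, " -> ", ch$sink_pool,
        " (", ch$n_sites, " sites, G = ", ch$input_fn$name, ")\n", sep = "")
  }
  invisible(x)
}

# index of the first site of each chain in the state vector, and pool offsets
state_layout <- function(network) {
  n <- network$n_sites
  offsets <- c(0L, cumsum(n))[seq_along(n)]
  names(offsets) <- names(n)
  list(
    chain_offset = offsets,
    pool_index = stats::setNames(
      sum(n) + seq_along(network$pools), network$pools
    )
  )
}

#' Assemble a network state vector
#'
#' Packs per-chain site densities and pool levels into the canonical
#' state-vector layout (chain sites in declaration order, then pools).
#' Site densities must lie in `[0, 1]`; pool levels must be non-negative.
#'
#' @param network An [pool_network()] object.
#' @param sites Named list, one numeric vector of length `n_sites` per
#'   chain; chains omitted default to all-zero.
#' @param pools Named numeric vector of pool levels; omitted pools default
#'   to zero.
#' @return Named numeric vector of length `network$s`.
#' @export
network_state <- function(network, sites = list(), pools = numeric()) {
  stopifnot(inherits(network, "rfm_network"))
  st <- stats::setNames(numeric(network$s), network$state_names)
  lay <- state_layout(network)
  for (id in names(sites)) {
    ch <- network$chains[[id]]
    if (is.null(ch)) stop("unknown chain `", id, "`.")
    v <- sites[[id]]
    if (length(v) != ch$n_sites) {
      stop("chain `", id, "`: expected ", ch$n_sites, " site densities.")
    }
    st[lay$chain_offset[[id]] + seq_len(ch$n_sites)] <- v
  }
  for (p in names(pools)) {
    if (!p %in% network$pools) stop("unknown pool `", p, "`.")
    st[lay$pool_index[[p]]] <- pools[[p]]
  }
  validate_state(network, st)
  st
}

validate_state <- function(network, state, tol = 1e-9) {
  if (length(state) != network$s) {
    stop("state has length ", length(state), ", expected ", network$s, ".")
  }
  n_site_vars <- network$s - length(network$pools)
  x <- state[seq_len(n_site_vars)]
  z <- state[n_site_vars + seq_along(network$pools)]
  if (any(x < -tol) || any(x > 1 + tol)) {
    stop("site densities must lie in [0, 1].")
  }
  if (any(z < -tol)) stop("pool levels must be non-negative.")
  invisible(state)
}

#' Split a state vector into per-chain densities and pool levels
#'
#' @inheritParams network_state
#' @param state State vector in canonical layout.
#' @return List with `sites` (named list per chain) and `pools` (named
#'   numeric vector).
#' @export
split_state <- function(network, state) {
  lay <- state_layout(network)
  sites <- lapply(network$chains, function(ch) {
    unname(state[lay$chain_offset[[ch$id]] + seq_len(ch$n_sites)])
  })
  pools <- stats::setNames(unname(state[lay$pool_index]), network$pools)
  list(sites = sites, pools = pools)
}

#' Total particle occupancy (the conserved first integral)
#'
#' The network is closed, so the sum of all pool levels and all site
#' densities is a first integral of the dynamics: trajectories stay on
#' the level set where they start, and each level set carries exactly one
#' steady state.
#'
#' @inheritParams split_state
#' @return The scalar total occupancy `Q(state) >= 0`.
#' @examples
#' net <- pool_network(
#'   pools = c("I", "II"),
#'   chains = list(
#'     chain_spec("X1", 2, c(0.8, 1, 1.2), "I", "II", input_fn("tanh")),
#'     chain_spec("Y1", 2, c(1, 2, 1), "II", "I")
#'   )
#' )
#' total_occupancy(net, network_state(net, sites = list(X1 = c(0.5, 0.5),
#'                                                      Y1 = c(0.5, 0.5))))
#' @export
total_occupancy <- function(network, state) {
  stopifnot(inherits(network, "rfm_network"), length(state) == network$s)
  sum(state)
}

#' Convert a pool network to an igraph multigraph
#'
#' Nodes are pools; each chain becomes one directed edge from its source
#' pool to its sink pool, carrying the chain id, site count and rates as
#' edge attributes.
#'
#' @inheritParams network_state
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "rfm_network"))
  edges <- dplyr::bind_rows(lapply(network$chains, function(ch) {
    tibble::tibble(
      from = ch$source_pool, to = ch$sink_pool, chain_id = ch$id,
      n_sites = ch$n_sites,
      rates = paste(ch$rates, collapse = ","),
      input_fn = ch$input_fn$name
    )
  }))
  igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = network$pools)
  )
}

#' Export the pool multigraph as GraphML
#'
#' @inheritParams network_state
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
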