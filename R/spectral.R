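#' Jacobi matrix of a chain
#'
#' The steady state of a single excluded-flow chain with rates
#' `lambda_0, ..., lambda_n` has a spectral representation through the
#' `(n + 2) x (n + 2)` symmetric tridiagonal matrix with zero diagonal
#' and off-diagonal entries `lambda_k^(-1/2)`. For a chain fed by a pool
#' the entry rate is the effective rate `lambda_0 * G(e_z)`.
#'
#' @param rates Positive rates `lambda_0, ..., lambda_n` (the first entry
#'   already effective if the chain is pool-fed).
#' @return The symmetric, non-negative, irreducible tridiagonal matrix.
#' @examples
#' jacobi_matrix(c(1, 1)) # 3x3, all off-diagonals 1
#' @export
jacobi_matrix <- function(rates) {
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all rates must be strictly positive.")
  }
  n2 <- length(rates) + 1L
  A <- matrix(0, n2, n2)
  off <- rates^(-0.5)
  A[cbind(seq_len(n2 - 1L), 2:n2)] <- off
  A[cbind(2:n2, seq_len(n2 - 1L))] <- off
  A
}

#' Perron eigenpair of a Jacobi matrix
#'
#' The matrix is non-negative, symmetric and irreducible, so it has a
#' simple maximal eigenvalue `sigma > 0` with a strictly positive
#' eigenvector (Perron–Frobenius). The eigenvector is returned with unit
#' 2-norm and its sign fixed so the first component is positive.
#'
#' @param A A matrix from [jacobi_matrix()].
#' @return List with `sigma` and `zeta` (class `rfm_spectrum`).
#' @export
perron_eigenpair <- function(A) {
  es <- eigen(A, symmetric = TRUE)
  sigma <- es$values[1L]
  zeta <- es$vectors[, 1L]
  if (zeta[1L] < 0) zeta <- -zeta
  if (any(zeta <= 0)) {
    stop("degenerate Perron eigenvector; eigensolver failure.")
  }
  structure(list(sigma = sigma, zeta = zeta), class = "rfm_spectrum")
}

#' Steady-state density profile of one chain
#'
#' Given the chain rates and the effective entry rate
#' `lambda_0 * G(e_z)`, the steady-state site densities are ratios of
#' consecutive Perron eigenvector entries,
#' `e_j = zeta_{j+2} / (lambda_j^(1/2) * sigma * zeta_{j+1})`, and the
#' steady-state flux through every link equals `1 / sigma^2`. A zero
#' effective entry rate (empty source pool) yields the all-zero profile.
#'
#' @param rates Chain rates `lambda_0, ..., lambda_n`.
#' @param effective_entry Effective entry rate replacing `rates[1]`;
#'   defaults to `rates[1]` (isolated chain with `G = 1`).
#' @return List with `densities` (length `n`, each in `(0, 1)`), `sigma`
#'   and `flux` (`= 1 / sigma^2`).
#' @examples
#' chain_steady_state(c(1, 1))$densities # single site, e = 1/2
#' @export
chain_steady_state <- function(rates, effective_entry = rates[1L]) {
  n <- length(rates) - 1L
  if (effective_entry <= 0) {
    return(list(densities = numeric(n), sigma = NA_real_, flux = 0))
  }
  eff_rates <- c(effective_entry, rates[-1L])
  sp <- perron_eigenpair(jacobi_matrix(eff_rates))
  lam <- rates[-1L] # lambda_1, ..., lambda_n
  j <- seq_len(n)
  dens <- sp$zeta[j + 2L] / (sqrt(lam) * sp$sigma * sp$zeta[j + 1L])
  list(densities = dens, sigma = sp$sigma, flux = 1 / sp$sigma^2)
}

#' Steady-state output rate from the Perron eigenvalue
#'
#' The steady-state flux of a chain — equal across all its links,
#' including the exit link `lambda_n e_n` — is `R = 1 / sigma^2`.
#'
#' @param spectrum An `rfm_spectrum` from [perron_eigenpair()], or a
#'   numeric `sigma`.
#' @return The flux `R`.
#' @export
steady_state_output_rate <- function(spectrum) {
  sigma <- if (inherits(spectrum, "rfm_spectrum")) spectrum$sigma else spectrum
  stopifnot(is.numeric(sigma), sigma > 0)
  1 / sigma^2
}

# chain output flux / total occupancy as a function of effective entry rate
chain_flux_at <- function(rates, eff) {
  chain_steady_state(rates, eff)$flux
}
chain_occupancy_at <- function(rates, eff) {
  sum(chain_steady_state(rates, eff)$densities)
}

# effective entry rate of a chain given its source-pool level
chain_eff <- function(ch, z) ch$rates[1L] * eval_input_fn(ch$input_fn, z)

#' Steady state by the spectral route (pool balance)
#'
#' Computes the steady state of the whole network without integrating
#' the dynamics. Given candidate pool levels, each chain's profile and
#' flux follow from its Perron eigenpair at the effective entry rate
#' `lambda_0 * G(e_z)`; the pool levels are then pinned down by the
#' per-pool flux balances (inflow = outflow at steady state) together
#' with the conservation constraint (total occupancy `= r`).
#'
#' For a two-pool network without self-loops the solve is a guaranteed
#' nested bisection in the two pool levels, exploiting strict
#' monotonicity of chain flux and occupancy in the effective entry rate.
#' For `M >= 3` pools (or self-loops) a damped Newton iteration on the
#' `M` pool levels is used, with a relaxation fallback for the initial
#' guess.
#'
#' @inheritParams network_state
#' @param r Level-set value (total particle count), `r >= 0`.
#' @param tol Residual tolerance for the balance and conservation
#'   equations.
#' @return An `rfm_steady_state` (method `"spectral"`); its
#'   `diagnostics` contain per-chain `sigma` and flux.
#' @export
solve_pool_balance <- function(network, r, tol = 1e-12) {
  stopifnot(inherits(network, "rfm_network"), is.numeric(r), r >= 0)
  if (r == 0) {
    return(structure(
      list(state = stats::setNames(numeric(network$s), network$state_names),
           r = 0, residual = 0, method = "spectral",
           diagnostics = list()),
      class = "rfm_steady_state"
    ))
  }
  src <- vapply(network$chains, `[[`, character(1), "source_pool")
  snk <- vapply(network$chains, `[[`, character(1), "sink_pool")
  two_pool <- length(network$pools) == 2L && !any(src == snk)
  z <- if (two_pool) {
    solve_two_pool(network, r, tol)
  } else {
    solve_m_pool(network, r, tol)
  }
  assemble_spectral_state(network, z, r)
}

# nested bisection for the bipartite two-pool network
solve_two_pool <- function(network, r, tol) {
  p1 <- network$pools[1L]
  xch <- Filter(function(ch) ch$source_pool == p1, network$chains)
  ych <- Filter(function(ch) ch$source_pool != p1, network$chains)
  out_x <- function(z1) sum(vapply(xch, function(ch)
    chain_flux_at(ch$rates, chain_eff(ch, z1)), numeric(1)))
  out_y <- function(z2) sum(vapply(ych, function(ch)
    chain_flux_at(ch$rates, chain_eff(ch, z2)), numeric(1)))
  occ_x <- function(z1) sum(vapply(xch, function(ch)
    chain_occupancy_at(ch$rates, chain_eff(ch, z1)), numeric(1)))
  occ_y <- function(z2) sum(vapply(ych, function(ch)
    chain_occupancy_at(ch$rates, chain_eff(ch, z2)), numeric(1)))
  # inner solve: z2 with out_y(z2) = target (out_y strictly increasing);
  # Inf when the target exceeds the saturating capacity of the Y side
  z2_of <- function(target) {
    if (target <= 0) return(0)
    hi <- 1
    while (out_y(hi) < target) {
      hi <- hi * 2
      if (hi > 1e9) return(Inf)
    }
    stats::uniroot(function(z2) out_y(z2) - target, c(0, hi),
                   tol = 1e-15)$root
  }
  # outer residual: total occupancy minus r, strictly increasing in z1
  g <- function(z1) {
    z2 <- z2_of(out_x(z1))
    if (!is.finite(z2)) return(Inf)
    z1 + z2 + occ_x(z1) + occ_y(z2) - r
  }
  lo <- 0; hi <- r
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (is.finite(gm) && abs(gm) < tol) { lo <- hi <- mid; break }
    if (gm > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-16 * max(1, r)) break
  }
  z1 <- (lo + hi) / 2
  z2 <- z2_of(out_x(z1))
  stats::setNames(c(z1, z2), network$pools)
}

# general M-pool solve: damped Newton on the pool levels
solve_m_pool <- function(network, r, tol) {
  M <- length(network$pools)
  src <- vapply(network$chains, `[[`, character(1), "source_pool")
  snk <- vapply(network$chains, `[[`, character(1), "sink_pool")
  resid <- function(z) {
    z <- pmax(z, 0)
    names(z) <- network$pools
    flux <- vapply(network$chains, function(ch)
      chain_flux_at(ch$rates, chain_eff(ch, z[[ch$source_pool]])), numeric(1))
    occ <- vapply(network$chains, function(ch)
      chain_occupancy_at(ch$rates, chain_eff(ch, z[[ch$source_pool]])), numeric(1))
    balance <- vapply(network$pools, function(p) {
      sum(flux[snk == p]) - sum(flux[src == p])
    }, numeric(1))
    c(balance[seq_len(M - 1L)], sum(z) + sum(occ) - r)
  }
  newton <- function(z0) {
    z <- z0
    f <- resid(z)
    for (it in seq_len(120L)) {
      if (max(abs(f)) < tol) break
      J <- matrix(0, M, M)
      h <- pmax(1e-7 * pmax(abs(z), 1e-3), 1e-10)
      for (j in seq_len(M)) {
        zp <- z; zp[j] <- z[j] + h[j]
        zm <- z; zm[j] <- max(z[j] - h[j], 0)
        J[, j] <- (resid(zp) - resid(zm)) / (zp[j] - zm[j])
      }
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      alpha <- 1
      repeat {
        z_new <- pmax(z - alpha * step, 0)
        f_new <- resid(z_new)
        if (max(abs(f_new)) < max(abs(f)) || alpha < 1e-6) break
        alpha <- alpha / 2
      }
      if (max(abs(f_new)) >= max(abs(f)) && alpha < 1e-6) return(NULL)
      z <- z_new; f <- f_new
    }
    if (max(abs(f)) < max(tol * 100, 1e-10)) z else NULL
  }
  z <- newton(rep(r / (2 * M), M))
  if (is.null(z)) {
    # fall back to a coarse relaxation of the dynamics for the guess
    ss <- find_steady_state(network, r = r, tol = 1e-10, switch_tol = 1e-8)
    z0 <- split_state(network, ss$state)$pools
    z <- newton(as.numeric(z0))
    if (is.null(z)) stop("pool-balance Newton iteration did not converge.")
  }
  stats::setNames(z, network$pools)
}

# build the full steady-state vector from solved pool levels
assemble_spectral_state <- function(network, z, r) {
  lay <- state_layout(network)
  st <- stats::setNames(numeric(network$s), network$state_names)
  sigma <- flux <- stats::setNames(numeric(length(network$chains)),
                                   names(network$chains))
  for (ch in network$chains) {
    css <- chain_steady_state(ch$rates, chain_eff(ch, z[[ch$source_pool]]))
    st[lay$chain_offset[[ch$id]] + seq_len(ch$n_sites)] <- css$densities
    sigma[ch$id] <- css$sigma
    flux[ch$id] <- css$flux
  }
  st[lay$pool_index] <- z
  residual <- max(abs(vector_field_unsafe(network, st)))
  structure(
    list(state = st, r = r, residual = residual, method = "spectral",
         diagnostics = list(sigma = sigma, flux = flux,
                            pool_levels = z,
                            conservation_gap = sum(st) - r)),
    class = "rfm_steady_state"
  )
}
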