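#' Periodic time-varying transition rates
#'
#' Wraps per-chain rate functions of time for the periodically forced
#' network. Every rate must be continuous, `T`-periodic with a common
#' period, and uniformly bounded away from zero; these conditions are
#' verified numerically on a sampling grid rather than assumed. Under
#' them every trajectory entrains: it converges to a periodic orbit with
#' the same period `T`.
#'
#' @param fns Named list (one entry per chain id) of functions `f(t)`
#'   returning the full rate vector (length `n_sites + 1`) of that chain
#'   at time `t`. Chains omitted keep their constant rates.
#' @param period The common period `T > 0`.
#' @param network The [pool_network()] the rates apply to.
#' @param n_check Number of grid points used to verify positivity and
#'   periodicity on `[0, T)`.
#' @return An object of class `rfm_rates`.
#' @export
time_varying_rates <- function(fns, period, network, n_check = 64L) {
  stopifnot(is.list(fns), length(fns) >= 1L, period > 0,
            inherits(network, "rfm_network"))
  unknown <- setdiff(names(fns), names(network$chains))
  if (length(unknown)) stop("unknown chain(s): ", paste(unknown, collapse = ", "))
  grid <- seq(0, period, length.out = n_check + 1L)[-(n_check + 1L)]
  for (id in names(fns)) {
    f <- fns[[id]]
    if (!is.function(f)) stop("rates for chain `", id, "` must be a function of t.")
    len <- network$chains[[id]]$n_sites + 1L
    for (t0 in grid) {
      v <- f(t0)
      if (length(v) != len) {
        stop("rates(", t0, ") for chain `", id, "` has length ", length(v),
             ", expected ", len, ".")
      }
      if (any(v <= 0)) {
        stop("rates for chain `", id, "` must stay strictly positive.")
      }
      if (max(abs(f(t0 + period) - v)) > 1e-8 * max(1, max(abs(v)))) {
        stop("rates for chain `", id, "` are not ", period, "-periodic.")
      }
    }
  }
  structure(list(fns = fns, period = period), class = "rfm_rates")
}

# rates for every chain at time t: named list of numeric vectors
rates_at <- function(network, rates, t) {
  out <- lapply(network$chains, `[[`, "rates")
  if (!is.null(rates)) {
    for (id in names(rates$fns)) out[[id]] <- rates$fns[[id]](t)
  }
  out
}

#' Right-hand side of the network ODEs
#'
#' For a chain fed by pool `j` with densities `x` and rates `lambda`, the
#' flow out of site `m` is `lambda_m x_m (1 - x_{m+1})` (exclusion: flow
#' slows as the next site fills), the entry flow is
#' `lambda_0 G(z_j) (1 - x_1)` and the exit flow is `lambda_n x_n`, which
#' is deposited into the sink pool. Each pool's level changes by the sum
#' of inbound exit flows minus the sum of outbound entry flows. Every
#' flux appears once with each sign, so the components of the derivative
#' sum to zero exactly: the total occupancy is conserved.
#'
#' @inheritParams split_state
#' @param t Time (only relevant for time-varying rates).
#' @param rates `NULL` for the chain's constant rates, or a
#'   [time_varying_rates()] object.
#' @return Named derivative vector of length `network$s`.
#' @export
vector_field <- function(network, state, t = 0, rates = NULL) {
  validate_state(network, state, tol = 1e-6)
  lay <- state_layout(network)
  rr <- rates_at(network, rates, t)
  d <- numeric(network$s)
  zidx <- lay$pool_index
  for (ch in network$chains) {
    n <- ch$n_sites
    ix <- lay$chain_offset[[ch$id]] + seq_len(n)
    x <- state[ix]
    lam <- rr[[ch$id]]
    z <- state[zidx[[ch$source_pool]]]
    eff <- lam[1L] * eval_input_fn(ch$input_fn, max(z, 0))
    # flux[m+1] = flow out of site m (flux[1] = entry flow)
    flux <- c(eff * (1 - x[1L]),
              if (n > 1L) lam[2:n] * x[1:(n - 1L)] * (1 - x[2:n]) else NULL,
              lam[n + 1L] * x[n])
    d[ix] <- flux[seq_len(n)] - flux[1L + seq_len(n)]
    d[zidx[[ch$source_pool]]] <- d[zidx[[ch$source_pool]]] - flux[1L]
    d[zidx[[ch$sink_pool]]] <- d[zidx[[ch$sink_pool]]] + flux[n + 1L]
  }
  stats::setNames(d, network$state_names)
}

#' Analytic Jacobian of the network vector field
#'
#' Assembles the block Jacobian: a tridiagonal block per chain, coupling
#' rows/columns between each chain and its source and sink pools, and
#' diagonal pool entries. At any admissible state all off-diagonal
#' entries are non-negative (the system is cooperative: the flow
#' preserves the componentwise partial order), and every column sums to
#' zero — the differential form of particle conservation.
#'
#' @inheritParams vector_field
#' @return An `s x s` matrix.
#' @export
network_jacobian <- function(network, state, t = 0, rates = NULL) {
  lay <- state_layout(network)
  rr <- rates_at(network, rates, t)
  s <- network$s
  J <- matrix(0, s, s)
  zidx <- lay$pool_index
  for (ch in network$chains) {
    n <- ch$n_sites
    ix <- lay$chain_offset[[ch$id]] + seq_len(n)
    x <- state[ix]
    lam <- rr[[ch$id]]
    iz_src <- zidx[[ch$source_pool]]
    iz_snk <- zidx[[ch$sink_pool]]
    z <- max(state[iz_src], 0)
    G <- eval_input_fn(ch$input_fn, z)
    Gp <- eval_input_fn_deriv(ch$input_fn, z)
    eff <- lam[1L] * G
    # d flux_m / d x: flux index m+1 is flow out of site m
    for (m in seq_len(n)) {
      i <- ix[m]
      # inflow to site m
      if (m == 1L) {
        J[i, i] <- J[i, i] - eff
        J[i, iz_src] <- J[i, iz_src] + lam[1L] * Gp * (1 - x[1L])
      } else {
        J[i, ix[m - 1L]] <- J[i, ix[m - 1L]] + lam[m] * (1 - x[m])
        J[i, i] <- J[i, i] - lam[m] * x[m - 1L]
      }
      # outflow from site m
      if (m < n) {
        J[i, i] <- J[i, i] - lam[m + 1L] * (1 - x[m + 1L])
        J[i, ix[m + 1L]] <- J[i, ix[m + 1L]] + lam[m + 1L] * x[m]
      } else {
        J[i, i] <- J[i, i] - lam[n + 1L]
      }
    }
    # source pool row: -entry flux
    J[iz_src, ix[1L]] <- J[iz_src, ix[1L]] + eff
    J[iz_src, iz_src] <- J[iz_src, iz_src] - lam[1L] * Gp * (1 - x[1L])
    # sink pool row: +exit flux
    J[iz_snk, ix[n]] <- J[iz_snk, ix[n]] + lam[n + 1L]
  }
  dimnames(J) <- list(network$state_names, network$state_names)
  J
}

#' Integrate the network ODEs
#'
#' Adaptive stiff-capable integration (lsoda via \pkg{deSolve}) at tight
#' tolerances; the default `rtol = 1e-10`, `atol = 1e-12` keeps the first
#' integral to ~1e-10 over long horizons. Conservation is monitored, not
#' enforced: a drift of the total occupancy beyond `drift_tol` aborts
#' with an error, since silent projection could mask a mis-assembled
#' vector field.
#'
#' @inheritParams vector_field
#' @param initial Initial state (canonical layout).
#' @param t_final Integration horizon.
#' @param n_out Number of equally spaced output times (including 0).
#' @param rtol,atol Integrator tolerances.
#' @param drift_tol Maximum tolerated `|Q(t) - Q(0)|`, relative to
#'   `max(1, Q(0))`.
#' @return An object of class `rfm_trajectory`: a list with `states` (a
#'   tibble, column `time` then one column per state component),
#'   `conservation_drift`, and the network.
#' @export
integrate_network <- function(network, initial, t_final, rates = NULL,
                              n_out = 201L, rtol = 1e-10, atol = 1e-12,
                              drift_tol = 1e-8) {
  stopifnot(inherits(network, "rfm_network"), t_final > 0)
  initial <- stats::setNames(as.numeric(initial), network$state_names)
  validate_state(network, initial)
  times <- seq(0, t_final, length.out = n_out)
  deriv <- function(t, y, parms) list(vector_field(network, y, t, rates))
  use_jac <- is.null(rates)
  sol <- deSolve::ode(
    y = initial, times = times, func = deriv, parms = NULL,
    method = "lsoda", rtol = rtol, atol = atol,
    jacfunc = if (use_jac) {
      function(t, y, parms) network_jacobian(network, y, t, rates)
    } else NULL,
    jactype = if (use_jac) "fullusr" else "fullint"
  )
  if (attr(sol, "istate")[1L] < 0) stop("ODE solver failed.")
  states <- tibble::as_tibble(as.data.frame(sol))
  names(states) <- c("time", network$state_names)
  q <- rowSums(states[, -1L, drop = FALSE])
  drift <- max(abs(q - q[1L]))
  if (drift > drift_tol * max(1, abs(q[1L]))) {
    stop("conservation drift ", format(drift),
         " exceeds tolerance; the vector field may be mis-assembled.")
  }
  structure(
    list(states = states, conservation_drift = drift, network = network,
         rates = rates),
    class = "rfm_trajectory"
  )
}

#' @export
print.rfm_trajectory <- function(x, ...) {
  cat("<rfm_trajectory: ", nrow(x$states), " time points on [0, ",
      max(x$states$time), "], |Q(t) - Q(0)| <= ",
      format(x$conservation_drift, digits = 3), ">\n", sep = "")
  invisible(x)
}

# last state of a trajectory as a named vector
final_state <- function(traj) {
  st <- traj$states[nrow(traj$states), -1L]
  stats::setNames(as.numeric(st), names(st))
}

#' Steady state of the network by relaxation plus Newton refinement
#'
#' Every level set of the conserved total occupancy carries a unique,
#' globally attracting steady state. This solver integrates the dynamics
#' until the vector field is small (`switch_tol`), then applies damped
#' Newton iteration to the algebraic system in which one (redundant) pool
#' balance equation is replaced by the conservation constraint
#' `Q(e) = r`, certifying the root to `tol`.
#'
#' @inheritParams integrate_network
#' @param r Level-set value (total particle count). Used to build the
#'   default initial state (all particles split evenly across pools) and
#'   enforced by the Newton step. If `NULL`, taken from `initial`.
#' @param initial Optional starting state; any state with total
#'   occupancy `r` converges to the same point.
#' @param tol Residual tolerance (max-norm of the vector field) for the
#'   refined root.
#' @param switch_tol Field norm below which relaxation hands over to
#'   Newton.
#' @param max_time Integration-time budget for the relaxation phase.
#' @return An object of class `rfm_steady_state`: `state` (named vector
#'   `e`), `r`, `residual`, `method`, `diagnostics`.
#' @export
find_steady_state <- function(network, r = NULL, initial = NULL,
                              tol = 1e-12, switch_tol = 1e-6,
                              max_time = 1e5, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(network, "rfm_network"))
  if (is.null(initial)) {
    if (is.null(r)) stop("supply `r` or `initial`.")
    if (r < 0) stop("`r` must be non-negative.")
    initial <- network_state(
      network,
      pools = stats::setNames(rep(r / length(network$pools),
                                  length(network$pools)), network$pools)
    )
  } else {
    initial <- stats::setNames(as.numeric(initial), network$state_names)
    validate_state(network, initial)
    if (is.null(r)) r <- sum(initial)
    if (abs(sum(initial) - r) > 1e-8 * max(1, r)) {
      stop("`initial` lies on level set ", sum(initial), ", not r = ", r, ".")
    }
  }
  if (r <= 0) {
    return(structure(
      list(state = stats::setNames(numeric(network$s), network$state_names),
           r = 0, residual = 0, method = "ode_relaxation",
           diagnostics = list(relax_time = 0, newton_iter = 0L)),
      class = "rfm_steady_state"
    ))
  }
  # relaxation: integrate in doubling chunks until the field is small
  y <- initial
  t_done <- 0
  chunk <- 20
  repeat {
    f <- vector_field(network, y)
    if (max(abs(f)) < switch_tol || t_done >= max_time) break
    traj <- integrate_network(network, y, chunk, n_out = 2L,
                              rtol = rtol, atol = atol)
    y <- pmin(pmax(final_state(traj), 0), Inf)
    t_done <- t_done + chunk
    chunk <- min(2 * chunk, max_time - t_done + 1)
  }
  relax_resid <- max(abs(vector_field(network, y)))
  # Newton on {field = 0 with one pool row replaced by Q - r}
  lay <- state_layout(network)
  last_pool <- lay$pool_index[[length(lay$pool_index)]]
  newton_iter <- 0L
  resid_fn <- function(u) {
    f <- vector_field_unsafe(network, u)
    f[last_pool] <- sum(u) - r
    f
  }
  fval <- resid_fn(y)
  for (it in seq_len(60L)) {
    if (max(abs(fval)) < tol) break
    J <- network_jacobian(network, pmax(y, 0))
    J[last_pool, ] <- 1
    step <- tryCatch(solve(J, fval), error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    repeat {
      y_new <- y - alpha * step
      f_new <- resid_fn(y_new)
      if (max(abs(f_new)) < max(abs(fval)) || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    y <- y_new
    fval <- f_new
    newton_iter <- it
  }
  residual <- max(abs(vector_field_unsafe(network, y)))
  if (residual > 1e-9 || abs(sum(y) - r) > 1e-9 * max(1, r)) {
    stop("steady-state solver did not converge (residual ",
         format(residual), ").")
  }
  structure(
    list(state = stats::setNames(y, network$state_names), r = r,
         residual = residual, method = "newton_refined",
         diagnostics = list(relax_time = t_done, relax_residual = relax_resid,
                            newton_iter = newton_iter)),
    class = "rfm_steady_state"
  )
}

# vector field without the state-space check (Newton iterates may leave B
# transiently)
vector_field_unsafe <- function(network, state) {
  lay <- state_layout(network)
  d <- numeric(network$s)
  zidx <- lay$pool_index
  for (ch in network$chains) {
    n <- ch$n_sites
    ix <- lay$chain_offset[[ch$id]] + seq_len(n)
    x <- state[ix]
    lam <- ch$rates
    eff <- lam[1L] * eval_input_fn(ch$input_fn, max(state[zidx[[ch$source_pool]]], 0))
    flux <- c(eff * (1 - x[1L]),
              if (n > 1L) lam[2:n] * x[1:(n - 1L)] * (1 - x[2:n]) else NULL,
              lam[n + 1L] * x[n])
    d[ix] <- flux[seq_len(n)] - flux[1L + seq_len(n)]
    d[zidx[[ch$source_pool]]] <- d[zidx[[ch$source_pool]]] - flux[1L]
    d[zidx[[ch$sink_pool]]] <- d[zidx[[ch$sink_pool]]] + flux[n + 1L]
  }
  d
}

#' @export
print.rfm_steady_state <- function(x, ...) {
  cat("<rfm_steady_state (", x$method, "): r = ", format(x$r),
      ", residual = ", format(x$residual, digits = 3), ">\n", sep = "")
  print(round(x$state, 4))
  invisible(x)
}

#' Simulate the periodically forced network
#'
#' Integrates the network under `T`-periodic rates over `n_periods`
#' periods with a uniform sampling grid, for entrainment analysis: the
#' trajectory converges to a periodic orbit of the same period `T`.
#'
#' @inheritParams integrate_network
#' @param rates A [time_varying_rates()] object.
#' @param n_periods Number of forcing periods to integrate.
#' @param samples_per_period Output samples per period.
#' @return An `rfm_trajectory`.
#' @export
simulate_periodic <- function(network, rates, initial, n_periods = 30L,
                              samples_per_period = 100L, rtol = 1e-10,
                              atol = 1e-12) {
  stopifnot(inherits(rates, "rfm_rates"))
  integrate_network(
    network, initial, t_final = n_periods * rates$period, rates = rates,
    n_out = n_periods * samples_per_period + 1L, rtol = rtol, atol = atol
  )
}

#' Estimate the asymptotic period of a trajectory
#'
#' Discards the transient, then for each state component finds the lag
#' minimising the mean-squared self-distance
#' `mean((x(t + L) - x(t))^2)` over the retained uniformly sampled
#' segment, refined by parabolic interpolation. Components whose
#' peak-to-trough amplitude is below `amp_tol` are flagged `"constant"`.
#'
#' @param traj An `rfm_trajectory` with uniform sampling.
#' @param discard_fraction Fraction of the window dropped as transient.
#' @param amp_tol Amplitude below which a component counts as constant.
#' @return A list with `period` (median over periodic components, `NA`
#'   if none), `flag` (`"periodic"`, `"constant"` or `"undetermined"`)
#'   and `components`, a tibble with one row per state component.
#' @export
estimate_period <- function(traj, discard_fraction = 0.5, amp_tol = 1e-8) {
  stopifnot(inherits(traj, "rfm_trajectory"))
  st <- traj$states
  keep <- st$time >= discard_fraction * max(st$time)
  st <- st[keep, ]
  if (nrow(st) < 16L) stop("too few samples after transient discard.")
  dt <- diff(st$time)
  if (max(abs(dt - dt[1L])) > 1e-8 * dt[1L]) {
    stop("period estimation requires uniform sampling.")
  }
  dt <- dt[1L]
  comps <- names(st)[-1L]
  rows <- lapply(comps, function(nm) {
    x <- st[[nm]]
    amp <- max(x) - min(x)
    if (amp < amp_tol) {
      return(tibble::tibble(component = nm, period = NA_real_,
                            flag = "constant"))
    }
    n <- length(x)
    max_lag <- floor(n / 2)
    msd <- vapply(seq_len(max_lag), function(L) {
      mean((x[(L + 1):n] - x[1:(n - L)])^2)
    }, numeric(1))
    # first local minimum with near-zero self-distance = fundamental period
    thresh <- 0.05 * amp^2
    cand <- which(
      msd < thresh &
        msd <= c(msd[-1], Inf) & msd <= c(Inf, msd[-max_lag])
    )
    cand <- cand[cand > 1 & cand < max_lag]
    if (!length(cand)) {
      return(tibble::tibble(component = nm, period = NA_real_,
                            flag = "undetermined"))
    }
    L <- cand[1L]
    # parabolic refinement around the minimum
    y1 <- msd[L - 1L]; y2 <- msd[L]; y3 <- msd[L + 1L]
    denom <- y1 - 2 * y2 + y3
    shift <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
    tibble::tibble(component = nm, period = (L + shift) * dt,
                   flag = "periodic")
  })
  components <- dplyr::bind_rows(rows)
  flags <- components$flag
  flag <- if (all(flags == "constant")) {
    "constant"
  } else if (any(flags == "undetermined")) {
    "undetermined"
  } else {
    "periodic"
  }
  list(
    period = if (flag == "periodic") {
      stats::median(components$period, na.rm = TRUE)
    } else NA_real_,
    flag = flag,
    components = components
  )
}
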