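#' Modify a single transition rate
#'
#' Returns a copy of the network in which rate `lambda_k` of one chain
#' (`site_index = k`, with `k = 0` the entry rate and `k = n` the exit
#' rate) is replaced by `new_rate`. The original network is untouched.
#'
#' @inheritParams network_state
#' @param chain_id Chain whose rate is modified.
#' @param site_index Rate index `k` in `0, ..., n_sites`.
#' @param new_rate Strictly positive replacement rate.
#' @return A new [pool_network()].
#' @export
perturb_rate <- function(network, chain_id, site_index, new_rate) {
  stopifnot(inherits(network, "rfm_network"))
  ch <- network$chains[[chain_id]]
  if (is.null(ch)) stop("unknown chain `", chain_id, "`.")
  if (!is.numeric(site_index) || length(site_index) != 1L ||
      site_index != round(site_index) || site_index < 0 ||
      site_index > ch$n_sites) {
    stop("`site_index` must be an integer in 0..", ch$n_sites, ".")
  }
  if (!is.numeric(new_rate) || new_rate <= 0) {
    stop("`new_rate` must be strictly positive.")
  }
  rates <- ch$rates
  rates[site_index + 1L] <- new_rate
  chains <- network$chains
  chains[[chain_id]] <- chain_spec(ch$id, ch$n_sites, rates, ch$source_pool,
                                   ch$sink_pool, ch$input_fn)
  suppressWarnings(pool_network(network$pools, unname(chains)))
}

#' Classify the network-wide effect of a rate change
#'
#' When one transition rate of a chain in a two-pool network is
#' increased, the density at the perturbed site always drops and every
#' downstream density of that chain rises; the rest of the network
#' responds in exactly one of five ways, determined by how the two
#' steady-state pool levels move. With pool I the perturbed chain's
#' source pool and pool II the other pool (and writing `e` / `e_bar` for
#' the steady states before / after):
#'
#' * `"i"`   — both pool levels rise; every other chain's densities rise.
#' * `"ii"`  — pool I falls, pool II rises; the other source-pool-I
#'   chains fall, all pool-II-fed chains rise.
#' * `"iii"` — both pools fall; every other chain's densities fall.
#' * `"iv"`  — pool I exactly unchanged, pool II rises.
#' * `"v"`   — pool I falls, pool II exactly unchanged.
#'
#' Equality (cases iv/v) is declared below a relative tolerance `tol`;
#' being measure-zero those labels are rare. `"other"` (with
#' diagnostics) signals an internally inconsistent pattern, i.e.
#' numerical trouble, since the five cases are exhaustive.
#'
#' @param e_before,e_after `rfm_steady_state` objects at the same `r`.
#' @param network The unperturbed network (two pools).
#' @param chain_id The perturbed chain.
#' @param tol Relative tolerance for the equality cases.
#' @return Character label, with attribute `"diagnostics"`.
#' @export
classify_effect <- function(e_before, e_after, network, chain_id,
                            tol = 1e-6) {
  stopifnot(inherits(e_before, "rfm_steady_state"),
            inherits(e_after, "rfm_steady_state"),
            inherits(network, "rfm_network"))
  if (length(network$pools) != 2L) {
    stop("case classification is defined for two-pool networks.")
  }
  if (length(e_before$state) != network$s ||
      length(e_after$state) != network$s) {
    stop("steady states do not match the network shape.")
  }
  ch <- network$chains[[chain_id]]
  if (is.null(ch)) stop("unknown chain `", chain_id, "`.")
  pool_I <- ch$source_pool
  pool_II <- setdiff(network$pools, pool_I)
  before <- split_state(network, e_before$state)
  after <- split_state(network, e_after$state)
  cmp <- function(a, b) { # -1 fell, 0 equal (within tol), +1 rose
    d <- b - a
    ifelse(abs(d) <= tol * pmax(1, abs(a)), 0L, ifelse(d > 0, 1L, -1L))
  }
  dz1 <- cmp(before$pools[[pool_I]], after$pools[[pool_I]])
  dz2 <- cmp(before$pools[[pool_II]], after$pools[[pool_II]])
  others <- setdiff(names(network$chains), chain_id)
  dir_of <- function(id) {
    d <- cmp(before$sites[[id]], after$sites[[id]])
    if (all(d > 0)) 1L else if (all(d < 0)) -1L else if (all(d == 0)) 0L else NA_integer_
  }
  chain_dir <- vapply(others, dir_of, integer(1))
  grp_I <- others[vapply(others, function(id)
    network$chains[[id]]$source_pool == pool_I, logical(1))]
  grp_II <- setdiff(others, grp_I)
  consistent <- function(expect_I, expect_II) {
    all(chain_dir[grp_I] %in% expect_I, na.rm = FALSE) &&
      all(chain_dir[grp_II] %in% expect_II, na.rm = FALSE)
  }
  label <- if (dz1 == 1L && dz2 == 1L && consistent(1L, 1L)) {
    "i"
  } else if (dz1 == -1L && dz2 == 1L && consistent(-1L, 1L)) {
    "ii"
  } else if (dz1 == -1L && dz2 == -1L && consistent(-1L, -1L)) {
    "iii"
  } else if (dz1 == 0L && dz2 == 1L && consistent(0L, 1L)) {
    "iv"
  } else if (dz1 == -1L && dz2 == 0L && consistent(-1L, 0L)) {
    "v"
  } else {
    "other"
  }
  structure(label, diagnostics = list(
    dz1 = dz1, dz2 = dz2, chain_dir = chain_dir,
    pool_I = pool_I, pool_II = pool_II
  ))
}

# local monotonicity at the perturbed chain: density at site k falls,
# densities at sites k+1..n rise (strict), for an increased rate
local_rate_checks <- function(network, chain_id, site_index,
                              e_before, e_after) {
  ch <- network$chains[[chain_id]]
  xb <- split_state(network, e_before$state)$sites[[chain_id]]
  xa <- split_state(network, e_after$state)$sites[[chain_id]]
  k <- site_index
  list(
    site_k_falls = if (k >= 1L) xa[k] < xb[k] else NA,
    downstream_rise = if (k < ch$n_sites) {
      all(xa[(k + 1L):ch$n_sites] > xb[(k + 1L):ch$n_sites])
    } else NA
  )
}

#' Full before/after report for a single rate change
#'
#' Computes the steady state before and after modifying one rate (same
#' level-set value `r`), the case label from [classify_effect()], and
#' the local monotonicity checks at the perturbed chain.
#'
#' @inheritParams perturb_rate
#' @param r Level-set value at which both steady states are computed.
#' @param method `"spectral"` (default) or `"ode"`.
#' @param tol Equality tolerance passed to [classify_effect()].
#' @return An object of class `rfm_perturbation`.
#' @export
perturbation_report <- function(network, chain_id, site_index, new_rate, r,
                                method = c("spectral", "ode"), tol = 1e-6) {
  method <- match.arg(method)
  solve_ss <- function(net) {
    if (method == "spectral") solve_pool_balance(net, r)
    else find_steady_state(net, r = r)
  }
  old_rate <- network$chains[[chain_id]]$rates[site_index + 1L]
  perturbed <- perturb_rate(network, chain_id, site_index, new_rate)
  e_before <- solve_ss(network)
  e_after <- solve_ss(perturbed)
  label <- if (length(network$pools) == 2L) {
    classify_effect(e_before, e_after, network, chain_id, tol = tol)
  } else NA_character_
  structure(
    list(chain_id = chain_id, site_index = site_index,
         old_rate = old_rate, new_rate = new_rate, r = r,
         e_before = e_before, e_after = e_after,
         case_label = as.character(label),
         diagnostics = attr(label, "diagnostics"),
         local_checks = local_rate_checks(network, chain_id, site_index,
                                          e_before, e_after)),
    class = "rfm_perturbation"
  )
}

#' @export
print.rfm_perturbation <- function(x, ...) {
  cat("<rfm_perturbation: ", x$chain_id, " lambda_", x$site_index, ": ",
      x$old_rate, " -> ", x$new_rate, ", case ", x$case_label, ">\n",
      sep = "")
  invisible(x)
}

#' Sweep one transition rate across a grid
#'
#' Recomputes the steady state (spectral route by default) for each
#' value of one rate and tabulates the pool levels and per-chain output
#' fluxes; between consecutive grid points the rate increase is
#' classified with [classify_effect()] and the local monotonicity checks
#' are evaluated.
#'
#' @inheritParams perturbation_report
#' @param values Ascending grid of strictly positive rate values.
#' @return A tibble with one row per grid value: `value`, one
#'   `pool.<id>` column per pool, one `output.<chain>` column per chain,
#'   `case` (label for the step from the previous row; `NA` in the first
#'   row) and `local_ok`.
#' @export
sweep_rate <- function(network, chain_id, site_index, values, r,
                       method = c("spectral", "ode"), tol = 1e-6) {
  method <- match.arg(method)
  if (is.unsorted(values, strictly = TRUE)) {
    stop("`values` must be strictly ascending.")
  }
  if (any(values <= 0)) stop("rate values must be strictly positive.")
  solve_ss <- function(net) {
    if (method == "spectral") solve_pool_balance(net, r)
    else find_steady_state(net, r = r)
  }
  nets <- lapply(values, function(v)
    perturb_rate(network, chain_id, site_index, v))
  sss <- lapply(nets, solve_ss)
  rows <- purrr::map2(values, sss, function(v, ss) {
    sp <- split_state(network, ss$state)
    out <- vapply(network$chains, function(ch) {
      lam_n <- if (ch$id == chain_id && site_index == ch$n_sites) v
               else ch$rates[ch$n_sites + 1L]
      lam_n * sp$sites[[ch$id]][ch$n_sites]
    }, numeric(1))
    tibble::tibble(
      value = v,
      !!!stats::setNames(as.list(sp$pools), paste0("pool.", names(sp$pools))),
      !!!stats::setNames(as.list(out), paste0("output.", names(out)))
    )
  })
  res <- dplyr::bind_rows(rows)
  case <- rep(NA_character_, length(values))
  local_ok <- rep(NA, length(values))
  if (length(network$pools) == 2L) {
    for (i in seq_along(values)[-1L]) {
      lbl <- classify_effect(sss[[i - 1L]], sss[[i]], nets[[i - 1L]],
                             chain_id, tol = tol)
      case[i] <- as.character(lbl)
      lc <- local_rate_checks(network, chain_id, site_index,
                              sss[[i - 1L]], sss[[i]])
      local_ok[i] <- all(unlist(lc), na.rm = TRUE)
    }
  }
  res$case <- case
  res$local_ok <- local_ok
  res
}
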