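#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a steady state into one row per state component
#'
#' @param x An `rfm_steady_state`.
#' @param ... Unused.
#' @return A tibble with `component`, `kind` (`"site"`/`"pool"`),
#'   `chain`, `site`, `pool` and `value`.
#' @method tidy rfm_steady_state
#' @export
tidy.rfm_steady_state <- function(x, ...) {
  nm <- names(x$state)
  is_pool <- startsWith(nm, "pool.")
  chain <- site <- rep(NA, length(nm))
  chain[!is_pool] <- sub("\\.x[0-9]+$", "", nm[!is_pool])
  site[!is_pool] <- as.integer(sub("^.*\\.x", "", nm[!is_pool]))
  tibble::tibble(
    component = nm,
    kind = ifelse(is_pool, "pool", "site"),
    chain = as.character(chain),
    site = as.integer(site),
    pool = ifelse(is_pool, sub("^pool\\.", "", nm), NA_character_),
    value = unname(x$state)
  )
}

#' One-row summary of a steady-state solve
#'
#' @inheritParams tidy.rfm_steady_state
#' @return A tibble with `r`, `residual`, `method` and `s`.
#' @method glance rfm_steady_state
#' @export
glance.rfm_steady_state <- function(x, ...) {
  tibble::tibble(
    r = x$r, residual = x$residual, method = x$method,
    s = length(x$state)
  )
}

#' Tidy a trajectory into long format
#'
#' @param x An `rfm_trajectory`.
#' @param ... Unused.
#' @return A tibble with `time`, `component`, `value`.
#' @method tidy rfm_trajectory
#' @export
tidy.rfm_trajectory <- function(x, ...) {
  tidyr::pivot_longer(x$states, -"time", names_to = "component",
                      values_to = "value")
}

#' One-row summary of a trajectory
#'
#' @inheritParams tidy.rfm_trajectory
#' @return A tibble with `t_final`, `n_times`, `conservation_drift` and
#'   the initial occupancy `Q0`.
#' @method glance rfm_trajectory
#' @export
glance.rfm_trajectory <- function(x, ...) {
  tibble::tibble(
    t_final = max(x$states$time),
    n_times = nrow(x$states),
    conservation_drift = x$conservation_drift,
    Q0 = sum(x$states[1L, -1L])
  )
}

#' Tidy Monte Carlo occupancies
#'
#' @param x An `rfm_mc`.
#' @param ... Unused.
#' @return The per-site occupancy tibble (`chain`, `site`, `occupancy`).
#' @method tidy rfm_mc
#' @export
tidy.rfm_mc <- function(x, ...) x$site_means

#' Plot all state components of a trajectory against time
#'
#' @param object An `rfm_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rfm_trajectory
#' @export
autoplot.rfm_trajectory <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$value,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "density / pool level",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a steady-state density profile per chain
#'
#' Site densities as profiles along each chain; pool levels as labelled
#' horizontal reference lines.
#'
#' @param object An `rfm_steady_state`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rfm_steady_state
#' @export
autoplot.rfm_steady_state <- function(object, ...) {
  d <- tidy(object)
  sites <- dplyr::filter(d, .data$kind == "site")
  ggplot2::ggplot(sites, ggplot2::aes(.data$site, .data$value,
                                      colour = .data$chain)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "site", y = "steady-state density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a rate sweep: pool levels against the swept rate
#'
#' @param sweep A tibble from [sweep_rate()].
#' @return A ggplot.
#' @export
plot_sweep <- function(sweep) {
  d <- tidyr::pivot_longer(
    dplyr::select(sweep, "value", dplyr::starts_with("pool.")),
    -"value", names_to = "pool", values_to = "level"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$value, .data$level,
                                  colour = .data$pool)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "transition rate", y = "steady-state pool level",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
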