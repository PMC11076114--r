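#' Pool outflow (input) functions
#'
#' A pool outflow function maps the occupancy `z` of a pool to the factor
#' modulating the entry rate of every lane fed by that pool: the effective
#' initiation rate of a lane with entry rate `lambda0` is
#' `lambda0 * G(z)`. Any admissible function must vanish at zero (an empty
#' pool injects nothing), be continuous, strictly increasing, and
#' non-negative on `[0, Inf)`.
#'
#' Three forms are registered: `"identity"` (`G(z) = z`), `"tanh"`
#' (`G(z) = tanh(z)`, saturating competition), and `"scaled_identity"`
#' (`G(z) = c * z`, parameter `c > 0`). A `"custom"` function may be
#' supplied as a closure together with (optionally) its derivative; it is
#' checked at registration for `G(0) = 0` and strict monotonicity on a
#' grid of test points.
#'
#' @param name One of `"identity"`, `"tanh"`, `"scaled_identity"`,
#'   `"custom"`.
#' @param params Named list of real parameters (`scaled_identity` takes
#'   `c`).
#' @param fn For `name = "custom"`, the function of `z`.
#' @param deriv For `name = "custom"`, its derivative (optional; required
#'   only for analytic Jacobians).
#' @param check_grid Grid of non-negative points on which custom functions
#'   are validated.
#'
#' @return An object of class `rfm_input_fn` with elements `name`,
#'   `params`, `fn` and `deriv`.
#' @examples
#' G <- input_fn("tanh")
#' eval_input_fn(G, 0.6023)
#' @export
input_fn <- function(name = c("identity", "tanh", "scaled_identity", "custom"),
                     params = list(), fn = NULL, deriv = NULL,
                     check_grid = seq(0, 10, length.out = 64)) {
  name <- match.arg(name)
  if (name == "identity") {
    fn <- function(z) z
    deriv <- function(z) rep_len(1, length(z))
  } else if (name == "tanh") {
    fn <- function(z) tanh(z)
    deriv <- function(z) 1 / cosh(z)^2
  } else if (name == "scaled_identity") {
    c0 <- params$c
    if (is.null(c0) || !is.numeric(c0) || length(c0) != 1L || c0 <= 0) {
      stop("`scaled_identity` requires a single positive parameter `c`.")
    }
    fn <- function(z) c0 * z
    deriv <- function(z) rep_len(c0, length(z))
  } else {
    if (!is.function(fn)) {
      stop("`custom` input functions require `fn`.")
    }
    vals <- vapply(check_grid, fn, numeric(1))
    if (abs(fn(0)) > 1e-12) {
      stop("input function must satisfy G(0) = 0.")
    }
    if (any(vals < -1e-12)) {
      stop("input function must be non-negative on [0, Inf).")
    }
    if (any(diff(vals) <= 0)) {
      stop("input function must be strictly increasing on [0, Inf).")
    }
  }
  structure(
    list(name = name, params = params, fn = fn, deriv = deriv),
    class = "rfm_input_fn"
  )
}

#' Evaluate a pool outflow function
#'
#' @param spec An [input_fn()] object.
#' @param z Non-negative pool occupancy (vectorised).
#' @return `G(z)`, non-negative.
#' @export
eval_input_fn <- function(spec, z) {
  stopifnot(inherits(spec, "rfm_input_fn"))
  if (any(z < 0)) stop("pool occupancy must be non-negative.")
  spec$fn(z)
}

#' Evaluate the derivative of a pool outflow function
#'
#' @inheritParams eval_input_fn
#' @return `G'(z)`.
#' @export
eval_input_fn_deriv <- function(spec, z) {
  stopifnot(inherits(spec, "rfm_input_fn"))
  if (is.null(spec$deriv)) {
    stop("input function `", spec$name, "` has no registered derivative.")
  }
  spec$deriv(z)
}

#' @export
print.rfm_input_fn <- function(x, ...) {
  p <- if (length(x$params)) {
    paste0("(", paste(names(x$params), unlist(x$params), sep = "=",
                      collapse = ", "), ")")
  } else ""
  cat("<input function: ", x$name, p, ">\n", sep = "")
  invisible(x)
}
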