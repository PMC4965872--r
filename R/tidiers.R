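# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an additive MARS fit
#'
#' @param x An `iso_mars` object.
#' @param ... Unused.
#' @return One row per hinge term: `term`, `variable`, `knot`, `direction`,
#'   `estimate`.
#' @export
tidy.iso_mars <- function(x, ...) {
  if (!nrow(x$terms)) {
    return(tibble(term = "(Intercept)", variable = NA_character_,
                  knot = NA_real_, direction = NA_integer_,
                  estimate = x$intercept))
  }
  lab <- ifelse(x$terms$dir > 0,
                sprintf("h(%s - %.6g)", x$terms$variable, x$terms$knot),
                sprintf("h(%.6g - %s)", x$terms$knot, x$terms$variable))
  bind_rows(
    tibble(term = "(Intercept)", variable = NA_character_, knot = NA_real_,
           direction = NA_integer_, estimate = x$intercept),
    tibble(term = lab, variable = x$terms$variable, knot = x$terms$knot,
           direction = x$terms$dir, estimate = x$terms$coef))
}

#' Glance at an additive MARS fit
#'
#' @param x An `iso_mars` object.
#' @param ... Unused.
#' @return One-row tibble: `r.squared`, `gcv`, `gcv.unpruned`, `n.terms`,
#'   `nobs`.
#' @export
glance.iso_mars <- function(x, ...) {
  tibble(r.squared = x$r_squared, gcv = x$gcv, gcv.unpruned = x$gcv_unpruned,
         n.terms = nrow(x$terms), nobs = x$n)
}
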