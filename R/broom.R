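#' Tidy and glance methods
#'
#' broom-style summaries for the package's result objects.
#'
#' * `tidy.pc_fixed_points()`: one row per fixed point (densities,
#'   residual, stability, composition).
#' * `glance.pc_fixed_points()`: one row summarising the phase structure
#'   (counts of fixed points, attractors, saddles; whether any attractor
#'   is a spiral).
#' * `tidy.pc_trajectory()`: long format (`time_h`, `population`,
#'   `density`).
#' * `glance.pc_trajectory()`: one row with the horizon, final densities
#'   and final total.
#' * `tidy.pc_region()` / `glance.pc_region()`: the attractor table and a
#'   one-row region summary.
#'
#' @param x A package result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.pc_fixed_points <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidiers
#' @export
glance.pc_fixed_points <- function(x, ...) {
  tibble::tibble(
    model = attr(x, "model"),
    n_fixed_points = nrow(x),
    n_stable = sum(x$stability %in% c("stable_node", "stable_spiral")),
    n_saddle = sum(x$stability == "saddle"),
    any_spiral_attractor = any(x$stability == "stable_spiral"),
    max_residual = if (nrow(x)) max(x$residual) else NA_real_)
}

#' @rdname tidiers
#' @export
tidy.pc_trajectory <- function(x, ...) {
  comp <- model_components(attr(x, "model"))
  tidyr::pivot_longer(tibble::as_tibble(x), cols = dplyr::all_of(comp),
                      names_to = "population", values_to = "density")
}

#' @rdname tidiers
#' @export
glance.pc_trajectory <- function(x, ...) {
  comp <- model_components(attr(x, "model"))
  last <- dplyr::slice_tail(tibble::as_tibble(x), n = 1)
  out <- tibble::tibble(model = attr(x, "model"),
                        regime = attr(x, "regime"),
                        t_end = last$time_h)
  dplyr::bind_cols(out, last[comp],
                   tibble::tibble(total = sum(unlist(last[comp]))))
}

#' @rdname tidiers
#' @export
tidy.pc_region <- function(x, ...) {
  if (is.null(x$fixed_points)) return(tibble::tibble())
  tibble::as_tibble(x$fixed_points)
}

#' @rdname tidiers
#' @export
glance.pc_region <- function(x, ...) {
  tibble::tibble(model = x$model, label = x$label,
                 n_attractors = if (is.null(x$attractors)) NA_integer_
                                else nrow(x$attractors))
}
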