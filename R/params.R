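#' Construct a model parameter set
#'
#' Bundles every rate and capacity used by the compensation models into one
#' validated record. Growth rates are Malthusian rates in h^-1: `alpha` for
#' plasmid-free cells, `beta_p` for uncompensated plasmid bearers, `beta_c`
#' for chromosomally compensated (chrCM) bearers and `beta_q` for
#' plasmid-compensated (plaCM) bearers. `mu` is the population turnover
#' (washout) rate and `eta` an optional selection pressure acting against
#' plasmid-free cells, both in h^-1. Conjugation rates `gamma_p`, `gamma_c`,
#' `gamma_q` are mass-action transfer rates, in ml cell^-1 h^-1 when the set
#' is dimensional or scaled by the carrying capacity `K` (cells ml^-1) when
#' `dimensionless = TRUE`.
#'
#' @param alpha Plasmid-free growth rate (h^-1). Must exceed `mu`.
#' @param beta_p Uncompensated plasmid-bearer growth rate (h^-1).
#' @param beta_c chrCM plasmid-bearer growth rate (h^-1).
#' @param beta_q plaCM plasmid-bearer growth rate (h^-1).
#' @param mu Population turnover rate (h^-1).
#' @param eta Selection pressure against plasmid-free cells (h^-1).
#' @param gamma_p,gamma_c,gamma_q Conjugation rates for the wild-type
#'   plasmid from uncompensated hosts, from chrCM hosts, and for the plaCM
#'   plasmid respectively.
#' @param K Carrying capacity (cells ml^-1); may be `NA` for a set that is
#'   already dimensionless.
#' @param dimensionless Logical; `TRUE` if the gamma rates have already been
#'   scaled by `K`.
#'
#' @return An object of class `plasmid_params` (a named list).
#' @seealso [nondimensionalize()], [fixture_params()], [read_params()]
#' @export
#' @examples
#' parameter_set(alpha = 0.54, beta_p = 0.82 * 0.54, beta_c = 0.97 * 0.54,
#'               beta_q = 0.95 * 0.54, mu = 0.04125, gamma_p = 4.6e-12,
#'               gamma_c = 4.6e-12, gamma_q = 4.6e-14, K = 5.7e9)
parameter_set <- function(alpha, beta_p, beta_c = beta_p, beta_q = beta_p,
                          mu, eta = 0, gamma_p = 0, gamma_c = gamma_p,
                          gamma_q = gamma_p, K = NA_real_,
                          dimensionless = FALSE) {
  p <- list(alpha = alpha, beta_p = beta_p, beta_c = beta_c,
            beta_q = beta_q, mu = mu, eta = eta, gamma_p = gamma_p,
            gamma_c = gamma_c, gamma_q = gamma_q, K = K,
            dimensionless = isTRUE(dimensionless))
  validate_params(p)
  structure(p, class = "plasmid_params")
}

validate_params <- function(p) {
  rates <- c("alpha", "beta_p", "beta_c", "beta_q", "mu", "eta",
             "gamma_p", "gamma_c", "gamma_q")
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      rlang::abort(sprintf("parameter `%s` must be a single nonnegative number", nm))
    }
  }
  if (p$alpha <= p$mu) {
    rlang::abort("`alpha` must exceed `mu`: otherwise every population is washed out")
  }
  if (!is.na(p$K) && p$K <= 0) rlang::abort("`K` must be positive")
  invisible(p)
}

#' @export
print.plasmid_params <- function(x, ...) {
  cat("<plasmid_params>",
      if (x$dimensionless) "(dimensionless)" else "(dimensional)", "\n")
  cat(sprintf("  growth:  alpha = %g, beta_p = %g, beta_c = %g, beta_q = %g  [h^-1]\n",
              x$alpha, x$beta_p, x$beta_c, x$beta_q))
  cat(sprintf("  turnover mu = %g, selection eta = %g  [h^-1]\n", x$mu, x$eta))
  unit <- if (x$dimensionless) "" else "  [ml cell^-1 h^-1]"
  cat(sprintf("  conjugation: gamma_p = %g, gamma_c = %g, gamma_q = %g%s\n",
              x$gamma_p, x$gamma_c, x$gamma_q, unit))
  cat(sprintf("  K = %g cells ml^-1\n", x$K))
  invisible(x)
}

#' @export
as_tibble.plasmid_params <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Convert a parameter set between dimensional and dimensionless form
#'
#' The models are analysed with densities expressed as fractions of the
#' carrying capacity `K`, under which each mass-action conjugation rate
#' gamma (ml cell^-1 h^-1) becomes gamma' = gamma * K (h^-1). Growth,
#' turnover and selection rates are unchanged. `dimensionalize()` inverts
#' the scaling; the round trip is exact to within floating-point error.
#'
#' @param params A dimensional (`nondimensionalize`) or dimensionless
#'   (`dimensionalize`) [parameter_set()] with finite `K > 0`.
#' @return A `plasmid_params` with rescaled conjugation rates and the
#'   `dimensionless` flag toggled.
#' @export
#' @examples
#' p <- fixture_params("figI")
#' nondimensionalize(p)$gamma_p # 4.6e-12 * 5.7e9 = 0.02622
nondimensionalize <- function(params) {
  stopifnot(inherits(params, "plasmid_params"))
  if (params$dimensionless) {
    rlang::abort("`params` is already dimensionless")
  }
  if (is.na(params$K)) {
    rlang::abort("cannot nondimensionalize: `K` is missing from the parameter set")
  }
  out <- unclass(params)
  for (nm in c("gamma_p", "gamma_c", "gamma_q")) out[[nm]] <- out[[nm]] * params$K
  out$dimensionless <- TRUE
  structure(out, class = "plasmid_params")
}

#' @rdname nondimensionalize
#' @export
dimensionalize <- function(params) {
  stopifnot(inherits(params, "plasmid_params"))
  if (!params$dimensionless) {
    rlang::abort("`params` is already dimensional")
  }
  if (is.na(params$K)) {
    rlang::abort("cannot dimensionalize: `K` is missing from the parameter set")
  }
  out <- unclass(params)
  for (nm in c("gamma_p", "gamma_c", "gamma_q")) out[[nm]] <- out[[nm]] / params$K
  out$dimensionless <- FALSE
  structure(out, class = "plasmid_params")
}

as_dimensionless <- function(params) {
  if (params$dimensionless) params else nondimensionalize(params)
}

require_dimensionless <- function(params) {
  if (!params$dimensionless) {
    rlang::abort(paste0("`params` must be dimensionless; call ",
                        "nondimensionalize() first"))
  }
  invisible(params)
}

#' Parameter fixtures for the study system
#'
#' Returns the parameter sets used throughout the package's worked examples:
#' the Pseudomonas fluorescens SBW25 / mercury-resistance plasmid pQBR57
#' system, in which the wild-type plasmid imposes an 18% growth cost
#' (relative fitness 0.82) that is ameliorated to 3% by a chromosomal
#' compensatory mutation (chrCM, relative fitness 0.97) or to 5% by a
#' plasmid-borne one (plaCM, relative fitness 0.95).
#'
#' Available fixtures:
#' \describe{
#'   \item{`"figA"`}{alpha = 0.5 h^-1, relative fitnesses 0.82
#'     (uncompensated) and 0.95 (compensated, both CM types), base
#'     conjugation rate 9.9e-12 ml cell^-1 h^-1 for all plasmids.}
#'   \item{`"figG"`}{alpha = 0.54 h^-1, chrCM fitness 0.97, plaCM fitness
#'     0.95, uncompensated fitness 0.82, measured conjugation rate 4.6e-12
#'     for the wild-type plasmid (from either host), plaCM rate 100-fold
#'     lower.}
#'   \item{`"figI"`}{as `"figG"` but for the three-population plaCM model:
#'     uncompensated fitness 0.82, plaCM fitness 0.95, gamma_p = 4.6e-12,
#'     gamma_q = gamma_p / 100.}
#' }
#' All share mu = 0.04125 h^-1, eta = 0 and K = 5.7e9 cells ml^-1, and are
#' returned dimensional.
#'
#' @param name One of `"figA"`, `"figG"`, `"figI"`.
#' @return A dimensional `plasmid_params`.
#' @export
#' @examples
#' fixture_params("figG")
fixture_params <- function(name) {
  fixtures <- c("figA", "figG", "figI")
  if (!is.character(name) || length(name) != 1L || !(name %in% fixtures)) {
    rlang::abort(sprintf("unknown fixture `%s`; available: %s",
                         paste(name, collapse = ","),
                         paste(fixtures, collapse = ", ")))
  }
  switch(name,
    figA = parameter_set(
      alpha = 0.5, beta_p = 0.82 * 0.5, beta_c = 0.95 * 0.5,
      beta_q = 0.95 * 0.5, mu = 0.04125,
      gamma_p = 9.9e-12, gamma_c = 9.9e-12, gamma_q = 9.9e-12,
      K = 5.7e9),
    figG = parameter_set(
      alpha = 0.54, beta_p = 0.82 * 0.54, beta_c = 0.97 * 0.54,
      beta_q = 0.95 * 0.54, mu = 0.04125,
      gamma_p = 4.6e-12, gamma_c = 4.6e-12, gamma_q = 4.6e-12 / 100,
      K = 5.7e9),
    figI = parameter_set(
      alpha = 0.54, beta_p = 0.82 * 0.54, beta_c = 0.97 * 0.54,
      beta_q = 0.95 * 0.54, mu = 0.04125,
      gamma_p = 4.6e-12, gamma_c = 4.6e-12, gamma_q = 4.6e-12 / 100,
      K = 5.7e9))
}

#' Read a parameter set from a flat key-value config file
#'
#' Parses a YAML (or flat JSON-style) file with keys `alpha`, `beta_p`,
#' `beta_c`, `beta_q`, `mu`, `eta`, `gamma_p`, `gamma_c`, `gamma_q`, `K`,
#' `dimensionless`. Keys with constructor defaults may be omitted; unknown
#' keys are an error so typos cannot pass silently.
#'
#' @param path Path to the config file.
#' @return A `plasmid_params`.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  raw <- yaml::read_yaml(path)
  allowed <- c("alpha", "beta_p", "beta_c", "beta_q", "mu", "eta",
               "gamma_p", "gamma_c", "gamma_q", "K", "dimensionless")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    rlang::abort(sprintf("unknown parameter keys: %s",
                         paste(unknown, collapse = ", ")))
  }
  required <- c("alpha", "beta_p", "mu")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    rlang::abort(sprintf("missing required parameter keys: %s",
                         paste(missing, collapse = ", ")))
  }
  do.call(parameter_set, raw)
}
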