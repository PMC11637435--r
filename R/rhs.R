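#' Model variants and their state components
#'
#' Four nested model variants are provided. `basic` tracks plasmid-free
#' cells (`f`) and uncompensated plasmid bearers (`p`); `chrcm` adds
#' chromosomally compensated bearers (`c`); `placm` instead adds bearers of
#' the compensated plasmid (`q`); `combined` tracks all four. Densities are
#' dimensionless fractions of the carrying capacity K.
#'
#' @param model One of `"basic"`, `"chrcm"`, `"placm"`, `"combined"`.
#' @return Character vector of component names for the variant.
#' @export
#' @examples
#' model_components("placm")
model_components <- function(model) {
  switch(match.arg(model, c("basic", "chrcm", "placm", "combined")),
         basic = c("f", "p"),
         chrcm = c("f", "p", "c"),
         placm = c("f", "p", "q"),
         combined = c("f", "p", "c", "q"))
}

#' Construct a state vector for a model variant
#'
#' @inheritParams model_components
#' @param f,p,c,q Subpopulation densities as fractions of K. Only the
#'   components of the chosen variant are kept; supplying a nonzero density
#'   for an absent component is an error.
#' @return A named numeric vector with attribute `model`.
#' @export
#' @examples
#' state_vector("chrcm", f = 0.005, p = 0.0025, c = 0.0025)
state_vector <- function(model, f = 0, p = 0, c = 0, q = 0) {
  comp <- model_components(model)
  all4 <- c(f = f, p = p, c = c, q = q)
  if (any(all4 < 0)) rlang::abort("state densities must be nonnegative")
  dropped <- all4[setdiff(names(all4), comp)]
  if (any(dropped != 0)) {
    rlang::abort(sprintf("component(s) %s are not part of the `%s` model",
                         paste(names(dropped)[dropped != 0], collapse = ", "),
                         model))
  }
  structure(all4[comp], model = model)
}

check_state <- function(state, model) {
  comp <- model_components(model)
  if (is.null(names(state))) {
    if (length(state) != length(comp)) {
      rlang::abort(sprintf("`%s` state needs %d components (%s)", model,
                           length(comp), paste(comp, collapse = ", ")))
    }
    names(state) <- comp
  }
  if (!all(comp %in% names(state))) {
    rlang::abort(sprintf("state is missing component(s): %s",
                         paste(setdiff(comp, names(state)), collapse = ", ")))
  }
  state[comp]
}

#' Right-hand sides of the compensation models
#'
#' Time derivatives (h^-1) of the dimensionless subpopulation densities.
#' All variants share the same structure: logistic growth on the free
#' capacity `1 - S` (S the total density), turnover `-mu x`, mass-action
#' conjugation into plasmid-free recipients, and an optional selection
#' pressure `-eta f` on plasmid-free cells only.
#'
#' * `rhs_basic`: df/dt = alpha f (1-f-p) - mu f - gamma_p p f - eta f;
#'   dp/dt = beta_p p (1-f-p) - mu p + gamma_p p f.
#' * `rhs_chrcm`: adds dc/dt = beta_c c (1-S) - mu c. Conjugation from
#'   chrCM hosts transfers the *wild-type* plasmid, so the gamma_c c f flux
#'   leaves `f` and enters `p` (transconjugants are uncompensated).
#' * `rhs_placm`: adds dq/dt = beta_q q (1-S) - mu q + gamma_q q f. The
#'   compensatory mutation travels with the plasmid, so transfer from `q`
#'   creates more `q`.
#' * `rhs_combined`: all four equations; only `f` can receive a plasmid
#'   (resident plasmids exclude superinfection).
#'
#' @param state Named numeric state (fractions of K), as from
#'   [state_vector()].
#' @param params A *dimensionless* [parameter_set()].
#' @return Named numeric vector of derivatives, same shape as `state`.
#' @export
#' @examples
#' p <- nondimensionalize(fixture_params("figA"))
#' rhs_basic(state_vector("basic", f = 0.5), p)
rhs_basic <- function(state, params) {
  require_dimensionless(params)
  y <- check_state(state, "basic")
  s <- 1 - sum(y)
  with(params, c(
    f = alpha * y[["f"]] * s - mu * y[["f"]] - gamma_p * y[["p"]] * y[["f"]] -
      eta * y[["f"]],
    p = beta_p * y[["p"]] * s - mu * y[["p"]] + gamma_p * y[["p"]] * y[["f"]]))
}

#' @rdname rhs_basic
#' @export
rhs_chrcm <- function(state, params) {
  require_dimensionless(params)
  y <- check_state(state, "chrcm")
  s <- 1 - sum(y)
  f <- y[["f"]]; p <- y[["p"]]; cc <- y[["c"]]
  with(params, c(
    f = alpha * f * s - mu * f - gamma_p * p * f - gamma_c * cc * f - eta * f,
    p = beta_p * p * s - mu * p + gamma_p * p * f + gamma_c * cc * f,
    c = beta_c * cc * s - mu * cc))
}

#' @rdname rhs_basic
#' @export
rhs_placm <- function(state, params) {
  require_dimensionless(params)
  y <- check_state(state, "placm")
  s <- 1 - sum(y)
  f <- y[["f"]]; p <- y[["p"]]; q <- y[["q"]]
  with(params, c(
    f = alpha * f * s - mu * f - gamma_p * p * f - gamma_q * q * f - eta * f,
    p = beta_p * p * s - mu * p + gamma_p * p * f,
    q = beta_q * q * s - mu * q + gamma_q * q * f))
}

#' @rdname rhs_basic
#' @export
rhs_combined <- function(state, params) {
  require_dimensionless(params)
  y <- check_state(state, "combined")
  s <- 1 - sum(y)
  f <- y[["f"]]; p <- y[["p"]]; cc <- y[["c"]]; q <- y[["q"]]
  with(params, c(
    f = alpha * f * s - mu * f - (gamma_p * p + gamma_c * cc + gamma_q * q) * f -
      eta * f,
    p = beta_p * p * s - mu * p + (gamma_p * p + gamma_c * cc) * f,
    c = beta_c * cc * s - mu * cc,
    q = beta_q * q * s - mu * q + gamma_q * q * f))
}

model_rhs <- function(model) {
  switch(model, basic = rhs_basic, chrcm = rhs_chrcm,
         placm = rhs_placm, combined = rhs_combined,
         rlang::abort(sprintf("unknown model `%s`", model)))
}

# Analytic Jacobian of the combined model, restricted to the components of
# `model`. Used by the Newton fixed-point solver; stability classification
# uses finite differences independently.
model_jacobian <- function(model, params) {
  comp <- model_components(model)
  function(y) {
    y4 <- c(f = 0, p = 0, c = 0, q = 0)
    y4[comp] <- y
    f <- y4[["f"]]; p <- y4[["p"]]; cc <- y4[["c"]]; q <- y4[["q"]]
    s <- 1 - sum(y4)
    with(params, {
      J <- matrix(0, 4, 4, dimnames = list(c("f", "p", "c", "q"),
                                           c("f", "p", "c", "q")))
      gsum <- gamma_p * p + gamma_c * cc + gamma_q * q
      J["f", "f"] <- alpha * (s - f) - mu - gsum - eta
      J["f", "p"] <- -alpha * f - gamma_p * f
      J["f", "c"] <- -alpha * f - gamma_c * f
      J["f", "q"] <- -alpha * f - gamma_q * f
      J["p", "f"] <- -beta_p * p + gamma_p * p + gamma_c * cc
      J["p", "p"] <- beta_p * (s - p) - mu + gamma_p * f
      J["p", "c"] <- -beta_p * p + gamma_c * f
      J["p", "q"] <- -beta_p * p
      J["c", "f"] <- -beta_c * cc
      J["c", "p"] <- -beta_c * cc
      J["c", "c"] <- beta_c * (s - cc) - mu
      J["c", "q"] <- -beta_c * cc
      J["q", "f"] <- -beta_q * q + gamma_q * q
      J["q", "p"] <- -beta_q * q
      J["q", "c"] <- -beta_q * q
      J["q", "q"] <- beta_q * (s - q) - mu + gamma_q * f
      J[comp, comp, drop = FALSE]
    })
  }
}
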