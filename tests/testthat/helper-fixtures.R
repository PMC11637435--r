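# Random parameter draws used by the property tests. Growth costs span the
# range seen for conjugative megaplasmids (relative fitness 0.6-0.95) and
# turnover sits well below growth so no population is trivially washed out.
rand_basic_params <- function() {
  alpha <- runif(1, 0.4, 1)
  parameter_set(alpha = alpha,
                beta_p = alpha * runif(1, 0.6, 0.95),
                mu = alpha * runif(1, 0.08, 0.3),
                gamma_p = 10^runif(1, -3, -1),
                dimensionless = TRUE)
}

rand_chrcm_params <- function() {
  p <- rand_basic_params()
  p$beta_c <- runif(1, p$beta_p, p$alpha)
  p$gamma_c <- 10^runif(1, -3, -1)
  p
}

# figA growth rates with conjugation rates placed in the bistable ("pink")
# regime: gamma_p below the uncompensated invasion threshold so the
# plasmid-free state is an attractor, gamma_c above the compensated
# domination threshold so chrCM fixation is one too.
pink_params <- function() {
  p <- nondimensionalize(fixture_params("figA"))
  p$gamma_p <- 0.005
  p$gamma_c <- 0.01
  p
}

canonical_init <- function(model, cm_fraction = 0.5, total = 0.01,
                           bearer_fraction = 0.5) {
  bearers <- total * bearer_fraction
  cm <- setdiff(model_components(model), c("f", "p"))
  args <- list(model, f = total - bearers)
  if (length(cm) == 0) {
    args$p <- bearers
  } else if (length(cm) == 1) {
    args$p <- bearers * (1 - cm_fraction)
    args[[cm]] <- bearers * cm_fraction
  } else {
    args$p <- 0
    args$c <- bearers * cm_fraction
    args$q <- bearers * (1 - cm_fraction)
  }
  do.call(state_vector, args)
}
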