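#' Beta-binomial random draws
#'
#' Draws from a beta-binomial parameterised by mean probability `prob` and
#' intraclass correlation `rho` (the overdispersion seen in repeated
#' flow-cytometry sampling of the same culture). The beta shape parameters
#' are a = prob (1 - rho) / rho and b = (1 - prob) (1 - rho) / rho, giving
#' mean `size * prob` and variance
#' `size * prob * (1 - prob) * (1 + (size - 1) * rho)`. `rho = 0`
#' degenerates to the ordinary binomial.
#'
#' @param n Number of draws.
#' @param size Number of trials per draw.
#' @param prob Mean success probability in \[0, 1\].
#' @param rho Intraclass correlation in \[0, 1).
#' @return Integer-valued numeric vector of counts.
#' @export
#' @examples
#' set.seed(1)
#' mean(rbetabinom(1e4, 5000, 0.3, rho = 0.1)) / 5000 # ~0.3
rbetabinom <- function(n, size, prob, rho = 0) {
  if (any(prob < 0 | prob > 1)) rlang::abort("`prob` must lie in [0, 1]")
  if (any(rho < 0 | rho >= 1)) rlang::abort("`rho` must lie in [0, 1)")
  if (rho == 0) return(stats::rbinom(n, size, prob))
  nu <- (1 - rho) / rho
  pi_draw <- numeric(n)
  degen <- prob == 0 | prob == 1
  if (length(prob) == 1) {
    if (degen) {
      pi_draw[] <- prob
    } else {
      pi_draw <- stats::rbeta(n, prob * nu, (1 - prob) * nu)
    }
  } else {
    pi_draw[degen] <- prob[degen]
    pi_draw[!degen] <- stats::rbeta(sum(!degen), prob[!degen] * nu,
                                    (1 - prob[!degen]) * nu)
  }
  stats::rbinom(n, size, pi_draw)
}

#' Generate overdispersed competition counts from a trajectory
#'
#' Emulates the flow-cytometry counting of serial-transfer competition
#' experiments: at each per-transfer endpoint the true subpopulation
#' frequencies are read from the trajectory and labelled-event counts are
#' drawn with beta-binomial noise at intraclass correlation `rho`
#' (`rho = 0` gives clean binomial sampling). Subpopulations are drawn
#' sequentially by stick-breaking, so counts always sum to at most
#' `sample_size` and each subpopulation's marginal mean equals
#' `sample_size` times its true frequency.
#'
#' @param trajectory A serial-transfer `pc_trajectory` (from
#'   [run_serial_transfer()]).
#' @param sample_size Total events recorded per time point.
#' @param rho Overdispersion (intraclass correlation), in \[0, 1).
#' @param n_replicates Number of replicate populations to simulate.
#' @param seed RNG seed; recorded in the output for reproducibility.
#' @return A tibble of class `pc_count_series` with columns `replicate`,
#'   `transfer`, `population`, `count`, `sample_size`, `seed`.
#' @export
generate_competition_counts <- function(trajectory, sample_size,
                                        rho = 0.05, n_replicates = 1,
                                        seed = 1) {
  stopifnot(inherits(trajectory, "pc_trajectory"))
  if (sample_size < 1) rlang::abort("`sample_size` must be at least 1")
  if (rho < 0 || rho >= 1) rlang::abort("`rho` must lie in [0, 1)")
  model <- attr(trajectory, "model")
  comp <- model_components(model)
  ends <- transfer_endpoints(trajectory)
  dens <- as.matrix(ends[comp])
  tot <- rowSums(dens)
  freq <- sweep(dens, 1, ifelse(tot > 0, tot, 1), "/")
  freq[tot == 0, ] <- 0
  if (any(freq < 0 | freq > 1)) {
    rlang::abort("trajectory frequencies fall outside [0, 1]")
  }
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n_replicates), function(rep_i) {
      purrr::map(seq_len(nrow(freq)), function(i) {
        remaining <- sample_size
        mass <- 1
        counts <- integer(length(comp))
        for (k in seq_along(comp)) {
          pk <- if (mass > 0) min(1, freq[i, k] / mass) else 0
          counts[k] <- rbetabinom(1, remaining, pk, rho)
          remaining <- remaining - counts[k]
          mass <- mass - freq[i, k]
        }
        tibble::tibble(replicate = rep_i, transfer = ends$transfer_index[i],
                       population = comp, count = counts,
                       sample_size = sample_size, seed = seed)
      })
    })
    out <- dplyr::bind_rows(purrr::flatten(rows))
    structure(out, class = c("pc_count_series", class(out)))
  })
}

#' Forward-simulate a conjugation assay
#'
#' Integrates the donor/recipient/transconjugant mass-action system
#' \deqn{dD/dt = \psi_D D,\quad dR/dt = \psi_R R - \gamma D R
#'   (- \gamma_T T R),\quad dT/dt = \psi_T T + \gamma D R (+ \gamma_T T R)}
#' in exponential phase and returns the end-point densities in the column
#' layout expected by [estimate_gamma()]. Donors and transconjugants carry
#' the plasmid and grow at `beta_p`; recipients are plasmid-free and grow
#' at `alpha`. Serves as the simulation oracle for the end-point
#' estimators. Onward transfer from transconjugants is off by default
#' (short-window design); optional Poisson counting noise emulates plating
#' a fixed sample volume.
#'
#' @param params A [parameter_set()] supplying `alpha` (recipient growth)
#'   and `beta_p` (donor/transconjugant growth).
#' @param gamma_true True conjugation rate (ml cell^-1 h^-1).
#' @param t Assay duration (h).
#' @param D0,R0 Initial densities (cells ml^-1). The
#'   `"excess_recipient"` preset overrides these with a 100-fold recipient
#'   excess and an 18 h window.
#' @param preset `"standard"` (4 h, equal inocula) or `"excess_recipient"`.
#' @param onward Allow conjugation from transconjugants at `gamma_true`.
#' @param noise Add Poisson counting noise at sampling volume `volume_ml`.
#' @param volume_ml Sampled volume for the Poisson noise (ml).
#' @param seed RNG seed used when `noise = TRUE`.
#' @return One-row tibble: `D0, R0, Dt, Rt, Tt, t_h, psi_d, psi_r, psi_t`.
#' @export
#' @examples
#' a <- simulate_assay(fixture_params("figG"), gamma_true = 1e-11)
#' estimate_gamma(a)$gamma # within 2-fold of 1e-11
simulate_assay <- function(params, gamma_true, t = 4, D0 = 1e7, R0 = 1e7,
                           preset = c("standard", "excess_recipient"),
                           onward = FALSE, noise = FALSE, volume_ml = 1e-4,
                           seed = 1) {
  stopifnot(inherits(params, "plasmid_params"))
  if (gamma_true < 0) rlang::abort("`gamma_true` must be nonnegative")
  preset <- match.arg(preset)
  if (preset == "excess_recipient") {
    R0 <- 100 * D0
    t <- 18
  }
  pars <- if (params$dimensionless) dimensionalize(params) else params
  psi_d <- pars$beta_p
  psi_r <- pars$alpha
  psi_t <- pars$beta_p
  rhs <- function(tt, y, p) {
    transfer <- gamma_true * y[1] * y[2] +
      if (onward) gamma_true * y[3] * y[2] else 0
    list(c(psi_d * y[1], psi_r * y[2] - transfer, psi_t * y[3] + transfer))
  }
  out <- deSolve::ode(c(D = D0, R = R0, T = 0), c(0, t), rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-6)
  if (nrow(out) < 2) rlang::abort(sprintf("assay integration failed (t = %g)", t))
  final <- pmax(out[2, -1], 0)
  if (noise) {
    final <- withr::with_seed(seed, {
      stats::rpois(3, final * volume_ml) / volume_ml
    })
  }
  tibble::tibble(D0 = D0, R0 = R0, Dt = final[[1]], Rt = final[[2]],
                 Tt = final[[3]], t_h = t, psi_d = psi_d, psi_r = psi_r,
                 psi_t = psi_t)
}
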