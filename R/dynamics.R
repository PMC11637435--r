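#' Serial-transfer protocol
#'
#' Describes a batch-culture experiment with repeated fixed-fraction
#' dilution into fresh medium. The defaults follow the study design of
#' daily 1% transfers for 8 days (about 50 generations, since each batch
#' regrows 100-fold, i.e. log2(100) ~ 6.6 doublings).
#'
#' @param n_transfers Number of transfers (batches).
#' @param dilution Fraction of the population carried over at each
#'   transfer; must lie strictly between 0 and 1.
#' @param hours_per_transfer Duration of each batch (h).
#' @return A list of class `transfer_protocol`.
#' @export
#' @examples
#' transfer_protocol()
#' transfer_generations(transfer_protocol()) # ~53 generations
transfer_protocol <- function(n_transfers = 8, dilution = 0.01,
                              hours_per_transfer = 24) {
  if (!(dilution > 0 && dilution < 1)) {
    rlang::abort("`dilution` must lie strictly between 0 and 1")
  }
  if (n_transfers < 1) rlang::abort("`n_transfers` must be at least 1")
  structure(list(n_transfers = as.integer(n_transfers), dilution = dilution,
                 hours_per_transfer = hours_per_transfer),
            class = "transfer_protocol")
}

#' @rdname transfer_protocol
#' @param protocol A [transfer_protocol()].
#' @export
transfer_generations <- function(protocol) {
  stopifnot(inherits(protocol, "transfer_protocol"))
  protocol$n_transfers * log2(1 / protocol$dilution)
}

new_trajectory <- function(df, model, params, regime, protocol = NULL) {
  out <- tibble::as_tibble(df)
  structure(out,
            class = c("pc_trajectory", class(out)),
            model = model, params = params, regime = regime,
            protocol = protocol)
}

# deSolve wrapper; clips round-off negatives (anything in [-1e-12, 0)) to
# zero and records how many values were clipped.
integrate_raw <- function(model, params, init, times, rtol = 1e-8,
                          atol = 1e-12) {
  comp <- model_components(model)
  rhs <- model_rhs(model)
  fun <- function(t, y, parms) list(unname(rhs(stats::setNames(y, comp), parms)))
  y0 <- unname(check_state(init, model))
  out <- try(deSolve::ode(y = y0, times = times, func = fun, parms = params,
                          method = "lsoda", rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times)) {
    t_fail <- if (inherits(out, "try-error")) times[1] else out[nrow(out), 1]
    rlang::abort(sprintf("integration failed near t = %g h", t_fail))
  }
  m <- out[, -1, drop = FALSE]
  neg <- m < 0
  if (any(neg)) {
    if (any(m[neg] < -1e-12)) {
      rlang::warn(sprintf("clipped %d negative densities below -1e-12 (min %g)",
                          sum(m[neg] < -1e-12), min(m)))
    }
    m[neg] <- 0
  }
  colnames(m) <- comp
  list(times = out[, 1], states = m, n_clipped = sum(neg))
}

#' Continuous-flow simulation
#'
#' Integrates a model variant as an open (chemostat-like) system in which
#' turnover `mu` removes all populations continuously. Uses a stiff-capable
#' solver (lsoda) at rtol 1e-8 / atol 1e-12 with dense output.
#'
#' @inheritParams rhs_basic
#' @param model Model variant name (see [model_components()]).
#' @param init Initial state, e.g. from [state_vector()]; nonnegative with
#'   total at most 1.
#' @param t_end Horizon (h).
#' @param n_out Number of output samples (at least 200).
#' @return A `pc_trajectory` tibble with columns `time_h`, one column per
#'   model component, `regime` and `transfer_index`.
#' @export
#' @examples
#' p <- nondimensionalize(fixture_params("figA"))
#' tr <- integrate_continuous("chrcm", p,
#'                            state_vector("chrcm", f = 0.005, p = 0.0025,
#'                                         c = 0.0025), t_end = 500)
#' dplyr::slice_tail(tr, n = 1)
integrate_continuous <- function(model, params, init, t_end, n_out = 201) {
  require_dimensionless(params)
  n_out <- max(201, n_out)
  y0 <- check_state(init, model)
  if (sum(y0) > 1 + 1e-9) rlang::abort("initial total density must be <= 1")
  times <- seq(0, t_end, length.out = n_out)
  raw <- integrate_raw(model, params, y0, times)
  df <- tibble::as_tibble(as.data.frame(raw$states))
  df <- dplyr::bind_cols(tibble::tibble(time_h = raw$times), df)
  df$regime <- "continuous_flow"
  df$transfer_index <- NA_integer_
  new_trajectory(df, model, params, "continuous_flow")
}

#' Serial-transfer simulation
#'
#' Emulates batch-culture evolution experiments: within each batch the
#' populations grow (and conjugate) in a closed culture, so turnover is set
#' to zero (`mu = 0`) while any selection pressure `eta` is kept; at the end
#' of each batch all densities are multiplied by the dilution factor.
#'
#' @inheritParams integrate_continuous
#' @param protocol A [transfer_protocol()].
#' @param n_within Output samples within each batch.
#' @return A `pc_trajectory` tibble; `transfer_index` numbers the batch each
#'   row belongs to, and batch-endpoint rows (sampled just before dilution)
#'   are marked in the `endpoint` column.
#' @export
run_serial_transfer <- function(model, params, protocol, init,
                                n_within = 25) {
  require_dimensionless(params)
  stopifnot(inherits(protocol, "transfer_protocol"))
  batch_params <- params
  batch_params$mu <- 0
  y <- check_state(init, model)
  if (sum(y) > 1 + 1e-9) rlang::abort("initial total density must be <= 1")
  comp <- model_components(model)
  pieces <- vector("list", protocol$n_transfers)
  t0 <- 0
  for (i in seq_len(protocol$n_transfers)) {
    times <- seq(0, protocol$hours_per_transfer, length.out = n_within)
    raw <- integrate_raw(model, batch_params, y, times)
    df <- tibble::as_tibble(as.data.frame(raw$states))
    df <- dplyr::bind_cols(tibble::tibble(time_h = t0 + raw$times), df)
    df$transfer_index <- i
    df$endpoint <- c(rep(FALSE, n_within - 1), TRUE)
    pieces[[i]] <- df
    y <- stats::setNames(raw$states[n_within, ], comp) * protocol$dilution
    t0 <- t0 + protocol$hours_per_transfer
  }
  df <- dplyr::bind_rows(pieces)
  df$regime <- "serial_transfer"
  new_trajectory(df, model, params, "serial_transfer", protocol)
}

#' Per-transfer endpoint compositions of a serial-transfer trajectory
#'
#' @param trajectory A `pc_trajectory` from [run_serial_transfer()].
#' @return Tibble of the batch-endpoint rows (one per transfer).
#' @export
transfer_endpoints <- function(trajectory) {
  stopifnot(inherits(trajectory, "pc_trajectory"))
  if (!identical(attr(trajectory, "regime"), "serial_transfer")) {
    rlang::abort("`trajectory` is not from a serial-transfer simulation")
  }
  dplyr::filter(tibble::as_tibble(trajectory), .data$endpoint)
}

#' Long-run outcome of a model
#'
#' Integrates to a long horizon and reports which subpopulations survive.
#' A subpopulation survives if its density exceeds `eps` at the horizon
#' *and* its time-average over the last 10% of the horizon exceeds `eps`,
#' which makes the call robust to oscillatory attractors (a population
#' cycling above `eps` on average is coexistence, not extinction).
#'
#' @inheritParams integrate_continuous
#' @param eps Extinction threshold (fraction of K).
#' @return Character vector of surviving component names.
#' @export
#' @examples
#' p <- nondimensionalize(fixture_params("figA"))
#' long_run_outcome("basic", p, state_vector("basic", f = 0.005, p = 0.005))
long_run_outcome <- function(model, params, init, t_end = 1e4, eps = 1e-6) {
  require_dimensionless(params)
  comp <- model_components(model)
  times <- seq(0, t_end, length.out = 301)
  raw <- integrate_raw(model, params, check_state(init, model), times)
  tail_rows <- raw$times >= 0.9 * t_end
  tail_mean <- colMeans(raw$states[tail_rows, , drop = FALSE])
  final <- raw$states[nrow(raw$states), ]
  comp[final > eps & tail_mean > eps]
}

#' Weaponisation contrast experiment
#'
#' Compares the fate of the chromosomally compensated population (chrCM,
#' `c`) with and without its ability to conjugate the costly wild-type
#' plasmid into competitors. The system is simulated twice from the same
#' initial condition: once with `gamma_c` as given and once with
#' `gamma_c = 0`. When compensation is imperfect (`beta_c < alpha`), chrCM
#' can only beat plasmid-free competitors by burdening them with the costly
#' plasmid ("weaponisation"); removing its conjugation rate then prevents
#' fixation.
#'
#' @inheritParams integrate_continuous
#' @param params Dimensionless parameters for a `chrcm` or `combined` model.
#' @param model `"combined"` (default) or `"chrcm"`.
#' @param fixation_threshold chrCM frequency (of total survivors at the
#'   horizon) above which chrCM counts as fixed.
#' @return A list of class `pc_weaponisation` with elements `trajectories`
#'   (with and without conjugation), `outcomes` (surviving sets),
#'   `cm_frequency` (chrCM frequency at the horizon in each arm),
#'   `cm_fixes` (logical per arm) and `differs` (whether fixation status
#'   differs between arms).
#' @export
weaponisation_contrast <- function(params, init, model = "combined",
                                   t_end = 1e4,
                                   fixation_threshold = 0.99) {
  require_dimensionless(params)
  if (!model %in% c("chrcm", "combined")) {
    rlang::abort("`model` must be \"chrcm\" or \"combined\"")
  }
  params0 <- params
  params0$gamma_c <- 0
  arms <- list(with_conjugation = params, without_conjugation = params0)
  traj <- purrr::map(arms, function(pp) {
    integrate_continuous(model, pp, init, t_end = t_end)
  })
  freq <- purrr::map_dbl(traj, function(tr) {
    last <- dplyr::slice_tail(tibble::as_tibble(tr), n = 1)
    dens <- unlist(last[model_components(model)])
    if (sum(dens) <= 0) return(0)
    dens[["c"]] / sum(dens)
  })
  outcomes <- purrr::map(arms, function(pp) {
    long_run_outcome(model, pp, init, t_end = t_end)
  })
  fixes <- freq > fixation_threshold
  structure(list(trajectories = traj, outcomes = outcomes,
                 cm_frequency = freq, cm_fixes = fixes,
                 differs = fixes[[1]] != fixes[[2]]),
            class = "pc_weaponisation")
}

#' @export
print.pc_weaponisation <- function(x, ...) {
  cat("<pc_weaponisation>\n")
  cat(sprintf("  gamma_c as given: chrCM frequency %.4f (%s)\n",
              x$cm_frequency[[1]],
              if (x$cm_fixes[[1]]) "fixes" else "does not fix"))
  cat(sprintf("  gamma_c = 0:      chrCM frequency %.4f (%s)\n",
              x$cm_frequency[[2]],
              if (x$cm_fixes[[2]]) "fixes" else "does not fix"))
  cat(sprintf("  fixation status differs between arms: %s\n", x$differs))
  invisible(x)
}

#' Scan conjugation-rate reduction for three-population coexistence
#'
#' For the plaCM model, scans fold-reductions `r` of the compensated
#' plasmid's conjugation rate (`gamma_q = gamma_p / r`) and asks, for each,
#' whether plasmid-free (`f`), wild-type plasmid (`p`) and plaCM (`q`)
#' populations all persist — the oscillatory rock-paper-scissors
#' coexistence regime. Persistence is established by a stable interior
#' fixed point (via [find_fixed_points()]) together with long-horizon
#' integration from the canonical initial condition.
#'
#' @param params Parameter set (dimensional or dimensionless) supplying
#'   `alpha`, `beta_p`, `beta_q`, `mu` and the wild-type rate `gamma_p`.
#' @param reductions Fold-reductions to scan.
#' @param init Initial state; defaults to the canonical low-density
#'   inoculum (total 0.01 of K, half plasmid-bearing, half of the bearers
#'   compensated).
#' @param t_end Integration horizon (h).
#' @return A tibble of class `pc_rps_scan` with columns `reduction`,
#'   `gamma_q`, `has_interior_fp`, `interior_stability`, `survivors`
#'   (list-column) and `coexists`.
#' @export
rps_scan <- function(params, reductions = c(1, 3, 10, 30, 100, 300),
                     init = NULL, t_end = 1e4) {
  params <- as_dimensionless(params)
  if (is.null(init)) {
    init <- state_vector("placm", f = 0.005, p = 0.0025, q = 0.0025)
  }
  rows <- purrr::map(reductions, function(r) {
    pr <- params
    pr$gamma_q <- params$gamma_p / r
    fps <- find_fixed_points("placm", pr)
    interior <- dplyr::filter(fps, .data$composition == "interior")
    stab <- if (nrow(interior)) interior$stability[[1]] else NA_character_
    has_fp <- nrow(interior) > 0 &&
      any(interior$stability %in% c("stable_node", "stable_spiral"))
    surv <- long_run_outcome("placm", pr, init, t_end = t_end)
    tibble::tibble(reduction = r, gamma_q = pr$gamma_q,
                   has_interior_fp = has_fp, interior_stability = stab,
                   survivors = list(surv),
                   coexists = has_fp || setequal(surv, c("f", "p", "q")))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pc_rps_scan", class(out))
  out
}

#' @rdname rps_scan
#' @param scan A `pc_rps_scan` result.
#' @return `min_rps_reduction()`: the smallest scanned fold-reduction at
#'   which all three populations coexist, or `Inf` if none does.
#' @export
min_rps_reduction <- function(scan) {
  stopifnot(inherits(scan, "pc_rps_scan"))
  hit <- scan$reduction[scan$coexists]
  if (!length(hit)) Inf else min(hit)
}
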