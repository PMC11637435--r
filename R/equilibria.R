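#' Analytical invasion and domination thresholds
#'
#' For the two-member (plasmid-free vs plasmid-bearing) system, a costly
#' plasmid with dimensionless conjugation rate gamma invades the resident
#' plasmid-free equilibrium only if gamma exceeds the *invasion* threshold
#' mu (alpha - beta) / (alpha - mu), and competitively displaces the
#' plasmid-free population only if gamma exceeds the larger *domination*
#' threshold mu (alpha - beta) / (beta - mu). Both vanish for a costless
#' plasmid (beta = alpha).
#'
#' @param alpha Plasmid-free growth rate (h^-1); must exceed `mu`.
#' @param beta Plasmid-bearer growth rate (h^-1); for the domination
#'   threshold it must exceed `mu`.
#' @param mu Turnover rate (h^-1).
#' @return Dimensionless conjugation-rate threshold (divide by K for the
#'   dimensional rate in ml cell^-1 h^-1).
#' @export
#' @examples
#' gamma_invasion_threshold(0.5, 0.41, 0.04125)
#' gamma_domination_threshold(0.5, 0.41, 0.04125)
gamma_invasion_threshold <- function(alpha, beta, mu) {
  if (any(alpha <= mu)) {
    rlang::abort("invasion threshold undefined: `alpha` must exceed `mu` (washout)")
  }
  mu * (alpha - beta) / (alpha - mu)
}

#' @rdname gamma_invasion_threshold
#' @export
gamma_domination_threshold <- function(alpha, beta, mu) {
  if (any(beta <= mu)) {
    rlang::abort("domination threshold undefined: `beta` must exceed `mu` (washout)")
  }
  mu * (alpha - beta) / (beta - mu)
}

#' Minimum chrCM growth rate for persistence under conjugation-rate loss
#'
#' A chromosomal compensatory mutation that reduces the plasmid's
#' conjugation rate to gamma_c persists only if compensation is strong
#' enough: beta_c must exceed mu (gamma_c + alpha) / (mu + gamma_c). With
#' no conjugation (gamma_c = 0) the bound is alpha itself; as gamma_c grows
#' the bound relaxes towards mu.
#'
#' @param alpha Plasmid-free growth rate (h^-1).
#' @param mu Turnover rate (h^-1).
#' @param gamma_c Dimensionless chrCM conjugation rate.
#' @return Minimum `beta_c` (h^-1).
#' @export
chrcm_persistence_bound <- function(alpha, mu, gamma_c) {
  if (any(gamma_c < 0)) rlang::abort("`gamma_c` must be nonnegative")
  mu * (gamma_c + alpha) / (mu + gamma_c)
}

#' Fold by which a measured conjugation rate exceeds the domination threshold
#'
#' @param gamma_measured Measured dimensional conjugation rate
#'   (ml cell^-1 h^-1).
#' @inheritParams gamma_invasion_threshold
#' @param K Carrying capacity (cells ml^-1).
#' @return `gamma_measured` divided by the dimensional domination threshold.
#' @export
#' @examples
#' # chrCM: measured rate exceeds its domination threshold ~19-fold
#' domination_fold_excess(4.6e-12, 0.54, 0.97 * 0.54, 0.04125, 5.7e9)
domination_fold_excess <- function(gamma_measured, alpha, beta, mu, K) {
  if (any(gamma_measured <= 0)) rlang::abort("`gamma_measured` must be positive")
  gamma_measured / (gamma_domination_threshold(alpha, beta, mu) / K)
}

# ---------------------------------------------------------------------------
# Fixed points

comp_label <- function(dens, comp, tol = 1e-7) {
  nz <- comp[dens > tol]
  cm <- intersect(nz, c("c", "q"))
  if (length(nz) == 0) return("extinct")
  if (setequal(nz, "f")) return("plasmid_free_only")
  if (setequal(nz, "p")) return("plasmid_only")
  if (length(nz) == length(cm)) return("cm_only")
  if (setequal(nz, c("f", "p"))) return("mixed_fp")
  if (length(nz) == length(comp)) return("interior")
  "mixed_other"
}

newton_root <- function(fun, jac, x0, tol = 1e-12, max_iter = 60) {
  x <- x0
  fx <- fun(x)
  for (i in seq_len(max_iter)) {
    if (!all(is.finite(fx))) return(NULL)
    if (max(abs(fx)) < tol) return(x)
    J <- jac(x)
    step <- try(solve(J, fx), silent = TRUE)
    if (inherits(step, "try-error") || !all(is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      x_new <- x - lambda * step
      fx_new <- fun(x_new)
      if (all(is.finite(fx_new)) &&
          (max(abs(fx_new)) < max(abs(fx)) || lambda < 1e-4)) break
      lambda <- lambda / 2
    }
    x <- x_new
    fx <- fx_new
  }
  if (max(abs(fx)) < tol) x else NULL
}

# Local minima of |RHS|^2 on a regular grid over the simplex, used to seed
# Newton iterations for interior fixed points. Points outside the simplex
# (total > 1) get +Inf so they never seed.
grid_seed_minima <- function(fun_vec, d, n_grid) {
  axes <- rep(list(seq(0, 1, length.out = n_grid)), d)
  grid <- as.matrix(expand.grid(axes))
  norms <- fun_vec(grid)
  norms[rowSums(grid) > 1 + 1e-9] <- Inf
  arr <- array(norms, dim = rep(n_grid, d))
  is_min <- array(TRUE, dim = dim(arr))
  idx_all <- lapply(rep(n_grid, d), seq_len)
  for (k in seq_len(d)) {
    for (shift in c(-1L, 1L)) {
      idx_from <- idx_all
      idx_to <- idx_all
      if (shift == 1L) {
        idx_from[[k]] <- 2:n_grid; idx_to[[k]] <- 1:(n_grid - 1)
      } else {
        idx_from[[k]] <- 1:(n_grid - 1); idx_to[[k]] <- 2:n_grid
      }
      neighbour <- do.call(`[`, c(list(arr), idx_from, list(drop = FALSE)))
      here <- do.call(`[`, c(list(arr), idx_to, list(drop = FALSE)))
      ok <- here <= neighbour
      sub <- as.matrix(expand.grid(idx_to))
      is_min[sub] <- is_min[sub] & as.vector(ok)
    }
  }
  keep <- which(as.vector(is_min) & is.finite(norms))
  grid[keep, , drop = FALSE]
}

# Vectorised |RHS|^2 over a matrix of states (rows), for grid prefiltering.
rhs_norm2_vec <- function(model, params) {
  comp <- model_components(model)
  function(m) {
    y4 <- matrix(0, nrow(m), 4, dimnames = list(NULL, c("f", "p", "c", "q")))
    y4[, comp] <- m
    f <- y4[, "f"]; p <- y4[, "p"]; cc <- y4[, "c"]; q <- y4[, "q"]
    s <- 1 - rowSums(y4)
    with(params, {
      dfd <- alpha * f * s - mu * f -
        (gamma_p * p + gamma_c * cc + gamma_q * q) * f - eta * f
      dpd <- beta_p * p * s - mu * p + (gamma_p * p + gamma_c * cc) * f
      dcd <- beta_c * cc * s - mu * cc
      dqd <- beta_q * q * s - mu * q + gamma_q * q * f
      d4 <- cbind(f = dfd, p = dpd, c = dcd, q = dqd)
      rowSums(d4[, comp, drop = FALSE]^2)
    })
  }
}

# Deterministic analytic seed candidates: extinction, single-population
# logistic balances, and pairwise combinations at their single-population
# levels (good Newton starting guesses for mixed boundary roots).
analytic_seeds <- function(model, params) {
  comp <- model_components(model)
  d <- length(comp)
  growth <- c(f = params$alpha, p = params$beta_p, c = params$beta_c,
              q = params$beta_q)[comp]
  level <- pmax(0, 1 - params$mu / growth)
  seeds <- list(rep(0, d))
  for (i in seq_len(d)) {
    s <- rep(0, d)
    s[i] <- level[i]
    seeds <- c(seeds, list(s))
  }
  if (d >= 2) {
    for (i in seq_len(d - 1)) {
      for (j in (i + 1):d) {
        s <- rep(0, d)
        s[i] <- level[i] / 2
        s[j] <- level[j] / 2
        seeds <- c(seeds, list(s))
      }
    }
  }
  do.call(rbind, seeds)
}

#' Find all fixed points of a model variant
#'
#' Locates roots of the right-hand side by damped Newton iteration from a
#' deterministic seed set: the analytic boundary candidates (extinction,
#' single-population logistic balances `1 - mu/rate`, pairwise mixtures)
#' plus the local minima of the squared RHS norm on a regular grid over the
#' density simplex (21 points per axis by default). Roots are deduplicated
#' at distance 1e-6, restricted to the nonnegative simplex, and returned
#' with their residual, finite-difference stability classification and a
#' composition label.
#'
#' @inheritParams integrate_continuous
#' @param n_grid Grid resolution per axis for interior seeding.
#' @param dedup_tol Distance below which two roots are considered the same.
#' @return A tibble of class `pc_fixed_points` with one row per fixed
#'   point: the component densities, `residual` (max |RHS|), `stability`
#'   and `composition`.
#' @export
#' @examples
#' p <- nondimensionalize(fixture_params("figA"))
#' find_fixed_points("basic", p)
find_fixed_points <- function(model, params, n_grid = 21, dedup_tol = 1e-6) {
  require_dimensionless(params)
  comp <- model_components(model)
  d <- length(comp)
  rhs <- model_rhs(model)
  fun <- function(x) unname(rhs(stats::setNames(x, comp), params))
  jac <- model_jacobian(model, params)
  seeds <- rbind(analytic_seeds(model, params),
                 grid_seed_minima(rhs_norm2_vec(model, params), d, n_grid))
  roots <- list()
  for (i in seq_len(nrow(seeds))) {
    x0 <- seeds[i, ]
    if (length(roots) &&
        any(vapply(roots, function(r) max(abs(r - x0)) < 1e-3, logical(1)))) {
      next
    }
    x <- newton_root(fun, jac, x0)
    if (is.null(x)) next
    x[abs(x) < 1e-10] <- 0
    if (any(x < -1e-8) || sum(x) > 1 + 1e-6) next
    x <- pmax(x, 0)
    if (length(roots) &&
        any(vapply(roots, function(r) max(abs(r - x)) < dedup_tol, logical(1)))) {
      next
    }
    roots <- c(roots, list(x))
  }
  if (!length(roots)) {
    rlang::warn("no fixed points converged from any seed")
    out <- tibble::tibble(residual = numeric(), stability = character(),
                          composition = character())
    for (nm in rev(comp)) out <- tibble::add_column(out, !!nm := numeric(),
                                                    .before = 1)
    return(structure(out, class = c("pc_fixed_points", class(out)),
                     model = model, params = params))
  }
  rows <- purrr::map(roots, function(x) {
    st <- stats::setNames(x, comp)
    res <- max(abs(fun(x)))
    tibble::tibble(!!!as.list(st), residual = res,
                   stability = classify_stability(model, params, st),
                   composition = comp_label(st, comp))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$composition)
  structure(out, class = c("pc_fixed_points", class(out)),
            model = model, params = params)
}

# Central finite-difference Jacobian, relative step h.
fd_jacobian <- function(fun, x, h = 1e-7) {
  d <- length(x)
  f0 <- fun(x)
  J <- matrix(0, length(f0), d)
  for (j in seq_len(d)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xm <- x
    xp[j] <- xp[j] + hj
    xm[j] <- xm[j] - hj
    J[, j] <- (fun(xp) - fun(xm)) / (2 * hj)
  }
  J
}

#' Classify the linear stability of a fixed point
#'
#' Builds the Jacobian by central finite differences (relative step 1e-7),
#' computes its eigenvalues, and labels the point: `stable_node` /
#' `stable_spiral` when all real parts are negative (spiral if a complex
#' pair with |Im| > 1e-8 is present), `unstable_node` / `unstable_spiral`
#' when all are positive, `saddle` for mixed signs, and `nonhyperbolic`
#' whenever some eigenvalue's real part has magnitude at most 1e-8 — no
#' guess is made in that case.
#'
#' @inheritParams integrate_continuous
#' @param point Named state at (or very near) a fixed point.
#' @param re_tol Hyperbolicity tolerance on eigenvalue real parts.
#' @param im_tol Threshold on |Im| for spiral classification.
#' @return A stability label (character scalar).
#' @export
classify_stability <- function(model, params, point, re_tol = 1e-8,
                               im_tol = 1e-8) {
  require_dimensionless(params)
  comp <- model_components(model)
  rhs <- model_rhs(model)
  x <- unname(check_state(point, model))
  fun <- function(y) unname(rhs(stats::setNames(y, comp), params))
  ev <- eigen(fd_jacobian(fun, x), only.values = TRUE)$values
  re <- Re(ev)
  has_spiral <- any(abs(Im(ev)) > im_tol)
  if (any(abs(re) <= re_tol)) return("nonhyperbolic")
  if (all(re < 0)) return(if (has_spiral) "stable_spiral" else "stable_node")
  if (all(re > 0)) return(if (has_spiral) "unstable_spiral" else "unstable_node")
  "saddle"
}

#' Critical initial chrCM fraction for fixation (basin boundary)
#'
#' In the regime where compensation is imperfect (`beta_c < alpha`) and the
#' chrCM conjugation rate is below its domination requirement, the chrCM
#' fixation point and the chrCM-free attractor are separated by a saddle:
#' fixation then depends on the initial chrCM fraction. This function
#' locates the separating fraction by bisection (to `tol` on the fraction)
#' on the initial share of plasmid-bearers that carry the compensatory
#' mutation, judging each outcome with [long_run_outcome()].
#'
#' @inheritParams integrate_continuous
#' @param total Initial total density (fraction of K).
#' @param bearer_fraction Initial fraction of the population bearing a
#'   plasmid.
#' @param tol Bisection tolerance on the fraction.
#' @param t_end Horizon passed to [long_run_outcome()].
#' @return The critical chrCM fraction of plasmid-bearers (between 0 and 1).
#' @export
basin_threshold_chrcm <- function(params, total = 0.01,
                                  bearer_fraction = 0.5, tol = 1e-4,
                                  t_end = 1e4) {
  params <- as_dimensionless(params)
  bearers <- total * bearer_fraction
  wins <- function(x) {
    init <- state_vector("chrcm", f = total - bearers,
                         p = bearers * (1 - x), c = bearers * x)
    "c" %in% long_run_outcome("chrcm", params, init, t_end = t_end)
  }
  lo <- 1e-6
  hi <- 1 - 1e-6
  w_lo <- wins(lo)
  w_hi <- wins(hi)
  if (w_lo == w_hi) {
    rlang::abort(sprintf(
      "no threshold in this regime: chrCM %s from any initial fraction",
      if (w_lo) "fixes" else "is lost"))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (wins(mid) == w_hi) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Classify the phase region of a compensation model
#'
#' Combines fixed-point analysis with a confirmation simulation from the
#' canonical initial condition (total density 0.01 of K, plasmid-bearers at
#' 50%, the compensatory mutant at 50% of bearers) to name the region of
#' parameter space the system sits in, mirroring the phase-diagram layout:
#'
#' * `wildtype_plasmid_lost` — plaCM with `gamma_q > gamma_p`: the
#'   wild-type plasmid is always lost (assigned without simulation);
#' * `cm_fixes_always` — the CM fixation point is the only attractor;
#' * `cm_fixes_above_saddle` — CM fixation coexists with a CM-free
#'   attractor, separated by a saddle (initial-condition dependence);
#' * `rps_coexistence` — a stable interior (all-population) fixed point,
#'   typically a spiral, exists;
#' * `mixed_fp_persists` — the CM is lost and plasmid-free and wild-type
#'   plasmid coexist;
#' * `plasmid_free_wins` — the plasmid-free fixation point is the only
#'   attractor;
#' * `cm_lost` — any other stable configuration without the CM;
#' * `conflict` — the confirmation simulation reached a composition not
#'   matching any stable fixed point (reported explicitly, never silently
#'   resolved).
#'
#' @inheritParams integrate_continuous
#' @param model `"chrcm"` or `"placm"`.
#' @param t_end Horizon for the confirmation simulation.
#' @return A list of class `pc_region` with elements `model`, `label`,
#'   `attractors` (tibble of stable fixed points), `fixed_points` (all of
#'   them) and `simulated_survivors`.
#' @export
classify_region <- function(model, params, t_end = 1e4) {
  if (!model %in% c("chrcm", "placm")) {
    rlang::abort("`model` must be \"chrcm\" or \"placm\"")
  }
  params <- as_dimensionless(params)
  cm <- if (model == "chrcm") "c" else "q"
  region <- function(label, fps, attractors, surv = NULL) {
    structure(list(model = model, label = label, attractors = attractors,
                   fixed_points = fps, simulated_survivors = surv),
              class = "pc_region")
  }
  if (model == "placm" && params$gamma_q > params$gamma_p) {
    return(region("wildtype_plasmid_lost", NULL, NULL))
  }
  fps <- find_fixed_points(model, params)
  stable <- dplyr::filter(fps, .data$stability %in%
                            c("stable_node", "stable_spiral"))
  bearers <- 0.005
  init <- stats::setNames(c(0.005, bearers / 2, bearers / 2),
                          c("f", "p", cm))
  surv <- long_run_outcome(model, params, init, t_end = t_end)
  comp <- model_components(model)
  # does the simulated surviving set match some stable fixed point?
  matches <- any(purrr::map_lgl(seq_len(nrow(stable)), function(i) {
    dens <- unlist(stable[i, comp])
    setequal(comp[dens > 1e-5], surv)
  }))
  label <- if (any(stable$composition == "interior")) {
    "rps_coexistence"
  } else if (any(stable$composition == "cm_only")) {
    others <- dplyr::filter(stable, .data$composition != "cm_only")
    if (nrow(others) == 0) "cm_fixes_always" else "cm_fixes_above_saddle"
  } else if (any(stable$composition == "mixed_fp")) {
    "mixed_fp_persists"
  } else if (nrow(stable) > 0 &&
             all(stable$composition == "plasmid_free_only")) {
    "plasmid_free_wins"
  } else {
    "cm_lost"
  }
  # the saddle-split label implies initial-condition dependence; either
  # attractor is a legitimate simulation endpoint there
  if (!matches && label != "cm_fixes_above_saddle") label <- "conflict"
  region(label, fps, stable, surv)
}

#' @export
print.pc_region <- function(x, ...) {
  cat("<pc_region>", x$model, "model:", x$label, "\n")
  if (!is.null(x$attractors) && nrow(x$attractors)) {
    cat("  attractors:\n")
    print(tibble::as_tibble(x$attractors))
  }
  if (!is.null(x$simulated_survivors)) {
    cat("  simulated survivors:",
        paste(x$simulated_survivors, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Phase-region scan over conjugation rates
#'
#' Classifies the region label on a log-spaced grid of the uncompensated
#' conjugation rate (`gamma_p`, x axis) and the compensated one (`gamma_c`
#' or `gamma_q`, y axis), reproducing the layout of the compensation phase
#' diagrams.
#'
#' @inheritParams classify_region
#' @param gamma_p_range,gamma_cm_range Ranges (dimensionless) for the two
#'   axes.
#' @param n Grid points per axis.
#' @return A tibble of class `pc_region_scan` with columns `gamma_p`,
#'   `gamma_cm`, `label`.
#' @export
phase_region_scan <- function(model, params, gamma_p_range,
                              gamma_cm_range, n = 6, t_end = 1e4) {
  params <- as_dimensionless(params)
  gp <- exp(seq(log(gamma_p_range[1]), log(gamma_p_range[2]),
                length.out = n))
  gcm <- exp(seq(log(gamma_cm_range[1]), log(gamma_cm_range[2]),
                 length.out = n))
  grid <- tidyr::expand_grid(gamma_p = gp, gamma_cm = gcm)
  grid$label <- purrr::map2_chr(grid$gamma_p, grid$gamma_cm,
    function(x, y) {
      pr <- params
      pr$gamma_p <- x
      if (model == "chrcm") pr$gamma_c <- y else pr$gamma_q <- y
      classify_region(model, pr, t_end = t_end)$label
    })
  structure(grid, class = c("pc_region_scan", class(grid)), model = model)
}
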