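test_that("invasion and domination thresholds match their closed forms", {
  expect_equal(gamma_invasion_threshold(0.5, 0.5, 0.04125), 0)
  expect_equal(gamma_domination_threshold(0.5, 0.5, 0.04125), 0)
  expect_equal(gamma_invasion_threshold(0.5, 0.41, 0.04125),
               0.04125 * 0.09 / (0.5 - 0.04125), tolerance = 1e-12)
  expect_equal(gamma_invasion_threshold(0.5, 0.41, 0.04125), 0.0080926,
               tolerance = 1e-4)
  expect_equal(gamma_invasion_threshold(0.54, 0.95 * 0.54, 0.04125),
               0.0022331, tolerance = 1e-4)
  expect_equal(gamma_domination_threshold(0.5, 0.41, 0.04125), 0.0100678,
               tolerance = 1e-4)
  # the dimensional base rate used in the worked examples exceeds it
  expect_gt(9.9e-12, gamma_domination_threshold(0.5, 0.41, 0.04125) / 5.7e9)
  expect_error(gamma_invasion_threshold(0.04, 0.03, 0.05), "washout")
  expect_error(gamma_domination_threshold(0.5, 0.03, 0.05), "washout")
})

test_that("domination threshold dominates invasion threshold", {
  withr::local_seed(3)
  for (i in 1:50) {
    alpha <- runif(1, 0.2, 1)
    mu <- alpha * runif(1, 0.05, 0.5)
    beta <- runif(1, mu + 1e-3, alpha)
    inv <- gamma_invasion_threshold(alpha, beta, mu)
    dom <- gamma_domination_threshold(alpha, beta, mu)
    expect_gte(dom, inv)
  }
  expect_equal(gamma_invasion_threshold(0.5, 0.5, 0.1),
               gamma_domination_threshold(0.5, 0.5, 0.1))
})

test_that("chrCM persistence bound interpolates between alpha and mu", {
  expect_equal(chrcm_persistence_bound(0.54, 0.04125, 0), 0.54)
  expect_equal(chrcm_persistence_bound(0.54, 0.04125, 1e9), 0.04125,
               tolerance = 1e-6)
  expect_equal(chrcm_persistence_bound(0.54, 0.04125, 0.02622),
               0.04125 * (0.02622 + 0.54) / (0.04125 + 0.02622),
               tolerance = 1e-12)
  # equals the domination threshold condition solved for beta_c
  bc <- chrcm_persistence_bound(0.54, 0.04125, 0.02622)
  expect_equal(gamma_domination_threshold(0.54, bc, 0.04125), 0.02622,
               tolerance = 1e-10)
})

test_that("measured conjugation rates exceed domination thresholds by the
           expected folds", {
  fold_chr <- domination_fold_excess(4.6e-12, 0.54, 0.97 * 0.54, 0.04125,
                                     5.7e9)
  fold_pla <- domination_fold_excess(4.6e-12, 0.54, 0.95 * 0.54, 0.04125,
                                     5.7e9)
  expect_gte(fold_chr, 18)
  expect_gte(fold_pla, 10)
  # at the threshold itself the fold is exactly 1
  thr <- gamma_domination_threshold(0.54, 0.5, 0.04125) / 5.7e9
  expect_equal(domination_fold_excess(thr, 0.54, 0.5, 0.04125, 5.7e9), 1,
               tolerance = 1e-12)
})

test_that("fixed points of the basic model have the analytic structure", {
  p <- parameter_set(alpha = 0.5, beta_p = 0.41, mu = 0.04125,
                     gamma_p = 0.5 * gamma_invasion_threshold(0.5, 0.41,
                                                              0.04125),
                     dimensionless = TRUE)
  fps <- find_fixed_points("basic", p)
  expect_true(all(fps$residual < 1e-9))
  free <- dplyr::filter(fps, composition == "plasmid_free_only")
  expect_equal(free$f, 1 - p$mu / p$alpha, tolerance = 1e-9)
  expect_equal(free$stability, "stable_node")
  ext <- dplyr::filter(fps, composition == "extinct")
  expect_equal(ext$stability, "unstable_node")
})

test_that("the bistable chrCM regime contains a separating saddle", {
  fps <- find_fixed_points("chrcm", pink_params())
  expect_true(all(fps$residual < 1e-9))
  stable <- dplyr::filter(fps, stability %in% c("stable_node",
                                                "stable_spiral"))
  expect_true("cm_only" %in% stable$composition)
  expect_gte(nrow(stable), 2)
  expect_true("saddle" %in% fps$stability)
})

test_that("washout of plasmid growth leaves only the plasmid-free state", {
  p <- parameter_set(alpha = 0.5, beta_p = 0.02, mu = 0.04125,
                     gamma_p = 0, dimensionless = TRUE)
  fps <- find_fixed_points("basic", p)
  stable <- dplyr::filter(fps, stability %in% c("stable_node",
                                                "stable_spiral"))
  expect_equal(stable$composition, "plasmid_free_only")
})

test_that("stability labels flip from node to saddle at the invasion
           threshold", {
  alpha <- 0.5; beta <- 0.41; mu <- 0.04125
  thr <- gamma_invasion_threshold(alpha, beta, mu)
  fstar <- c(f = 1 - mu / alpha, p = 0)
  below <- parameter_set(alpha = alpha, beta_p = beta, mu = mu,
                         gamma_p = 0.8 * thr, dimensionless = TRUE)
  above <- parameter_set(alpha = alpha, beta_p = beta, mu = mu,
                         gamma_p = 1.2 * thr, dimensionless = TRUE)
  expect_equal(classify_stability("basic", below, fstar), "stable_node")
  expect_equal(classify_stability("basic", above, fstar), "saddle")
})

test_that("finite-difference Jacobian matches the analytic one", {
  withr::local_seed(5)
  for (i in 1:10) {
    p <- rand_chrcm_params()
    y <- runif(3) / 4
    fun <- function(x) {
      unname(rhs_chrcm(stats::setNames(x, c("f", "p", "c")), p))
    }
    J_fd <- plasmidcomp:::fd_jacobian(fun, y)
    J_an <- plasmidcomp:::model_jacobian("chrcm", p)(y)
    expect_equal(J_fd, unname(J_an), tolerance = 1e-6)
  }
})

test_that("the plaCM interior point at a 100-fold rate trade-off is a
           stable spiral", {
  p <- nondimensionalize(fixture_params("figI"))
  fps <- find_fixed_points("placm", p)
  interior <- dplyr::filter(fps, composition == "interior")
  expect_equal(nrow(interior), 1)
  expect_equal(interior$stability, "stable_spiral")
})

test_that("stable fixed points attract a perturbed start", {
  withr::local_seed(17)
  n_checked <- 0
  for (i in 1:50) {
    p <- rand_basic_params()
    fps <- find_fixed_points("basic", p)
    stable <- dplyr::filter(fps, stability == "stable_node")
    for (j in seq_len(nrow(stable))) {
      x0 <- unlist(stable[j, c("f", "p")])
      dir <- stats::rnorm(2)
      x1 <- pmax(x0 + 1e-4 * dir / sqrt(sum(dir^2)), 0)
      tr <- integrate_continuous("basic", p,
                                 stats::setNames(x1, c("f", "p")),
                                 t_end = 2e4)
      last <- dplyr::slice_tail(tibble::as_tibble(tr), n = 1)
      expect_lt(max(abs(c(last$f, last$p) - x0)), 1e-5)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 50)
})

test_that("basin threshold behaves across regimes", {
  # bistable regime: threshold strictly inside (0.0001, 0.5)
  thr <- basin_threshold_chrcm(pink_params())
  expect_gt(thr, 1e-4)
  expect_lt(thr, 0.5)
  # above the threshold chrCM fixes, below it is lost
  p <- pink_params()
  hi <- canonical_init("chrcm", cm_fraction = min(1, thr * 1.2))
  lo <- canonical_init("chrcm", cm_fraction = thr * 0.8)
  expect_true("c" %in% long_run_outcome("chrcm", p, hi))
  expect_false("c" %in% long_run_outcome("chrcm", p, lo))
  # chrCM conjugation above its domination requirement: fixes from any
  # positive fraction, so no threshold exists
  green <- nondimensionalize(fixture_params("figA"))
  green$gamma_p <- 0.009
  green$gamma_c <- 0.005
  expect_error(basin_threshold_chrcm(green), "any initial fraction")
  # neutral CM (beta_c = beta_p, gamma_c = gamma_p, gamma above domination):
  # the fate of the CM cannot genuinely depend on the initial split, so the
  # search either reports fraction-independence or returns a fraction at
  # the extinction-tolerance floor
  neutral <- nondimensionalize(fixture_params("figA"))
  neutral$beta_c <- neutral$beta_p
  res <- try(basin_threshold_chrcm(neutral), silent = TRUE)
  if (inherits(res, "try-error")) {
    expect_match(attr(res, "condition")$message, "any initial fraction")
  } else {
    expect_lt(res, 1e-3)
  }
})

test_that("region classification reproduces the phase-diagram layout", {
  base <- nondimensionalize(fixture_params("figA"))
  at <- function(model, gp, gcm) {
    pr <- base
    pr$gamma_p <- gp
    if (model == "chrcm") pr$gamma_c <- gcm else pr$gamma_q <- gcm
    classify_region(model, pr)$label
  }
  expect_equal(at("placm", 0.005, 0.01), "wildtype_plasmid_lost")
  expect_equal(at("chrcm", 0.009, 0.005), "cm_fixes_always")
  expect_equal(at("chrcm", 0.005, 0.01), "cm_fixes_above_saddle")
  expect_equal(at("chrcm", 0.009, 0.001), "rps_coexistence")
  expect_equal(at("placm", 0.02622, 0.0002622), "rps_coexistence")
  expect_equal(at("chrcm", 0.0005, 0.0005), "plasmid_free_wins")
  expect_equal(at("placm", 0.0005, 0.0005), "plasmid_free_wins")
  expect_equal(at("chrcm", 0.0082, 0.0002), "mixed_fp_persists")
})

test_that("phase-region scan tabulates labels over a rate grid", {
  base <- nondimensionalize(fixture_params("figA"))
  sc <- phase_region_scan("chrcm", base, c(0.0005, 0.009), c(0.0005, 0.01),
                          n = 2)
  expect_s3_class(sc, "pc_region_scan")
  expect_equal(nrow(sc), 4)
  expect_true(all(c("gamma_p", "gamma_cm", "label") %in% names(sc)))
  expect_true("plasmid_free_wins" %in% sc$label)
})
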