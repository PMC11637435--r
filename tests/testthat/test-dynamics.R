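test_that("a costly non-transmissible plasmid declines monotonically", {
  p <- parameter_set(alpha = 0.5, beta_p = 0.41, mu = 0.04125, gamma_p = 0,
                     dimensionless = TRUE)
  tr <- integrate_continuous("basic", p,
                             state_vector("basic", f = 0.005, p = 0.005),
                             t_end = 2000)
  ratio <- tr$p / tr$f
  expect_true(all(diff(ratio) < 0))
  expect_lt(ratio[length(ratio)], 1e-6)
})

test_that("chrCM sweeps to its logistic balance when conjugation is strong", {
  p <- nondimensionalize(fixture_params("figA"))
  p$gamma_p <- 0.009
  p$gamma_c <- 0.005
  tr <- integrate_continuous("chrcm", p, canonical_init("chrcm"),
                             t_end = 1e4)
  last <- dplyr::slice_tail(tibble::as_tibble(tr), n = 1)
  expect_equal(last$c, 1 - p$mu / p$beta_c, tolerance = 1e-3)
  expect_lt(last$f + last$p, 1e-6)
})

test_that("integration is converged at the default tolerances", {
  p <- nondimensionalize(fixture_params("figG"))
  init <- state_vector("combined", f = 0.005, c = 0.0025, q = 0.0025)
  comp <- model_components("combined")
  end1 <- plasmidcomp:::integrate_raw("combined", p, init,
                                      seq(0, 2000, length.out = 201))
  end2 <- plasmidcomp:::integrate_raw("combined", p, init,
                                      seq(0, 2000, length.out = 201),
                                      rtol = 5e-9, atol = 5e-13)
  expect_lt(max(abs(end1$states[201, ] - end2$states[201, ])), 1e-6)
})

test_that("trajectories remain nonnegative and respect the capacity", {
  p <- nondimensionalize(fixture_params("figI"))
  tr <- integrate_continuous("placm", p, canonical_init("placm"),
                             t_end = 2e4)
  m <- as.matrix(tibble::as_tibble(tr)[model_components("placm")])
  expect_true(all(m >= 0))
  expect_true(all(rowSums(m) <= 1 + 1e-8))
  expect_true(all(diff(tr$time_h) > 0))
})

test_that("identical competitors keep their frequency across transfers", {
  p <- parameter_set(alpha = 0.5, beta_p = 0.45, beta_q = 0.45,
                     mu = 0.04125, gamma_p = 0.01, gamma_q = 0.01,
                     dimensionless = TRUE)
  tr <- run_serial_transfer("placm", p, transfer_protocol(),
                            state_vector("placm", f = 0.005, p = 0.00375,
                                         q = 0.00125))
  ep <- transfer_endpoints(tr)
  expect_equal(nrow(ep), 8)
  freq <- ep$p / (ep$p + ep$q)
  expect_true(all(abs(freq - 0.75) < 8 * 1e-10))
})

test_that("chrCM outcompetes plaCM across serial transfers and batches
           saturate", {
  p <- nondimensionalize(fixture_params("figG"))
  tr <- run_serial_transfer("combined", p, transfer_protocol(),
                            state_vector("combined", f = 0.005, c = 0.0025,
                                         q = 0.0025))
  ep <- transfer_endpoints(tr)
  cm_freq <- ep$c / (ep$c + ep$q)
  expect_true(all(diff(cm_freq) > 0))
  total <- ep$f + ep$p + ep$c + ep$q
  expect_true(all(total > 0.98 & total <= 1))
})

test_that("long-run outcomes bracket the analytic thresholds", {
  p <- parameter_set(alpha = 0.5, beta_p = 0.41, mu = 0.04125,
                     gamma_p = 1.2 * gamma_domination_threshold(0.5, 0.41,
                                                                0.04125),
                     dimensionless = TRUE)
  out <- long_run_outcome("basic", p,
                          state_vector("basic", f = 0.005, p = 0.005),
                          t_end = 1e5)
  expect_setequal(out, "p")
})

test_that("selection against plasmid-free cells eliminates them", {
  p <- nondimensionalize(fixture_params("figA"))
  p$gamma_p <- 0.009 # persistence without domination when eta = 0
  p$eta <- 0.2
  out <- long_run_outcome("basic", p,
                          state_vector("basic", f = 0.005, p = 0.005))
  expect_false("f" %in% out)
  expect_true("p" %in% out)
})

test_that("plasmid growth below turnover washes the bearers out", {
  p <- parameter_set(alpha = 0.5, beta_p = 0.02, beta_c = 0.03,
                     mu = 0.04125, gamma_p = 0, gamma_c = 0,
                     dimensionless = TRUE)
  out <- long_run_outcome("chrcm", p, canonical_init("chrcm"))
  expect_setequal(out, "f")
})

test_that("weaponisation drives chrCM fixation in the worked example", {
  p <- nondimensionalize(fixture_params("figG"))
  init <- state_vector("combined", f = 0.005, c = 0.0025, q = 0.0025)
  w <- weaponisation_contrast(p, init)
  expect_true(w$cm_fixes[["with_conjugation"]])
  expect_false(w$cm_fixes[["without_conjugation"]])
  expect_true(w$differs)
})

test_that("super-compensation fixes chrCM with or without conjugation", {
  p <- nondimensionalize(fixture_params("figG"))
  p$beta_c <- 1.05 * p$alpha
  init <- state_vector("combined", f = 0.005, c = 0.0025, q = 0.0025)
  w <- weaponisation_contrast(p, init, t_end = 2e4)
  expect_true(w$cm_fixes[["with_conjugation"]])
  expect_true(w$cm_fixes[["without_conjugation"]])
  expect_false(w$differs)
})

test_that("the contrast arms are identical when nothing conjugates", {
  p <- nondimensionalize(fixture_params("figG"))
  p$gamma_p <- p$gamma_c <- p$gamma_q <- 0
  init <- state_vector("combined", f = 0.005, c = 0.0025, q = 0.0025)
  w <- weaponisation_contrast(p, init, t_end = 1000)
  t1 <- tibble::as_tibble(w$trajectories[[1]])
  t2 <- tibble::as_tibble(w$trajectories[[2]])
  expect_equal(t1$c, t2$c, tolerance = 1e-12)
  expect_identical(w$outcomes[[1]], w$outcomes[[2]])
})

test_that("the RPS attractor is approached as a decaying winding spiral", {
  p <- nondimensionalize(fixture_params("figI"))
  fps <- find_fixed_points("placm", p)
  interior <- dplyr::filter(fps, composition == "interior")
  star <- unlist(interior[c("f", "p", "q")])
  tr <- integrate_continuous("placm", p, canonical_init("placm"),
                             t_end = 3e4, n_out = 2001)
  m <- as.matrix(tibble::as_tibble(tr)[c("f", "p", "q")])
  dist <- sqrt(rowSums(sweep(m, 2, star)^2))
  # distance to the interior point decays over the tail of the trajectory
  late <- dist[tr$time_h > 1e4]
  expect_lt(late[length(late)], min(dist[tr$time_h < 5e3]))
  # the f component winds around its equilibrium value (many sign changes)
  detrended <- m[tr$time_h > 5e3, "f"] - star[["f"]]
  crossings <- sum(diff(sign(detrended)) != 0)
  expect_gt(crossings, 4)
})

test_that("a serial-transfer protocol records ~50 generations over 8 days", {
  expect_equal(transfer_generations(transfer_protocol()), 8 * log2(100),
               tolerance = 1e-12)
  expect_error(transfer_protocol(dilution = 1), "strictly between")
  expect_error(transfer_protocol(dilution = 0), "strictly between")
})

test_that("the coexistence scan finds the RPS regime only at strong
           trade-offs", {
  p <- fixture_params("figI")
  sc <- rps_scan(p, reductions = c(1, 30))
  expect_false(sc$coexists[sc$reduction == 1])
  expect_true(sc$coexists[sc$reduction == 30])
  expect_equal(min_rps_reduction(sc), 30)
})
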