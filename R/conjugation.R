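#' End-point conjugation-rate estimators
#'
#' `simonsen_gamma()` implements the classic end-point estimate of the
#' mass-action conjugation rate from a single mating culture:
#' \deqn{\gamma = \psi \, \ln(1 + (T/R)(N/D)) / (N_t - N_0), \qquad
#'       \psi = \ln(N_t/N_0)/t,}
#' where D, R, T are donor, recipient and transconjugant densities at the
#' end point, N = D + R + T, and \eqn{\psi} is the bulk Malthusian growth
#' rate. It assumes all populations grow at the same rate.
#'
#' `asm_gamma()` is a growth-rate-corrected extension for assays where
#' donors, recipients and transconjugants grow at different rates
#' \eqn{\psi_D, \psi_R, \psi_T} (e.g. because the plasmid is costly): in
#' the per-population exponential model with mass-action transfer, the
#' transconjugant pool accumulates at effective rate
#' \eqn{\psi_D + \psi_R - \psi_T}, which replaces the bulk rate in the
#' end-point formula:
#' \deqn{\gamma = (\psi_D + \psi_R - \psi_T)\,
#'       \ln(1 + (T/R)(N/D)) / (N_t - N_0).}
#' When the three rates are equal the correction factor equals the bulk
#' rate of any real equal-growth assay and the estimate reduces exactly to
#' `simonsen_gamma()`. Onward transfer from transconjugants is neglected,
#' appropriate for short assay windows (~4 h).
#'
#' Both functions are vectorised and return 0 where `Tt = 0`.
#'
#' @param D0,R0 Initial donor and recipient densities (cells ml^-1).
#' @param Dt,Rt,Tt Final donor, recipient, transconjugant densities.
#' @param t Assay duration (h).
#' @param psi_d,psi_r,psi_t Per-population growth rates (h^-1), required
#'   for `asm_gamma()`.
#' @return Estimated conjugation rate (ml cell^-1 h^-1).
#' @export
#' @examples
#' simonsen_gamma(D0 = 1e7, R0 = 1e7, Dt = 5.9e7, Rt = 8.7e7,
#'                Tt = 1e3, t = 4)
simonsen_gamma <- function(D0, R0, Dt, Rt, Tt, t) {
  if (any(c(D0, R0, Dt, Rt, Tt) < 0)) rlang::abort("densities must be nonnegative")
  if (any(t <= 0)) rlang::abort("`t` must be positive")
  N0 <- D0 + R0
  Nt <- Dt + Rt + Tt
  if (any(Nt <= N0)) {
    rlang::abort("no net growth (N_t <= N_0): the end-point estimator is undefined")
  }
  psi <- log(Nt / N0) / t
  psi * log1p((Tt / Rt) * (Nt / Dt)) / (Nt - N0)
}

#' @rdname simonsen_gamma
#' @export
asm_gamma <- function(D0, R0, Dt, Rt, Tt, t, psi_d = NULL, psi_r = NULL,
                      psi_t = NULL) {
  if (is.null(psi_d) || is.null(psi_r) || is.null(psi_t) ||
      anyNA(c(psi_d, psi_r, psi_t))) {
    rlang::abort(paste0("per-population growth rates psi_d, psi_r, psi_t are ",
                        "required; without them use simonsen_gamma()"))
  }
  if (any(c(D0, R0, Dt, Rt, Tt) < 0)) rlang::abort("densities must be nonnegative")
  if (any(t <= 0)) rlang::abort("`t` must be positive")
  N0 <- D0 + R0
  Nt <- Dt + Rt + Tt
  if (any(Nt <= N0)) {
    rlang::abort("no net growth (N_t <= N_0): the end-point estimator is undefined")
  }
  (psi_d + psi_r - psi_t) * log1p((Tt / Rt) * (Nt / Dt)) / (Nt - N0)
}

#' Estimate conjugation rates for a table of assays
#'
#' Data-frame-first wrapper around [simonsen_gamma()] / [asm_gamma()].
#' Expects columns `D0`, `R0`, `Dt`, `Rt`, `Tt`, `t_h` and, for the
#' growth-corrected method, `psi_d`, `psi_r`, `psi_t`.
#'
#' @param data A data frame of assays, e.g. from [simulate_assay()] or
#'   [read_assays()].
#' @param method `"asm"` (growth-corrected, default) or `"simonsen"`.
#' @return `data` as a tibble with an added `gamma` column
#'   (ml cell^-1 h^-1).
#' @export
estimate_gamma <- function(data, method = c("asm", "simonsen")) {
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  needed <- c("D0", "R0", "Dt", "Rt", "Tt", "t_h")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    rlang::abort(sprintf("missing assay columns: %s",
                         paste(missing, collapse = ", ")))
  }
  data$gamma <- if (method == "simonsen") {
    simonsen_gamma(data$D0, data$R0, data$Dt, data$Rt, data$Tt, data$t_h)
  } else {
    if (!all(c("psi_d", "psi_r", "psi_t") %in% names(data))) {
      rlang::abort(paste0("method \"asm\" needs psi_d, psi_r, psi_t columns; ",
                          "use method = \"simonsen\" without them"))
    }
    asm_gamma(data$D0, data$R0, data$Dt, data$Rt, data$Tt, data$t_h,
              data$psi_d, data$psi_r, data$psi_t)
  }
  data
}

#' Read a conjugation-assay table from CSV
#'
#' Columns: `D0, R0, Dt, Rt, Tt, t_h` with optional trailing
#' `psi_d, psi_r, psi_t`. Lines starting with `#` are comments.
#'
#' @param path CSV path.
#' @return A tibble of assays.
#' @export
read_assays <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Malthusian relative fitness from competition counts
#'
#' Computes r = ln(test_end / test_start) - ln(ref_end / ref_start), the
#' difference in Malthusian parameters of a test and a reference competitor
#' over a competition window. The result is invariant to any common
#' rescaling of all four counts (so flow-cytometry events and cells ml^-1
#' give identical r). If a marker effect (the fitness cost of the
#' fluorescent label, estimated from isogenic control competitions) is
#' supplied it is subtracted via [marker_correct()].
#'
#' @param data A data frame with columns `test_start`, `test_end`,
#'   `ref_start`, `ref_end` (all positive).
#' @param marker_effect Marker fitness effect to subtract (default 0).
#' @return `data` as a tibble with an added `fitness` column.
#' @export
#' @examples
#' relative_fitness(data.frame(test_start = 100, test_end = 1000,
#'                             ref_start = 100, ref_end = 500)) # ln 2
relative_fitness <- function(data, marker_effect = 0) {
  data <- tibble::as_tibble(data)
  needed <- c("test_start", "test_end", "ref_start", "ref_end")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    rlang::abort(sprintf("missing count columns: %s",
                         paste(missing, collapse = ", ")))
  }
  counts <- data[needed]
  if (any(as.matrix(counts) <= 0, na.rm = FALSE) || anyNA(counts)) {
    rlang::abort("all counts must be positive for a computable ratio")
  }
  r <- log(data$test_end / data$test_start) -
    log(data$ref_end / data$ref_start)
  data$fitness <- marker_correct(r, marker_effect)
  data
}

#' Subtract a marker effect from a relative-fitness value
#'
#' @param r Relative fitness (Malthusian difference).
#' @param r_marker Fitness effect of the marker alone.
#' @return `r - r_marker`.
#' @export
marker_correct <- function(r, r_marker) {
  r - r_marker
}
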