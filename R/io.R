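#' Load a simulation run configuration
#'
#' Reads a flat key-value YAML config describing one simulation run.
#' Recognised keys: `model`, `fixture` *or* `params_file` (exactly one),
#' `regime` (`continuous_flow` or `serial_transfer`), `n_transfers`,
#' `dilution`, `hours_per_transfer`, `t_end`, `seed`, `out`, `verbose`.
#' Unknown keys are an error so typos cannot pass silently; all missing
#' required keys are listed in one message.
#'
#' @param path Path to the YAML config.
#' @return A list of class `pc_config` with defaults filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) rlang::abort("config must be a flat key-value document")
  allowed <- c("model", "fixture", "params_file", "regime", "n_transfers",
               "dilution", "hours_per_transfer", "t_end", "seed", "out",
               "verbose")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    rlang::abort(sprintf("unknown config keys: %s",
                         paste(unknown, collapse = ", ")))
  }
  missing <- character()
  if (is.null(raw$model)) missing <- c(missing, "model")
  has_fixture <- !is.null(raw$fixture)
  has_file <- !is.null(raw$params_file)
  if (!has_fixture && !has_file) {
    missing <- c(missing, "fixture or params_file")
  }
  if (length(missing)) {
    rlang::abort(sprintf("missing required config keys: %s",
                         paste(missing, collapse = ", ")))
  }
  if (has_fixture && has_file) {
    rlang::abort("config must name exactly one parameter source: `fixture` or `params_file`, not both")
  }
  model_components(raw$model) # validates the model name
  cfg <- list(
    model = raw$model,
    fixture = raw$fixture,
    params_file = raw$params_file,
    regime = raw$regime %||% "continuous_flow",
    n_transfers = raw$n_transfers %||% 8L,
    dilution = raw$dilution %||% 0.01,
    hours_per_transfer = raw$hours_per_transfer %||% 24,
    t_end = raw$t_end %||% 1e4,
    seed = raw$seed %||% 1L,
    out = raw$out,
    verbose = isTRUE(raw$verbose))
  if (!cfg$regime %in% c("continuous_flow", "serial_transfer")) {
    rlang::abort(sprintf("unknown regime `%s`", cfg$regime))
  }
  if (!(cfg$dilution > 0 && cfg$dilution < 1)) {
    rlang::abort("`dilution` must lie strictly between 0 and 1")
  }
  cfg$params <- if (has_fixture) fixture_params(cfg$fixture)
                else read_params(cfg$params_file)
  structure(cfg, class = "pc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a trajectory as annotated CSV
#'
#' The interchange format is RFC-4180 CSV preceded by `#`-prefixed header
#' comment lines recording the model, regime, parameters and (optionally)
#' the seed, so every file is reproducible from its own header. Densities
#' are written at 12 significant digits, which round-trips losslessly at
#' the solver tolerances used. Components absent from the model variant
#' are written as empty fields.
#'
#' @param trajectory A `pc_trajectory`.
#' @param path Output CSV path.
#' @param seed Optional seed to record in the header.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the reconstructed `pc_trajectory`.
#' @export
write_trajectory <- function(trajectory, path, seed = NULL) {
  stopifnot(inherits(trajectory, "pc_trajectory"))
  model <- attr(trajectory, "model")
  params <- attr(trajectory, "params")
  regime <- attr(trajectory, "regime")
  pkv <- paste(sprintf("%s=%s",
                       setdiff(names(params), "dimensionless"),
                       vapply(params[setdiff(names(params), "dimensionless")],
                              function(v) format(v, digits = 12),
                              character(1))),
               collapse = " ")
  header <- c(sprintf("# model: %s", model),
              sprintf("# regime: %s", regime),
              sprintf("# dimensionless: %s", params$dimensionless),
              sprintf("# params: %s", pkv))
  if (!is.null(seed)) header <- c(header, sprintf("# seed: %d", seed))
  df <- tibble::as_tibble(trajectory)
  all4 <- c("f", "p", "c", "q")
  for (nm in setdiff(all4, names(df))) df[[nm]] <- NA_real_
  if (!"transfer_index" %in% names(df)) df$transfer_index <- NA_integer_
  out <- df[c("time_h", all4, "regime", "transfer_index")]
  num <- function(x) ifelse(is.na(x), "", format(x, digits = 12))
  lines <- c(header,
             paste(colnames(out), collapse = ","),
             do.call(paste, c(lapply(names(out), function(nm) {
               v <- out[[nm]]
               if (is.numeric(v)) num(v) else as.character(v)
             }), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_hdr <- function(key) {
    hit <- grep(sprintf("^# %s: ", key), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(sprintf("^# %s: ", key), "", hit[1])
  }
  model <- get_hdr("model")
  regime <- get_hdr("regime")
  if (is.null(model) || is.null(regime)) {
    rlang::abort("trajectory header is missing `model` or `regime` lines")
  }
  pkv <- get_hdr("params")
  params <- NULL
  if (!is.null(pkv)) {
    kv <- strsplit(strsplit(pkv, " ")[[1]], "=")
    vals <- stats::setNames(
      lapply(kv, function(x) {
        if (identical(x[2], "NA")) NA_real_ else as.numeric(x[2])
      }),
      vapply(kv, `[`, character(1), 1))
    vals$dimensionless <- identical(get_hdr("dimensionless"), "TRUE")
    params <- do.call(parameter_set, vals)
  }
  cols <- strsplit(body[1], ",")[[1]]
  rows <- body[-1]
  if (!length(rows)) {
    df <- tibble::as_tibble(stats::setNames(
      replicate(length(cols), numeric(), simplify = FALSE), cols))
  } else {
    parts <- strsplit(rows, ",", fixed = TRUE)
    # a trailing empty field (absent q or transfer index) is dropped by
    # strsplit; repair before length validation
    short <- which(lengths(parts) == length(cols) - 1)
    for (i in short) parts[[i]] <- c(parts[[i]], "")
    bad <- which(lengths(parts) != length(cols))
    if (length(bad)) {
      rlang::abort(sprintf("malformed row at line %d of %s",
                           length(hdr) + 1 + bad[1], path))
    }
    m <- do.call(rbind, parts)
    df <- tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
    names(df) <- cols
    numeric_cols <- setdiff(cols, "regime")
    for (nm in numeric_cols) {
      v <- df[[nm]]
      v[v == ""] <- NA
      suppressWarnings(vn <- as.numeric(v))
      if (any(is.nan(vn))) {
        rlang::abort(sprintf("NaN density in column `%s`", nm))
      }
      if (any(is.na(vn) & !is.na(v) & v != "NA")) {
        rlang::abort(sprintf("non-numeric value in column `%s`", nm))
      }
      df[[nm]] <- vn
    }
  }
  comp <- model_components(model)
  keep <- c("time_h", comp, "regime", "transfer_index")
  df <- df[intersect(keep, names(df))]
  if (nrow(df) && any(is.nan(as.matrix(df[comp])))) {
    rlang::abort("NaN density in trajectory body")
  }
  df$transfer_index <- as.integer(df$transfer_index)
  new_trajectory(df, model, params, regime)
}
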