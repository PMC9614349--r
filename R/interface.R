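# File-level interface: CSV in, CSV/JSON out. These functions are thin
# wrappers over iht_test() and the study harness for scripted use.

#' Run informative hypothesis tests on a CSV file
#'
#' Reads a delimited data file (first column response, header required; see
#' [read_regression_csv()]) and a plain-text constraint specification (see
#' [read_constraints()]), runs [iht_test()] and optionally writes the tidy
#' result table to `out`. Mixture weights are flattened into a
#' semicolon-separated string column in the written file.
#'
#' @param data_csv Path to the data CSV.
#' @param constraints_spec Path to the constraint file, or an
#'   [iht_constraints] object.
#' @param out Optional output CSV path.
#' @inheritParams iht_test
#' @return The result tibble, invisibly when `out` is given.
#' @export
iht_test_file <- function(data_csv, constraints_spec,
                          statistics = c("fbar", "wald_info", "lrt",
                                         "score_u", "score_nullinfo",
                                         "score_info", "f"),
                          version = "corrected",
                          distribution = "default",
                          out = NULL, seed = NULL) {
  data <- read_regression_csv(data_csv)
  cons <- if (inherits(constraints_spec, "iht_constraints")) constraints_spec
          else read_constraints(constraints_spec)
  if (ncol(cons$R) != data$k) {
    stop("constraint rows have ", ncol(cons$R), " coefficients but the data ",
         "implies k = ", data$k, call. = FALSE)
  }
  res <- iht_test(data, cons, statistics = statistics, version = version,
                  distribution = distribution, seed = seed)
  if (!is.null(out)) {
    flat <- res
    flat$weights <- vapply(res$weights, function(w) {
      if (is.null(w)) "" else paste(format(w, digits = 10), collapse = ";")
    }, character(1))
    readr::write_csv(flat, out)
    return(invisible(res))
  }
  res
}

#' Run a simulation study from a YAML configuration file
#'
#' The configuration keys mirror the arguments of [study_config()]
#' (`n_grid`, `f2_grid`, `reps`, `alpha`, `constraint_id`, `seed`,
#' `design_mode`, plus `mode`: `"type1"`, `"type2"` or both, and an
#' optional `statistics` list of `{statistic, version, distribution}`
#' entries). Writes one long-format CSV per mode, an optional wide table
#' (statistics as columns), and a JSON manifest recording the seed and a
#' hash of the configuration.
#'
#' @param config_path Path to the YAML configuration.
#' @param out_dir Output directory (created if needed).
#' @return Named list of result tibbles, invisibly.
#' @export
run_study_config <- function(config_path, out_dir) {
  raw <- yaml::read_yaml(config_path)
  modes <- raw$mode %||% "type1"
  if (!all(modes %in% c("type1", "type2"))) {
    stop("config field 'mode' must be \"type1\" and/or \"type2\"", call. = FALSE)
  }
  stat_tbl <- if (is.null(raw$statistics)) default_study_statistics() else {
    dplyr::bind_rows(lapply(raw$statistics, tibble::as_tibble))
  }
  args <- raw[intersect(names(raw),
                        c("n_grid", "f2_grid", "reps", "alpha",
                          "constraint_id", "seed", "design_mode", "p", "beta"))]
  cfg <- do.call(study_config, c(args, list(statistics = stat_tbl)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  for (m in modes) {
    res <- if (m == "type1") run_type1_study(cfg) else run_type2_study(cfg)
    readr::write_csv(res, file.path(out_dir, paste0(m, "_long.csv")))
    wide <- tidyr::pivot_wider(
      dplyr::mutate(res, test = paste(.data$statistic, .data$version,
                                      .data$distribution, sep = ".")),
      id_cols = dplyr::any_of(c("n", "f2")),
      names_from = "test", values_from = "rejection_rate"
    )
    readr::write_csv(wide, file.path(out_dir, paste0(m, "_wide.csv")))
    results[[m]] <- res
  }
  manifest <- list(
    seed = cfg$seed,
    config = raw,
    config_hash = rlang::hash(cfg),
    modes = modes,
    reps = cfg$reps,
    created = "see file mtime"     # no wall-clock in outputs: reruns stay identical
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Mixture weights for a covariance kernel stored as CSV
#'
#' Reads a square positive-definite matrix from a headerless CSV file and
#' prints/returns its chi-bar-squared mixture weights.
#'
#' @param path CSV file holding the kernel, no header.
#' @inheritParams chibar_weights
#' @return A [chibar_weights] object.
#' @export
weights_from_csv <- function(path, method = "auto", mc_draws = 1e5,
                             seed = NULL) {
  V <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(V) <- NULL
  if (nrow(V) != ncol(V)) stop("kernel must be square", call. = FALSE)
  chibar_weights(V, method = method, mc_draws = mc_draws, seed = seed)
}
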