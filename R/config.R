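#' Load and validate a model configuration
#'
#' Reads a YAML (or JSON) model configuration and validates it against the
#' schema of the shipped default configuration. All schema violations are
#' collected and reported together.
#'
#' @param path Path to a YAML/JSON configuration file.
#' @return Validated configuration list of class `cua_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}

#' @rdname load_config
#' @export
default_config <- function() {
  load_config(system.file("extdata", "default_config.yaml",
                          package = "migrainecua", mustWork = TRUE))
}

validate_config <- function(cfg) {
  errs <- character()
  need <- function(ok, msg) if (!isTRUE(all(ok))) errs <<- c(errs, msg)

  need(all(c("model", "bands", "initial_distribution", "trials",
             "strategies", "costs") %in% names(cfg)),
       "missing top-level section(s): config needs model, bands, initial_distribution, trials, strategies, costs")

  if (!is.null(cfg$model)) {
    need(isTRUE(cfg$model$cycles >= 1), "model.cycles must be >= 1")
    need(isTRUE(cfg$model$cycle_length_years > 0),
         "model.cycle_length_years must be > 0")
    need(isTRUE(cfg$model$discount_rate_annual >= 0),
         "model.discount_rate_annual must be >= 0")
    need(length(cfg$model$wtp_thresholds) >= 1 &&
           all(cfg$model$wtp_thresholds >= 0),
         "model.wtp_thresholds must be non-negative")
  }
  if (!is.null(cfg$bands)) {
    need(identical(unlist(cfg$bands$labels), band_labels()),
         paste0("bands.labels must be exactly: ",
                paste(band_labels(), collapse = ", ")))
    need(length(cfg$bands$midpoints) == 6,
         "bands.midpoints must have 6 values")
  }
  for (s in names(cfg$strategies)) {
    st <- cfg$strategies[[s]]
    m <- st$transitions$matrix
    need(length(m) == 6 && all(lengths(m) == 6),
         sprintf("strategies.%s.transitions.matrix must be 6x6", s))
    need(isTRUE(st$transitions$orientation %in% c("column", "row")),
         sprintf("strategies.%s.transitions.orientation must be 'column' or 'row'", s))
    for (fld in c("mean", "sd")) {
      if (length(st$utilities[[fld]]) != 6) {
        errs <- c(errs, sprintf(
          "strategies.%s.utilities.%s must have one value per band (%s)",
          s, fld, paste(band_labels()[seq_len(6) >
                                        length(st$utilities[[fld]])],
                        collapse = ", ")))
      }
    }
  }
  need(length(cfg$strategies) == 2, "exactly two strategies are required")
  if (!is.null(cfg$costs)) {
    med <- do.call(rbind, lapply(cfg$costs$medication, as.data.frame))
    need(setequal(med$item,
                  c("cm_acute", "cm_prevention", "em_acute", "em_prevention")),
         "costs.medication must list cm_acute, cm_prevention, em_acute, em_prevention")
    need(isTRUE(cfg$costs$drug$per_dose >= 0), "costs.drug.per_dose must be >= 0")
  }
  if (!is.null(cfg$initial_distribution)) {
    need(isTRUE(cfg$initial_distribution$method %in%
                  c("analytic", "sample", "explicit")),
         "initial_distribution.method must be analytic, sample or explicit")
    if (identical(cfg$initial_distribution$method, "explicit")) {
      w <- unlist(cfg$initial_distribution$weights)
      need(length(w) == 6 && all(w >= 0) && abs(sum(w) - 1) < 1e-6,
           "initial_distribution.weights must be 6 non-negative values summing to 1")
    }
  }
  if (length(errs)) {
    stop("invalid model configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = c("cua_config", "list"))
}

#' Write pipeline outputs to CSV/JSON files
#'
#' Writes whichever result components are present to plain-text files with
#' deterministic column ordering: `trace.csv`, `base_case.csv`,
#' `tornado.csv`, `psa_draws.csv`, `ceac.csv`, `transition_estimates.csv`
#' and `run_metadata.json`.
#'
#' @param results Named list; recognized elements: `solution` (from
#'   [solve_model()]), `tornado` (from [run_owsa()]), `psa` (from
#'   [run_psa()]), `ceac` (from [ceac()]), `transition_estimates` (named
#'   list of [bootstrap_matrix()] results), `metadata` (list).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  paths <- character()
  put <- function(df, file) {
    p <- file.path(out_dir, file)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(results$solution)) {
    sol <- results$solution
    tr <- do.call(rbind, lapply(names(sol$traces), function(s) {
      occ <- sol$traces[[s]]$occupancy
      data.frame(strategy = s, cycle = as.integer(rownames(occ)),
                 occ, check.names = FALSE, row.names = NULL)
    }))
    put(tr, "trace.csv")
    ce <- sol$ce
    bc <- ce$summary
    bc$incremental_cost <- c(ce$incremental_cost, NA)
    bc$incremental_qalys <- c(ce$incremental_qalys, NA)
    bc$icer <- c(ce$icer, NA)
    bc$status <- c(ce$status, NA)
    bc$mmd_change_from_baseline <-
      vapply(bc$strategy, function(s) sol$mmd[[s]]$change_from_baseline,
             numeric(1))
    put(bc, "base_case.csv")
  }
  if (!is.null(results$tornado)) put(results$tornado, "tornado.csv")
  if (!is.null(results$psa)) put(results$psa$draws, "psa_draws.csv")
  if (!is.null(results$ceac)) put(results$ceac, "ceac.csv")
  if (!is.null(results$transition_estimates)) {
    te <- do.call(rbind, lapply(names(results$transition_estimates),
                                function(s) {
      est <- results$transition_estimates[[s]]
      grid <- expand.grid(from = band_labels(), to = band_labels(),
                          stringsAsFactors = FALSE)
      data.frame(strategy = s, grid,
                 mean = as.vector(est$mean), se = as.vector(est$se),
                 row.names = NULL)
    }))
    put(te, "transition_estimates.csv")
  }
  meta <- results$metadata
  if (is.null(meta)) meta <- list()
  meta$package_version <- as.character(utils::packageVersion("migrainecua"))
  meta$r_version <- R.version.string
  p <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Stable digest of a configuration
#'
#' MD5 of the canonical YAML serialization, for run metadata.
#'
#' @param cfg A configuration list.
#' @return Hex digest string.
#' @export
config_digest <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}
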