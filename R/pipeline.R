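#' Run configuration
#'
#' Collects everything one end-to-end analysis needs: the input (paths to
#' roster/scan CSVs, or a synthetic specification), the behaviours and
#' periods to analyse, the significance level, the minimum class size and
#' the random-effect grouping mode.
#'
#' @param roster_path,scan_path CSV inputs (both `NULL` for a synthetic
#'   run).
#' @param synthetic list with optional elements `group_specs`, `params`
#'   ([behaviour_params()]), `n_scans`, `periods`; defaults are the
#'   study-like generator settings with periods `resocialisation` and
#'   `year2` at 500 scans each.
#' @param behaviours subset of `c("proximity", "grooming")`.
#' @param alpha significance level in (0, 1).
#' @param min_class_n minimum deprivation-class size for post-hoc
#'   eligibility.
#' @param random_by `"group"` (random intercept by group identity) or
#'   `"group_size"` (by group size; coincides with identity unless two
#'   groups share a size).
#' @param out_dir output directory (`NULL` for in-memory results only).
#' @param seed integer seed for synthetic input generation.
#' @return A `run_config` object.
#' @export
run_config <- function(roster_path = NULL, scan_path = NULL,
                       synthetic = list(),
                       behaviours = c("proximity", "grooming"),
                       alpha = 0.05, min_class_n = 3,
                       random_by = c("group", "group_size"),
                       out_dir = NULL, seed = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("config validation error: alpha must lie in (0, 1)", call. = FALSE)
  }
  bad <- setdiff(behaviours, c("proximity", "grooming"))
  if (length(bad) > 0) {
    stop("config validation error: unknown behaviour(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  random_by <- match.arg(random_by)
  use_files <- !is.null(roster_path) || !is.null(scan_path)
  if (use_files) {
    for (p in c(roster_path, scan_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("config validation error: input file missing: ",
             if (is.null(p)) "(not given)" else p, call. = FALSE)
      }
    }
  }
  structure(
    list(roster_path = roster_path, scan_path = scan_path,
         synthetic = synthetic, behaviours = behaviours, alpha = alpha,
         min_class_n = min_class_n, random_by = random_by,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  syn <- raw$synthetic
  if (!is.null(syn$params)) {
    syn$params <- behaviour_params(
      sociability = unlist(syn$params$sociability),
      grooming = unlist(syn$params$grooming),
      selectivity = unlist(syn$params$selectivity),
      individual_sd = syn$params$individual_sd %||% 0)
  }
  if (!is.null(syn$group_specs)) {
    syn$group_specs <- lapply(syn$group_specs, function(g)
      tibble::as_tibble(as.data.frame(g)))
  }
  run_config(
    roster_path = raw$roster_path, scan_path = raw$scan_path,
    synthetic = syn %||% list(),
    behaviours = raw$behaviours %||% c("proximity", "grooming"),
    alpha = raw$alpha %||% 0.05,
    min_class_n = raw$min_class_n %||% 3,
    random_by = raw$random_by %||% "group",
    out_dir = raw$out_dir, seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

synthetic_inputs <- function(config) {
  syn <- config$synthetic
  group_specs <- syn$group_specs %||% default_group_specs()
  params <- syn$params %||% default_behaviour_params()
  n_scans <- syn$n_scans %||% 500L
  periods <- syn$periods %||% c("resocialisation", "year2")
  roster <- make_roster(group_specs, seed = config$seed)
  profiles <- draw_profiles(roster, params, seed = config$seed)
  records <- list()
  for (i in seq_along(periods)) {
    # same realized individuals across periods; fresh scan randomness
    sim <- simulate_scans(roster, params, n_scans,
                          seed = config$seed + 1000L * i,
                          period_id = periods[i], profiles = profiles)
    records <- c(records, unname(sim))
  }
  list(roster = roster, records = records, profiles = profiles)
}

#' Run the full analysis pipeline
#'
#' For every behaviour and period: builds the weighted network per group,
#' computes the measure table, fits the full mixed model for each measure
#' (strength centrality; deviation from edge weight disparity on the
#' defined rows only), reduces it by AICc backward selection, and runs the
#' Holm-corrected post-hoc Mann-Whitney comparisons implied by the
#' retained terms. Exclusions (undefined disparity rows, too-small
#' classes) are reported via messages as they occur.
#'
#' @param config a [run_config()].
#' @return A `report_bundle`: list with `roster`, `networks`, `measures`
#'   (the combined measure table), `models` (per behaviour-period-measure:
#'   full fit, selection ledger, best fit), `posthocs` (combined
#'   [posthoc_pairwise()] table) and `manifest`. If `config$out_dir` is
#'   set, all tables, networks and the manifest are also written there.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$roster_path)) {
    roster <- read_roster(config$roster_path)
    records <- read_scan_table(config$scan_path, roster)
  } else {
    inputs <- synthetic_inputs(config)
    roster <- inputs$roster
    records <- inputs$records
  }
  for (r in records) {
    rep <- validate_records(r, roster)
    if (rep$n_violations > 0) {
      stop("stage [validate]: scan records for group ", r$group_id,
           ", period ", r$period_id, " carry ", rep$n_violations,
           " violation(s)", call. = FALSE)
    }
  }
  networks <- list()
  for (r in records) {
    key <- paste(r$group_id, r$period_id, sep = ":")
    if ("proximity" %in% config$behaviours) {
      networks[[paste0("proximity:", key)]] <-
        build_proximity_network(r, roster)
    }
    if ("grooming" %in% config$behaviours) {
      networks[[paste0("grooming:", key)]] <-
        build_grooming_network(r, roster)
    }
  }
  measures <- metrics_table(networks, roster)
  if (config$random_by == "group_size") {
    measures$random_group <- paste0("size", measures$n_group)
  } else {
    measures$random_group <- measures$group_id
  }
  periods <- unique(measures$period_id)
  models <- list()
  posthocs <- list()
  for (beh in config$behaviours) {
    for (per in periods) {
      sub <- measures[measures$behaviour == beh &
                        measures$period_id == per, ]
      for (meas in c("strength_centrality", "dy2")) {
        dat <- sub
        if (meas == "dy2") {
          n_undef <- sum(!dat$defined)
          if (n_undef > 0) {
            drops <- table(dat$deprivation_class[!dat$defined])
            message(sprintf(
              "[%s %s] %d individual(s) undefined for disparity (no %s) — excluded: %s",
              beh, per, n_undef, beh,
              paste(names(drops), drops, sep = " x ", collapse = ", ")))
          }
          dat <- dat[dat$defined, ]
        }
        key <- paste(beh, per, meas, sep = ":")
        spec <- model_spec(meas, random = "random_group")
        sel <- tryCatch(
          backward_select(dat, spec),
          error = function(e) {
            stop("stage [model ", key, "]: ", conditionMessage(e),
                 call. = FALSE)
          })
        models[[key]] <- list(
          full = fit_lmm(dat, spec), selection = sel$ledger,
          best = sel$best, best_reml = sel$best_reml)
        posthocs[[key]] <- posthoc_pairwise(
          dat, measure = meas, behaviour = beh, period = per,
          retained_terms = sel$best$spec$fixed_terms,
          alpha = config$alpha, min_class_n = config$min_class_n)
      }
    }
  }
  posthocs <- dplyr::bind_rows(posthocs)
  manifest <- list(
    package = "scansoc",
    version = as.character(utils::packageVersion("scansoc")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    behaviours = config$behaviours, alpha = config$alpha,
    min_class_n = config$min_class_n, random_by = config$random_by,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  bundle <- structure(
    list(config = config, roster = roster, networks = networks,
         measures = measures, models = models, posthocs = posthocs,
         manifest = manifest),
    class = "report_bundle")
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat("  groups:", paste(group_ids(x$roster), collapse = ", "), "\n")
  cat("  networks:", length(x$networks), " measure rows:",
      nrow(x$measures), "\n")
  for (key in names(x$models)) {
    best <- x$models[[key]]$best
    cat(sprintf("  %s: best model ~ %s (AICc %.2f)\n", key,
                format_terms(best$spec$fixed_terms), best$aicc))
  }
  nsig <- sum(x$posthocs$significant)
  cat("  posthoc comparisons:", nrow(x$posthocs), "(", nsig,
      "significant )\n")
  invisible(x)
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_roster(bundle$roster, file.path(out_dir, "roster.csv"))
  write_measure_table(bundle$measures, file.path(out_dir, "measures.csv"))
  utils::write.csv(as.data.frame(bundle$posthocs),
                   file.path(out_dir, "posthoc.csv"), row.names = FALSE)
  for (key in names(bundle$networks)) {
    fname <- paste0("network_", gsub(":", "_", key), ".graphml")
    export_network(bundle$networks[[key]], file.path(out_dir, fname),
                   format = "graphml")
  }
  model_rows <- lapply(names(bundle$models), function(key) {
    m <- bundle$models[[key]]
    tb <- m$best$terms
    tb$analysis <- key
    tb$retained <- TRUE
    full_only <- m$full$terms[!m$full$terms$term %in% tb$term, ]
    if (nrow(full_only) > 0) {
      full_only$analysis <- key
      full_only$retained <- FALSE
    }
    dplyr::bind_rows(tb, full_only)
  })
  utils::write.csv(as.data.frame(dplyr::bind_rows(model_rows)),
                   file.path(out_dir, "model_terms.csv"), row.names = FALSE)
  ledger_rows <- lapply(names(bundle$models), function(key) {
    lg <- bundle$models[[key]]$selection
    lg$analysis <- key
    lg
  })
  utils::write.csv(as.data.frame(dplyr::bind_rows(ledger_rows)),
                   file.path(out_dir, "selection_ledger.csv"),
                   row.names = FALSE)
  yaml::write_yaml(bundle$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
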