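#' End-to-end clock building and compound screening runs
#'
#' `run_build_clock()` composes the clock-building workflow from a run
#' configuration: read beta matrix and sample sheet, apply the probe filters
#' (detection p-value gate, blocklist, completeness), optionally select the
#' screening threshold by leave-one-out validation, screen DMPs, fit the
#' elastic-net clock, and evaluate on a held-out test set when one is
#' configured. All outputs — `clock.json`, `screened_dmps.tsv`,
#' `predictions.tsv`, `metrics.json`, `report.txt` and the fully resolved
#' `config.yaml` — are written to the run's output directory, so every run is
#' reproducible from the resolved config alone.
#'
#' Config fields (paths are file paths; unset optional stages are skipped):
#' `beta`, `sheet` (required); `detp`, `detp_cutoff` (default 0.01),
#' `detp_rule`, `blocklist`; `threshold` (default 1e-11) or `threshold_grid`
#' (triggers leave-one-out selection); `alpha` (0.5), `n_folds` (10),
#' `lambda_rule` ("min"), `seed` (1); `test_beta`, `test_sheet`; `out_dir`
#' (required).
#'
#' @param config a named list, or path to a YAML file of one.
#' @return `run_build_clock()` returns (invisibly) a list with `model`,
#'   `dmps`, `metrics` (NULL without a test set) and `report` (character
#'   vector of report lines).
#' @export
run_build_clock <- function(config) {
  cfg <- resolve_config(config, defaults = list(
    detp_cutoff = 0.01, detp_rule = "any-sample", threshold = 1e-11,
    threshold_grid = NULL, alpha = 0.5, n_folds = 10, lambda_rule = "min",
    seed = 1), required = c("beta", "sheet", "out_dir"))
  check_inputs(cfg, c("beta", "sheet", "detp", "blocklist",
                      "test_beta", "test_sheet"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  rep_ <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    message(line)
    rep_ <<- c(rep_, line)
  }

  beta <- read_beta_matrix(cfg$beta)
  sheet <- read_sample_sheet(cfg$sheet)
  say("input: %d probes x %d samples", nrow(beta), ncol(beta))
  if (!is.null(cfg$detp)) {
    detp <- as.matrix(utils::read.delim(cfg$detp, row.names = 1,
                                        check.names = FALSE))
    n0 <- nrow(beta)
    beta <- filter_by_detection(beta, detp, cutoff = cfg$detp_cutoff,
                                rule = cfg$detp_rule)
    say("detection filter: %d -> %d probes", n0, nrow(beta))
  }
  if (!is.null(cfg$blocklist)) {
    n0 <- nrow(beta)
    beta <- suppressMessages(remove_blocklist(beta,
                                              read_blocklist(cfg$blocklist)))
    say("blocklist: %d -> %d probes", n0, nrow(beta))
  }
  n0 <- nrow(beta)
  beta <- suppressMessages(drop_incomplete_probes(beta))
  if (nrow(beta) < n0) say("completeness: %d -> %d probes", n0, nrow(beta))

  tau <- cfg$threshold
  if (!is.null(cfg$threshold_grid)) {
    sel <- select_threshold_loo(beta, sheet, grid = cfg$threshold_grid,
                                alpha = cfg$alpha, lambda_rule = cfg$lambda_rule,
                                seed = cfg$seed)
    tau <- sel$threshold
    say("leave-one-out threshold selection: tau = %g", tau)
  }
  dmps <- suppressMessages(screen_dmps(beta, sheet, threshold = tau))
  say("screen at tau = %g: %d DMPs (%d hypo, %d hyper)", tau, nrow(dmps),
      sum(dmps$direction == "hypo"), sum(dmps$direction == "hyper"))
  if (nrow(dmps) == 0) stop("screening selected no CpGs", call. = FALSE)
  utils::write.table(dmps, file.path(cfg$out_dir, "screened_dmps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  model <- fit_clock(beta[dmps$probe_id, , drop = FALSE], sheet,
                     alpha = cfg$alpha, n_folds = cfg$n_folds,
                     lambda_rule = cfg$lambda_rule, seed = cfg$seed,
                     threshold = tau)
  say("clock: %d CpGs selected at lambda = %g", length(model$weights),
      model$training_meta$lambda)
  write_clock_model(model, file.path(cfg$out_dir, "clock.json"))

  metrics <- NULL
  if (!is.null(cfg$test_beta) && !is.null(cfg$test_sheet)) {
    tb <- read_beta_matrix(cfg$test_beta)
    ts <- read_sample_sheet(cfg$test_sheet)
    pred <- predict_passage(model, tb, ts)
    metrics <- evaluate_predictions(pred)
    say("test set: RMSE %.4f, Spearman rho %.4f (n = %d)",
        metrics$rmse, metrics$spearman_rho, metrics$n)
    utils::write.table(pred, file.path(cfg$out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(metrics[c("rmse", "spearman_rho", "spearman_p", "n")],
                         file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  writeLines(rep_, file.path(cfg$out_dir, "report.txt"))
  cfg$passclock_version <- as.character(utils::packageVersion("passclock"))
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config.yaml"))
  invisible(list(model = model, dmps = dmps, metrics = metrics,
                 report = rep_))
}

#' @rdname run_build_clock
#' @details `run_screen_compound()` scores treated and control cohorts with a
#' trained clock, computes the deceleration readout by passage (and by
#' cumulative population doublings when the sheet carries them), scores an
#' optional marker panel (CSV with columns `marker,polarity,cohort,value`) by
#' robust Z against the control cohort, and writes a per-compound verdict:
#' "decelerated" when the overall effect is below -2 standard errors,
#' "accelerated" above +2, otherwise "no effect".
#' Additional config fields: `clock`, `treatment`, `control`, `panel`,
#' `z_cutoff` (0.5).
#' @return `run_screen_compound()` returns (invisibly) a list with
#'   `comparison` (a `cohort_comparison`), `comparison_cpd` (or NULL),
#'   `marker_calls` (or NULL), `verdict` and `report`.
#' @export
run_screen_compound <- function(config) {
  cfg <- resolve_config(config, defaults = list(z_cutoff = 0.5),
                        required = c("clock", "beta", "sheet", "treatment",
                                     "control", "out_dir"))
  check_inputs(cfg, c("clock", "beta", "sheet", "panel"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  rep_ <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    message(line)
    rep_ <<- c(rep_, line)
  }

  model <- read_clock_model(cfg$clock)
  beta <- read_beta_matrix(cfg$beta)
  sheet <- read_sample_sheet(cfg$sheet)
  for (lab in c(cfg$treatment, cfg$control))
    if (!lab %in% sheet$treatment)
      stop("cohort label not in sample sheet: ", lab, call. = FALSE)

  pred <- predict_passage(model, beta, sheet)
  utils::write.table(pred, file.path(cfg$out_dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cmp <- compute_acceleration(pred, sheet, cfg$treatment, cfg$control,
                              x_axis = "passage")
  utils::write.table(cmp$table, file.path(cfg$out_dir, "effect_passage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cmp_cpd <- NULL
  if ("cumulative_pd" %in% names(sheet) && !anyNA(sheet$cumulative_pd)) {
    cmp_cpd <- compute_acceleration(pred, sheet, cfg$treatment, cfg$control,
                                    x_axis = "cumulative_pd")
    utils::write.table(cmp_cpd$table,
                       file.path(cfg$out_dir, "effect_cumulative_pd.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  verdict <- if (!is.na(cmp$overall_se) &&
                 cmp$overall_effect < -2 * cmp$overall_se) "decelerated"
             else if (!is.na(cmp$overall_se) &&
                      cmp$overall_effect > 2 * cmp$overall_se) "accelerated"
             else "no effect"
  say("%s vs %s: overall effect %.4f (SE %.4f) -> %s", cfg$treatment,
      cfg$control, cmp$overall_effect, cmp$overall_se, verdict)

  calls <- NULL
  if (!is.null(cfg$panel)) {
    panel <- utils::read.csv(cfg$panel, stringsAsFactors = FALSE)
    calls <- score_marker_panel(panel, control_label = cfg$control,
                                cutoff = cfg$z_cutoff)
    utils::write.csv(calls, file.path(cfg$out_dir, "marker_calls.csv"),
                     row.names = FALSE)
    say("marker panel: %d senescent, %d proliferative, %d no-change call(s)",
        sum(calls$call == "senescent"), sum(calls$call == "proliferative"),
        sum(calls$call == "no-change"))
  }
  writeLines(rep_, file.path(cfg$out_dir, "report.txt"))
  cfg$passclock_version <- as.character(utils::packageVersion("passclock"))
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config.yaml"))
  invisible(list(comparison = cmp, comparison_cpd = cmp_cpd,
                 marker_calls = calls, verdict = verdict, report = rep_))
}

#' Score a marker panel table by robust Z
#'
#' @param panel data.frame with columns `marker`, `polarity`, `cohort`,
#'   `value`; rows with `cohort == control_label` are the vehicle control of
#'   their marker.
#' @param control_label cohort label of the vehicle control.
#' @param cutoff call cutoff passed to [classify_marker()].
#' @return data.frame of robust-Z calls for every non-control row.
#' @export
score_marker_panel <- function(panel, control_label, cutoff = 0.5) {
  need <- c("marker", "polarity", "cohort", "value")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0)
    stop("panel lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (mk in unique(panel$marker)) {
    sub <- panel[panel$marker == mk, ]
    ctrl <- sub$value[sub$cohort == control_label]
    pol <- sub$polarity[1]
    for (co in setdiff(unique(sub$cohort), control_label)) {
      z <- robust_z(ctrl, sub$value[sub$cohort == co], marker = mk,
                    polarity = pol, cutoff = cutoff)
      z$cohort <- co
      out[[paste(mk, co)]] <- z
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# merge defaults, check required fields; accepts a YAML path or a list
resolve_config <- function(config, defaults, required) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  miss <- setdiff(required, names(config))
  if (length(miss) > 0)
    stop("config lacks required field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  config
}

# fail fast on missing input files, before any computation
check_inputs <- function(cfg, fields) {
  for (f in intersect(fields, names(cfg))) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("config field '%s' points at a missing file: %s", f, p),
           call. = FALSE)
  }
}
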