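#' Configure a synthetic serially-passaged methylome cohort
#'
#' Builds the configuration for [simulate_cohort()]: a methylome in which most
#' CpGs sit on a static bimodal background (modes near beta 0.1 and 0.9,
#' mirroring the unmethylated/methylated peaks of array data) while a small
#' set of "drifting" CpGs moves linearly with passage — hypomethylating or
#' hypermethylating at about `drift_total` total delta-beta over ten passages
#' (slopes jittered +/- 20%). Observations are beta-distributed around the
#' mean trajectory with precision `kappa` (`beta ~ Beta(mu * kappa,
#' (1 - mu) * kappa)`), which keeps values in (0, 1) without clipping
#' artefacts. Treatment cohorts age on a compressed "effective passage" scale
#' (see [effective_passage()]); immortalised cohorts keep only a fraction of
#' the drift slope beyond the immortalisation passage.
#'
#' @param n_probes total CpG count (default 10000).
#' @param n_hypo,n_hyper counts of hypo- and hypermethylating drifters
#'   (defaults 23 and 19, the split observed among clock CpGs on real
#'   fibroblast series).
#' @param n_extra additional drifters, split evenly between directions
#'   (default 0).
#' @param drift_total mean |delta beta| between passage 10 and passage 20 for
#'   drifting CpGs (default 0.2).
#' @param kappa precision of the beta observation noise (default 200, i.e.
#'   SD ~ 0.035 at beta = 0.5, comparable to array replicate noise).
#' @param passages passages available to cohort schedules (default 9:20).
#' @param cohorts list of [sim_cohort()] entries. The default is the standard
#'   two-cohort design: a 39-sample training cohort (6 samples at each of
#'   P10/12/14, 7 at each of P16/18/20) and a 26-sample test cohort spread
#'   over P9-P20.
#' @param clip bounds for mean trajectories (default c(0.01, 0.99)).
#' @param pd_per_passage population doublings credited per passage when
#'   filling the `cumulative_pd` column (default 2).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return a list of class `sim_config`.
#' @export
simulate_config <- function(n_probes = 10000, n_hypo = 23, n_hyper = 19,
                            n_extra = 0, drift_total = 0.2, kappa = 200,
                            passages = 9:20, cohorts = NULL,
                            clip = c(0.01, 0.99), pd_per_passage = 2,
                            seed = 1) {
  if (is.null(cohorts)) {
    cohorts <- list(
      sim_cohort("train", schedule = c("10" = 6, "12" = 6, "14" = 6,
                                       "16" = 7, "18" = 7, "20" = 7)),
      sim_cohort("test", schedule = c("9" = 1, "10" = 2, "11" = 2, "12" = 1,
                                      "13" = 2, "14" = 2, "15" = 2,
                                      "16" = 6, "18" = 4, "20" = 4)))
  }
  stopifnot(n_probes >= n_hypo + n_hyper + n_extra, drift_total >= 0,
            kappa > 0, length(clip) == 2, clip[1] < clip[2])
  structure(list(n_probes = n_probes, n_hypo = n_hypo, n_hyper = n_hyper,
                 n_extra = n_extra, drift_total = drift_total, kappa = kappa,
                 passages = as.integer(passages), cohorts = cohorts,
                 clip = clip, pd_per_passage = pd_per_passage,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname simulate_config
#' @param label cohort label (also used as the `cohort` column).
#' @param schedule named integer vector: names are passages, values sample
#'   counts.
#' @param deceleration treatment deceleration d in \[0, 1\]: from `onset`
#'   onward the cohort ages at rate (1 - d) on the effective-passage scale.
#' @param onset first decelerated passage.
#' @param immortalisation passage after which drift slows to `residual_drift`
#'   times its rate (NA = not immortalised).
#' @param residual_drift fraction of the drift slope retained beyond the
#'   immortalisation passage.
#' @param treatment treatment label written to the sample sheet (defaults to
#'   "vehicle" when no deceleration, otherwise the cohort label).
#' @export
sim_cohort <- function(label, schedule, deceleration = 0, onset = 9,
                       immortalisation = NA_real_, residual_drift = 1,
                       treatment = NULL) {
  stopifnot(deceleration >= 0, deceleration <= 1,
            residual_drift >= 0, residual_drift <= 1)
  if (is.null(treatment))
    treatment <- if (deceleration == 0 && (is.na(immortalisation) ||
                                           residual_drift == 1))
      "vehicle" else label
  list(label = label,
       schedule = stats::setNames(as.integer(schedule), names(schedule)),
       deceleration = deceleration, onset = onset,
       immortalisation = immortalisation, residual_drift = residual_drift,
       treatment = treatment)
}

#' Effective passage under treatment deceleration
#'
#' A decelerating treatment compresses the ageing axis: from the onset
#' passage p0 onward, the cohort's methylome behaves as if at passage
#' `p0 + (p - p0) * (1 - d)` instead of p. d = 0 is untreated ageing, d = 1
#' freezes the methylome at the onset passage.
#'
#' @param p passage (vectorised).
#' @param deceleration d in \[0, 1\].
#' @param onset onset passage p0.
#' @return effective passage, same length as `p`.
#' @export
effective_passage <- function(p, deceleration, onset) {
  ifelse(p >= onset, onset + (p - onset) * (1 - deceleration), p)
}

#' Generate a synthetic passaged-methylome cohort
#'
#' Draws the beta matrix, sample sheet and ground-truth table defined by a
#' [simulate_config()]. The truth table records which probes drift, their
#' slopes and directions, and each cohort's deceleration parameters — the
#' recovery target for screening and clock tests.
#'
#' @param config a `sim_config`.
#' @return list with `beta` (beta matrix), `sheet` (sample sheet with
#'   `cohort`, `treatment` and `cumulative_pd` columns) and `truth` (list:
#'   `probes` data.frame, `cohorts` data.frame, `seed`).
#' @examples
#' sim <- simulate_cohort(simulate_config(n_probes = 200, seed = 42))
#' dim(sim$beta)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  np <- config$n_probes
  probe_ids <- sprintf("cg%08d", seq_len(np))

  n_ext_hypo <- ceiling(config$n_extra / 2)
  n_ext_hyper <- config$n_extra - n_ext_hypo
  n_hypo <- config$n_hypo + n_ext_hypo
  n_hyper <- config$n_hyper + n_ext_hyper
  n_drift <- n_hypo + n_hyper

  # background: bimodal static baselines. Drifting CpGs start where ageing
  # CpGs start on arrays: hypomethylating probes begin methylated (high
  # beta), hypermethylating probes begin unmethylated, each with headroom
  # for the full directed drift without hitting the clip bounds.
  hi <- stats::runif(np) < 0.5
  baseline <- ifelse(hi, stats::rbeta(np, 45, 5), stats::rbeta(np, 5, 45))
  drift_idx <- sort(sample.int(np, n_drift))
  dir_ <- sample(rep(c(-1, 1), c(n_hypo, n_hyper)))
  baseline[drift_idx] <- ifelse(dir_ < 0,
                                stats::runif(n_drift, 0.80, 0.95),
                                stats::runif(n_drift, 0.05, 0.20))

  base_slope <- config$drift_total / 10
  jitter <- stats::runif(n_drift, -0.2, 0.2)
  slope <- numeric(np)
  slope[drift_idx] <- dir_ * base_slope * (1 + jitter)

  mu_at <- function(p_eff) {
    pmin(pmax(baseline + slope * (p_eff - 10), config$clip[1]),
         config$clip[2])
  }

  cols <- list(); sheet_rows <- list(); pinned <- 0L; cells <- 0L
  for (co in config$cohorts) {
    ps <- as.integer(names(co$schedule))
    for (k in seq_along(ps)) {
      p <- ps[k]
      pe <- effective_passage(p, co$deceleration, co$onset)
      if (!is.na(co$immortalisation) && pe > co$immortalisation)
        pe <- co$immortalisation +
          co$residual_drift * (pe - co$immortalisation)
      mu <- mu_at(pe)
      pinned <- pinned + sum(mu[drift_idx] %in% config$clip)
      cells <- cells + n_drift
      for (i in seq_len(co$schedule[k])) {
        sid <- sprintf("%s_P%02d_%02d", co$label, p, i)
        cols[[sid]] <- stats::rbeta(np, mu * config$kappa,
                                    (1 - mu) * config$kappa)
        sheet_rows[[sid]] <- data.frame(
          sample_id = sid, passage = p, cell_type = "HMF", donor_id = "D1",
          treatment = co$treatment, dose = NA_character_,
          cumulative_pd = (p - min(config$passages)) * config$pd_per_passage,
          cohort = co$label, stringsAsFactors = FALSE)
      }
    }
  }
  if (cells > 0 && pinned / cells > 0.1)
    warning(sprintf(
      "drift_total %g pins %.0f%% of drifting-CpG means at the clip bounds",
      config$drift_total, 100 * pinned / cells), call. = FALSE)

  beta <- do.call(cbind, cols)
  rownames(beta) <- probe_ids
  sheet <- do.call(rbind, c(sheet_rows, make.row.names = FALSE))
  truth <- list(
    probes = data.frame(
      probe_id = probe_ids[drift_idx],
      slope = slope[drift_idx],
      direction = ifelse(slope[drift_idx] < 0, "hypo", "hyper"),
      baseline = baseline[drift_idx],
      stringsAsFactors = FALSE),
    cohorts = do.call(rbind, lapply(config$cohorts, function(co)
      data.frame(label = co$label, treatment = co$treatment,
                 deceleration = co$deceleration, onset = co$onset,
                 immortalisation = co$immortalisation,
                 residual_drift = co$residual_drift,
                 stringsAsFactors = FALSE))),
    seed = config$seed)
  list(beta = as_beta_matrix(beta), sheet = as_sample_sheet(sheet),
       truth = truth)
}

#' @rdname simulate_cohort
#' @param immortalisation passage after which drift slows.
#' @param residual_drift retained fraction of the drift slope (r = 1
#'   reproduces an untreated cohort, r = 0 freezes drift at the
#'   immortalisation passage).
#' @param schedule passage schedule for the immortalised cohort (default: the
#'   training schedule).
#' @return `simulate_immortalised()` returns the same structure as
#'   `simulate_cohort()`, for a single immortalised cohort labelled "immort".
#' @export
simulate_immortalised <- function(config, immortalisation = 12,
                                  residual_drift = 0.4, schedule = NULL) {
  if (is.null(schedule))
    schedule <- c("10" = 6, "12" = 6, "14" = 6, "16" = 7, "18" = 7, "20" = 7)
  cfg <- config
  cfg$cohorts <- list(sim_cohort("immort", schedule = schedule,
                                 immortalisation = immortalisation,
                                 residual_drift = residual_drift,
                                 treatment = "immort"))
  simulate_cohort(cfg)
}
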