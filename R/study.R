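#' Configuration for a full simulated suppression/recovery study
#'
#' Bundles the behavioral phases (first suppression day, recovered phase,
#' bilateral-suppression day), the paired before/after imaging sessions and
#' the analysis parameters under one master seed. Phase trial counts default
#' to the session sizes of the study design the generator emulates (about
#' 320 trials on the first suppression day, 370 after recovery, 145 on the
#' bilateral day, 30% suppression probability on first/bilateral days and
#' 50% otherwise).
#'
#' @param seed master seed; every substream is derived from it.
#' @param n_trials_per_phase named integer vector with entries `first_day`,
#'   `recovered`, `bilateral`.
#' @param n_neurons number of simulated imaged neurons.
#' @param n_trials_imaging trials per imaging session (suppression-free).
#' @param frac_movement,frac_contra,frac_ipsi population composition, see
#'   [neuron_population()].
#' @param response_amplitude,noise_sd transient amplitude and per-frame noise
#'   s.d. (dF/F units).
#' @param p_contra_to_none,p_none_to_ipsi plasticity transition
#'   probabilities, see [apply_plasticity()]; set both to 0 for a no-plasticity
#'   control study.
#' @param alpha significance level for all per-neuron tests.
#' @param min_trials minimum trials per condition for classification.
#' @param hemisphere hemisphere under study.
#' @return Object of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         n_trials_per_phase = c(first_day = 320,
                                                recovered = 370,
                                                bilateral = 145),
                         n_neurons = 415,
                         n_trials_imaging = 75,
                         frac_movement = 0.47,
                         frac_contra = 0.245,
                         frac_ipsi = 0.075,
                         response_amplitude = 0.5,
                         noise_sd = response_amplitude / 3,
                         p_contra_to_none = 0.5,
                         p_none_to_ipsi = 0.15,
                         alpha = 0.05,
                         min_trials = 5L,
                         hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(all(c("first_day", "recovered", "bilateral") %in%
                  names(n_trials_per_phase)))
  structure(list(
    seed = as.integer(seed), n_trials_per_phase = n_trials_per_phase,
    n_neurons = n_neurons, n_trials_imaging = n_trials_imaging,
    frac_movement = frac_movement, frac_contra = frac_contra,
    frac_ipsi = frac_ipsi, response_amplitude = response_amplitude,
    noise_sd = noise_sd, p_contra_to_none = p_contra_to_none,
    p_none_to_ipsi = p_none_to_ipsi, alpha = alpha,
    min_trials = as.integer(min_trials), hemisphere = hemisphere),
    class = "study_config")
}

# simulate one suppression-free imaging session and return the per-trial
# activity table for the given neuron specs
simulate_imaging_session <- function(cfg, specs, tag) {
  sim <- sim_config(n_trials = cfg$n_trials_imaging, regime = "control",
                    p_suppression_trial = 0,
                    seed = substream_seed(cfg$seed, paste0("imaging_", tag)),
                    hemisphere = cfg$hemisphere)
  session <- simulate_behavior(sim)
  fluor <- simulate_calcium(session$schedule, specs,
                            hemisphere = cfg$hemisphere,
                            seed = substream_seed(cfg$seed,
                                                  paste0("noise_", tag)))
  trial_activity(fluor, session$schedule, hemisphere = cfg$hemisphere)
}

# long activity table -> named list of neuron_response objects
responses_by_neuron <- function(activity, session_tag) {
  lapply(split(seq_len(nrow(activity)), activity$neuron_id), function(ii) {
    sub <- activity[ii, ]
    neuron_response(sub$R[sub$condition == "contraversive"],
                    sub$R[sub$condition == "ipsiversive"],
                    neuron_id = sub$neuron_id[1], session_tag = session_tag)
  })
}

#' Run a complete simulated suppression/recovery study
#'
#' Executes every stage deterministically from the master seed: simulates and
#' scores the three behavioral phases, computes per-phase summaries and
#' suppressed-vs-unsuppressed contrasts plus the first-vs-recovered cross
#' contrast, simulates the paired before/after imaging sessions with the
#' configured plasticity transitions, classifies every neuron, and derives
#' the population statistics (movement-related and selective fractions,
#' skew of the difference in dF/F increase, shared-denominator delta-SI
#' tests).
#'
#' @param config a [study_config()].
#' @return Object of class `study_report`: list with `behavior` (per-phase
#'   trial tables, summaries and contrasts), `cross_phase`, `neurons`
#'   (paired per-neuron table), `classification_before`, `population`
#'   (population statistics) and `provenance`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  phases <- c("first_day", "recovered", "bilateral")
  behavior <- list()
  for (ph in phases) {
    sim <- sim_config(n_trials = config$n_trials_per_phase[[ph]],
                      regime = ph,
                      seed = substream_seed(config$seed, paste0("beh_", ph)),
                      hemisphere = config$hemisphere)
    session <- simulate_behavior(sim)
    trials <- score_trials(session$eye_trace, session$schedule,
                           hemisphere = config$hemisphere)
    behavior[[ph]] <- list(trials = trials,
                           summary = behavior_summary(trials),
                           contrast = suppression_contrast(trials))
  }
  rt_first <- with(behavior$first_day$trials,
                   reaction_time_s[suppressed & outcome == "correct"])
  rt_recov <- with(behavior$recovered$trials,
                   reaction_time_s[suppressed & outcome == "correct"])
  b1 <- sum(rt_first < 1)
  b2 <- sum(rt_recov < 1)
  n1 <- sum(behavior$first_day$trials$suppressed)
  n2 <- sum(behavior$recovered$trials$suppressed)
  cross <- list(
    chi2_lt1s = pearson_chi2_2x2(b1, n1 - b1, b2, n2 - b2),
    mannwhitney = compare_rt_distributions(rt_first, rt_recov))

  specs_before <- neuron_population(
    config$n_neurons, frac_movement = config$frac_movement,
    frac_contra = config$frac_contra, frac_ipsi = config$frac_ipsi,
    response_amplitude = config$response_amplitude,
    noise_sd = config$noise_sd,
    seed = substream_seed(config$seed, "specs"))
  specs_after <- apply_plasticity(
    specs_before, p_contra_to_none = config$p_contra_to_none,
    p_none_to_ipsi = config$p_none_to_ipsi,
    seed = substream_seed(config$seed, "transitions"))

  act_before <- simulate_imaging_session(config, specs_before, "before")
  act_after <- simulate_imaging_session(config, specs_after, "after")
  resp_before <- responses_by_neuron(act_before, "before")
  resp_after <- responses_by_neuron(act_after, "after")
  ids <- intersect(names(resp_before), names(resp_after))
  neurons <- dplyr::bind_rows(lapply(ids, function(id)
    paired_selectivity(resp_before[[id]], resp_after[[id]],
                       alpha = config$alpha,
                       min_trials = config$min_trials)))
  cls_before <- classify_population(act_before, alpha = config$alpha,
                                    min_trials = config$min_trials)

  usable <- cls_before[cls_before$usable, ]
  move <- usable[usable$movement_related, ]
  pct <- function(k, n) if (n > 0) 100 * k / n else NA_real_
  move_pair <- neurons[neurons$usable & neurons$movement_either, ]
  sel_pair <- move_pair[move_pair$selective_either, ]
  skew_move <- if (nrow(move) > 0) population_skew_test(move$diff_dff)
               else NULL
  dsi_all <- move_pair$delta_si[!is.na(move_pair$delta_si)]
  dsi_sel <- sel_pair$delta_si[!is.na(sel_pair$delta_si)]
  population <- list(
    n_neurons = nrow(usable),
    n_movement_related = nrow(move),
    pct_movement_related = pct(nrow(move), nrow(usable)),
    pct_contra_selective_of_movement =
      pct(sum(move$direction == "contra"), nrow(move)),
    pct_ipsi_selective_of_movement =
      pct(sum(move$direction == "ipsi"), nrow(move)),
    pct_contra_selective_of_all =
      pct(sum(move$direction == "contra"), nrow(usable)),
    pct_ipsi_selective_of_all =
      pct(sum(move$direction == "ipsi"), nrow(usable)),
    diff_dff_skew = skew_move,
    n_selective_before = sum(neurons$usable &
                               neurons$direction_before != "none"),
    n_selective_after = sum(neurons$usable &
                              neurons$direction_after != "none"),
    n_ipsi_before = sum(neurons$usable & neurons$direction_before == "ipsi"),
    n_ipsi_after = sum(neurons$usable & neurons$direction_after == "ipsi"),
    n_contra_before = sum(neurons$usable &
                            neurons$direction_before == "contra"),
    n_contra_after = sum(neurons$usable &
                           neurons$direction_after == "contra"),
    delta_si_movement = if (length(dsi_all) > 0)
      population_skew_test(dsi_all) else NULL,
    delta_si_selective = if (length(dsi_sel) > 0)
      population_skew_test(dsi_sel) else NULL)

  structure(list(
    behavior = behavior, cross_phase = cross, neurons = neurons,
    classification_before = cls_before, population = population,
    provenance = list(seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("mosaccade")),
                      config = unclass(config))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  p <- x$population
  cat("<study_report>\n")
  cat(sprintf("  neurons: %d usable, %.1f%% movement-related, %.1f%%/%.1f%% contra/ipsi selective (of movement-related)\n",
              p$n_neurons, p$pct_movement_related,
              p$pct_contra_selective_of_movement,
              p$pct_ipsi_selective_of_movement))
  for (ph in names(x$behavior)) {
    s <- x$behavior[[ph]]$summary
    cat(sprintf("  %-10s prop RT<1s: %.3f (suppressed) vs %.3f; chi2 p = %.3g\n",
                ph, s$prop_lt_1s[s$suppressed], s$prop_lt_1s[!s$suppressed],
                x$behavior[[ph]]$contrast$p_chi2))
  }
  if (!is.null(p$delta_si_selective))
    cat(sprintf("  delta SI (selective): median %.3f, p = %.3g\n",
                p$delta_si_selective$median, p$delta_si_selective$p))
  invisible(x)
}

#' Write study-report artifacts as CSV and JSON files
#'
#' Emits `trials_<phase>.csv`, `behavior_summary.csv`, `contrasts.csv`,
#' `neuron_results.csv` and `report.json` into `dir`. Every statistic in
#' `report.json` is recomputable from the emitted tables.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list()
  contrasts <- list()
  for (ph in names(report$behavior)) {
    b <- report$behavior[[ph]]
    write.csv(b$trials, file.path(dir, sprintf("trials_%s.csv", ph)),
              row.names = FALSE)
    s <- b$summary
    s$phase <- ph
    summaries[[ph]] <- s
    contrasts[[ph]] <- tibble::tibble(
      comparison = sprintf("%s_suppressed_vs_not", ph),
      chi2 = b$contrast$chi2, p_chi2 = b$contrast$p_chi2,
      p_mannwhitney = b$contrast$p_mannwhitney)
  }
  contrasts$cross <- tibble::tibble(
    comparison = "first_day_vs_recovered_suppressed",
    chi2 = report$cross_phase$chi2_lt1s$statistic,
    p_chi2 = report$cross_phase$chi2_lt1s$p,
    p_mannwhitney = report$cross_phase$mannwhitney$p)
  write.csv(dplyr::bind_rows(summaries),
            file.path(dir, "behavior_summary.csv"), row.names = FALSE)
  write.csv(dplyr::bind_rows(contrasts),
            file.path(dir, "contrasts.csv"), row.names = FALSE)
  write.csv(report$neurons, file.path(dir, "neuron_results.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(population = report$population, provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE)
  invisible(dir)
}
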