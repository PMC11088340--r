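## Session containers, validation, persistence and the config-driven
## pipeline driver.

#' Assemble a session container
#'
#' @param units named list of `spike_trains` (one per unit, identical trial
#'   designs).
#' @param stimuli trial metadata table shared by the units.
#' @param behavior optional behavioral trial table.
#' @param seed master seed the session was generated from.
#' @param config configuration object the session came from (hashed into the
#'   provenance record).
#' @return object of class `session`.
#' @export
make_session <- function(units, stimuli, behavior = NULL, seed = NA,
                         config = list()) {
  s <- structure(list(units = units, stimuli = stimuli, behavior = behavior,
                      provenance = list(
                        seed = seed,
                        config_hash = config_hash(config),
                        package_version =
                          as.character(utils::packageVersion("amcoder")),
                        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
                 class = "session")
  validate_session(s)
  s
}

#' Validate a session container
#'
#' Checks that every unit's trials reference the shared stimulus table and
#' that spike lists line up with the trial count; malformed sessions are
#' rejected before any computation.
#'
#' @param session a `session`.
#' @return `session`, invisibly; stops with a validation error otherwise.
#' @export
validate_session <- function(session) {
  if (!length(session$units)) stop("validation error: session has no units")
  n_stim <- nrow(session$stimuli)
  for (nm in names(session$units)) {
    u <- session$units[[nm]]
    if (length(u$spikes) != nrow(u$trials))
      stop("validation error: unit ", nm, " spike list does not match trials")
    if (nrow(u$trials) != n_stim)
      stop("validation error: unit ", nm,
           " references undefined stimuli (", nrow(u$trials), " trials vs ",
           n_stim, " stimulus rows)")
  }
  invisible(session)
}

#' Save a session to a directory container
#'
#' Lossless plain-text layout: `provenance.json`, `stimuli.csv`,
#' `behavior.csv` (if present) and one `units/<id>.csv` per unit with spike
#' times printed at full double precision (17 significant digits), so a
#' save/load round trip reproduces every spike time bit-exactly.
#'
#' @param session a validated `session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  validate_session(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(path, "units"), showWarnings = FALSE)
  jsonlite::write_json(session$provenance, file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(session$stimuli, file.path(path, "stimuli.csv"),
                   row.names = FALSE)
  if (!is.null(session$behavior))
    utils::write.csv(session$behavior, file.path(path, "behavior.csv"),
                     row.names = FALSE)
  for (nm in names(session$units)) {
    u <- session$units[[nm]]
    df <- data.frame(trial = rep(u$trials$trial, lengths(u$spikes)),
                     spike_time = fmt_double(unlist(u$spikes)))
    utils::write.csv(df, file.path(path, "units", paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Load a session from a directory container
#'
#' @param path directory written by [save_session()].
#' @return a `session`.
#' @export
load_session <- function(path) {
  prov <- jsonlite::read_json(file.path(path, "provenance.json"),
                              simplifyVector = TRUE)
  stimuli <- utils::read.csv(file.path(path, "stimuli.csv"))
  behavior <- if (file.exists(file.path(path, "behavior.csv")))
    utils::read.csv(file.path(path, "behavior.csv")) else NULL
  unit_files <- list.files(file.path(path, "units"), full.names = TRUE)
  units <- list()
  for (f in unit_files) {
    nm <- sub("\\.csv$", "", basename(f))
    df <- utils::read.csv(f, colClasses = c("integer", "character"))
    spikes <- lapply(seq_len(nrow(stimuli)), function(i)
      as.numeric(df$spike_time[df$trial == stimuli$trial[i]]))
    units[[nm]] <- structure(list(trials = stimuli, spikes = spikes),
                             class = "spike_trains")
  }
  s <- structure(list(units = units, stimuli = stimuli, behavior = behavior,
                      provenance = prov),
                 class = "session")
  validate_session(s)
  s
}

#' Default configuration of the salicylate-analogue demonstration
#'
#' A two-condition study: the "salicylate" condition multiplies each unit's
#' rate gain and phase-locking strength (sensitization) and lowers the
#' behavioral psychometric threshold, so every downstream threshold
#' (temporal, rate, decoder, behavioral) should come out lower than at
#' baseline.
#'
#' @param seed master seed.
#' @return configuration list accepted by [run_pipeline()].
#' @export
demo_salicylate_config <- function(seed = 1L) {
  list(
    seed = seed,
    stages = c("simulate", "amcode", "popdecode", "behavior"),
    n_units = 8,
    n_trials = 15,
    fmod = 16,
    depths = c(0, 0.06, 0.125, 0.25, 0.5, 1),
    um_duration = 1, am_duration = 1,
    conditions = list(baseline = list(gain = 1, lock = 1),
                      salicylate = list(gain = 1.6, lock = 2)),
    behavior = list(baseline = list(threshold_db = -10),
                    salicylate = list(threshold_db = -16),
                    n_per_cell = 30, n_catch = 60)
  )
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the configured stages end-to-end on synthetic data: `simulate`
#' (population spike trains and behavioral sessions per condition),
#' `amcode` (per-unit temporal and rate sensitivity curves), `popdecode`
#' (AM-encoding component, latency decoder and its thresholds) and
#' `behavior` (psychometric analysis). Tidy CSV outputs, a provenance
#' record and a log with all per-stage seeds and timings are written under
#' `out_dir`; results computed before a stage failure are preserved on
#' disk. Fully deterministic per (config, seed).
#'
#' @param config configuration list or path to a YAML file (see
#'   [demo_salicylate_config()] for the schema).
#' @param out_dir output directory.
#' @return list of stage results, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  ## YAML parses mixed int/real sequences as lists; flatten scalars/vectors
  for (f in c("depths", "fmod", "seed", "n_units", "n_trials",
              "um_duration", "am_duration"))
    if (!is.null(config[[f]])) config[[f]] <- as.numeric(unlist(config[[f]]))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(sprintf("pipeline started %s\nconfig hash %s\nseed %s\n",
              format(Sys.time()), config_hash(config), config$seed),
      file = log_path)
  res <- list()
  stages <- config$stages %||% c("simulate", "amcode", "popdecode",
                                 "behavior")
  conds <- names(config$conditions)
  t0 <- proc.time()[3]

  if ("simulate" %in% stages) {
    seed_s <- substream_seed(config$seed, "simulate")
    logf("stage simulate: seed %d", seed_s)
    design <- do.call(rbind, lapply(conds, function(cn)
      data.frame(fmod = config$fmod, depth = config$depths,
                 intensity = 60, condition = cn)))
    mult <- lapply(config$conditions, function(x)
      c(gain = x$gain, lock = x$lock))
    set.seed(substream_seed(config$seed, "unit_params"))
    unit_params <- lapply(seq_len(config$n_units), function(i)
      sam_unit_params(r_base = stats::runif(1, 10, 40),
                      gain_slope = stats::runif(1, 0.3, 0.8),
                      lock_strength = stats::runif(1, 1.5, 4),
                      pref_phase = stats::runif(1, -pi, pi),
                      condition_multipliers = mult))
    pop <- simulate_population(unit_params, design,
                               n_trials = config$n_trials,
                               um_duration = config$um_duration,
                               am_duration = config$am_duration,
                               seed = seed_s)
    behav <- do.call(rbind, lapply(conds, function(cn) {
      bp <- do.call(behavior_model_params,
                    config$behavior[[cn]] %||% list())
      simulate_behavior_session(
        bp, behavior_design(fmod = config$fmod,
                            n_per_cell = config$behavior$n_per_cell %||% 25,
                            n_catch = config$behavior$n_catch %||% 50,
                            condition = cn),
        seed = substream_seed(config$seed, paste0("behavior_", cn)))
    }))
    session <- make_session(pop$units, pop$trials, behav,
                            seed = config$seed, config = config)
    save_session(session, file.path(out_dir, "session"))
    res$simulate <- list(pop = pop, behav = behav, session = session)
    logf("stage simulate done at %.1f s", proc.time()[3] - t0)
  }

  if ("amcode" %in% stages) {
    pop <- res$simulate$pop
    if (is.null(pop)) stop("amcode stage needs the simulate stage")
    curves <- list()
    for (nm in names(pop$units)) for (cn in conds)
      for (coding in c("temporal", "rate")) {
        u <- pop$units[[nm]]
        sel <- u$trials$condition == cn
        sub <- list(trials = u$trials[sel, ], spikes = u$spikes[sel])
        curves[[paste(nm, cn, coding, sep = "_")]] <-
          sensitivity_curve(sub, coding, fmod = config$fmod)
      }
    tab <- sensitivity_table(curves,
                             file.path(out_dir, "sensitivity_curves.csv"))
    res$amcode <- list(curves = curves, table = tab)
    logf("stage amcode done at %.1f s", proc.time()[3] - t0)
  }

  if ("popdecode" %in% stages) {
    pop <- res$simulate$pop
    if (is.null(pop)) stop("popdecode stage needs the simulate stage")
    seed_d <- substream_seed(config$seed, "popdecode")
    logf("stage popdecode: seed %d", seed_d)
    pa <- population_activity(pop)
    comp <- am_encoding_component(pa, condition = conds[1])
    utils::write.csv(data.frame(unit = pa$unit_ids, weight = as.numeric(comp)),
                     file.path(out_dir, "am_component.csv"),
                     row.names = FALSE)
    proj <- project_trials(pa, comp)
    transition <- pa$trials$transition[1]
    ## detection level halfway between the pre-transition baseline peak and
    ## the post-transition peak of full-depth trials
    base <- stats::median(apply(proj[, pa$times < transition,
                                     drop = FALSE], 1, max))
    peak <- stats::median(apply(proj[pa$trials$depth == 1,
                                     pa$times >= transition,
                                     drop = FALSE], 1, max))
    level <- base + 0.5 * (peak - base)
    dec <- list()
    for (cn in conds) {
      sel <- pa$trials$condition == cn
      lat <- decoder_latencies(proj[sel, , drop = FALSE], pa$times,
                               level, 0.150, transition)
      dd <- pa$trials$depth[sel]
      dec[[cn]] <- decoder_sensitivity(
        split(lat[dd > 0], dd[dd > 0]), lat[dd == 0])
    }
    th <- data.frame(condition = conds,
                     threshold_db = vapply(dec, function(x)
                       as.numeric(x$threshold_db), numeric(1)))
    utils::write.csv(th, file.path(out_dir, "decoder_thresholds.csv"),
                     row.names = FALSE)
    res$popdecode <- list(component = comp, curves = dec, thresholds = th)
    logf("stage popdecode done at %.1f s", proc.time()[3] - t0)
  }

  if ("behavior" %in% stages) {
    behav <- res$simulate$behav
    if (is.null(behav)) stop("behavior stage needs the simulate stage")
    pr <- analyze_behavior(behav)
    utils::write.csv(pr$summary, file.path(out_dir, "behavior_summary.csv"),
                     row.names = FALSE)
    res$behavior <- pr
    logf("stage behavior done at %.1f s", proc.time()[3] - t0)
  }

  logf("pipeline finished at %.1f s", proc.time()[3] - t0)
  invisible(res)
}
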