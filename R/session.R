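#' Trial tables for the simulated tasks
#'
#' \code{nbackTrialTable} lays out n-back blocks: each block holds 36 + n
#' trials (37 at load 1, 38 at load 2), object/scene categories balanced
#' within block, exemplars drawn from a per-category pool, and the
#' trial-duration jitter options (0/50/100/150 ms) represented as equally as
#' the trial count allows (counts differ by at most one). \code{dmsTrialTable}
#' lays out a delayed match-to-sample run of 90 trials: 15 unique exemplars
#' (5 objects, 5 scenes, 5 faces) presented 6 times each in random order,
#' jitter balanced within run.
#'
#' @param blocks named integer vector, e.g. \code{c("2-back" = 8, "1-back" =
#'   4)}; block order is randomized.
#' @param seed integer seed.
#' @param exemplars_per_category exemplar pool size per category (n-back).
#' @param jitter jitter options in seconds.
#' @return data.frame with columns task, block, trial, category, exemplar,
#'   jitter_s.
#' @export
nbackTrialTable <- function(blocks = c("2-back" = 8L, "1-back" = 4L),
                            seed = 1L, exemplars_per_category = 8L,
                            jitter = c(0, 0.05, 0.10, 0.15)) {
  withSeed(seed, {
    order <- sample(rep(names(blocks), blocks))
    out <- list()
    for (b in seq_along(order)) {
      lvl <- order[b]
      n <- 36L + as.integer(sub("-back", "", lvl))
      cat_ <- sample(rep_len(c("object", "scene"), n))
      ex <- paste0(substr(cat_, 1, 3),
                   sample.int(exemplars_per_category, n, replace = TRUE))
      jt <- sample(rep_len(jitter, n))
      out[[b]] <- data.frame(task = lvl, block = b, trial = seq_len(n),
                             category = cat_, exemplar = ex, jitter_s = jt)
    }
    do.call(rbind, out)
  })
}

#' @rdname nbackTrialTable
#' @param run run index (1 or 2) recorded in the block column.
#' @export
dmsTrialTable <- function(run = 1L, seed = 1L,
                          jitter = c(0, 0.05, 0.10, 0.15)) {
  withSeed(seed, {
    cats <- c("object", "scene", "face")
    ex <- paste0(substr(rep(cats, each = 5L), 1, 3), rep(1:5, 3L))
    stim <- sample(rep(ex, 6L))               # 15 exemplars x 6 presentations
    n <- length(stim)
    jt <- sample(rep_len(jitter, n))
    data.frame(task = "dms", block = run, trial = seq_len(n),
               category = substr(stim, 1, 3), exemplar = stim, jitter_s = jt)
  })
}

#' Simulate a complete EEG session for one participant
#'
#' Generates, per task and epoch type, an [EpochSet-class] of 1/f background
#' noise with the configured effects injected: a fronto-medial theta
#' oscillator during the delay (per-task mean frequency and amplitude),
#' posterior category-specific patterns during stimulus and delay (patterns
#' shared across epochs of the session), and theta-band coupling between the
#' frontal seed and posterior channels during the delay. Inter-block 10 s
#' baseline epochs (noise only, two per n-back block) are emitted when
#' requested. Epoch arrays are rectangular at the minimum epoch duration
#' (the per-trial jitter is recorded in the metadata, not in the array) and
#' include 200 ms of pre-onset padding.
#'
#' All randomness derives from \code{config$master_seed} and the participant
#' index, so identical inputs give byte-identical outputs.
#'
#' @param config a [simConfig()] object.
#' @param participant participant index (changes the derived seeds).
#' @param tasks subset of c("dms", "1-back", "2-back") to generate.
#' @param epoch_types subset of c("stimulus", "response", "delay").
#' @param include_baseline emit inter-block baseline epochs for n-back tasks.
#' @param scenario "default" uses \code{theta_presets}; "irasa" uses
#'   \code{irasa_presets} (the 1/f-control oscillator scenario).
#' @return list with \code{epochs} (epochs[[task]][[epoch_type]]),
#'   \code{baseline} ([EpochSet-class] or NULL), \code{layout}, and
#'   \code{manifest} (list: \code{trials} data.frame with one row per
#'   generated trial incl. true oscillator frequency; \code{effects} with the
#'   injected channel sets, strengths and all seeds).
#' @export
simulateSession <- function(config, participant = 1L,
                            tasks = c("dms", "1-back", "2-back"),
                            epoch_types = c("stimulus", "delay"),
                            include_baseline = FALSE,
                            scenario = c("default", "irasa")) {
  stopifnot(inherits(config, "SimConfig"))
  scenario <- match.arg(scenario)
  validateSimConfig(config)
  bad <- setdiff(tasks, c("dms", "1-back", "2-back"))
  if (length(bad)) stop("unknown task(s): ", paste(bad, collapse = ", "))
  layout <- makeMontage(config$n_channels, config$head_radius,
                        deriveSeed(config$master_seed, 0))
  frontal <- frontalChannels(layout, 0.5)
  posterior <- posteriorChannels(layout, 0.5)
  presets <- if (scenario == "irasa") config$irasa_presets
             else config$theta_presets
  dur <- config$durations
  ms <- config$master_seed
  patternSeed <- deriveSeed(ms, participant, 90)
  epochs <- list()
  trials <- list()
  plan <- config$task_plan
  for (task in tasks) {
    ti <- match(task, c("dms", "1-back", "2-back"))
    tab <- if (task == "dms") {
      do.call(rbind, lapply(seq_len(plan$dms_runs), function(r)
        dmsTrialTable(r, deriveSeed(ms, participant, ti, r))))
    } else {
      nb <- plan$nback_blocks[task]
      names(nb) <- task
      nbackTrialTable(nb, deriveSeed(ms, participant, ti, 1),
                      jitter = dur$jitter)
    }
    n <- nrow(tab)
    acc <- config$accuracy_presets[task]
    beh <- withSeed(deriveSeed(ms, participant, ti, 2), list(
      correct = stats::runif(n) < acc,
      rt = stats::rlnorm(n, meanlog = log(0.55), sdlog = 0.25)))
    tab$correct <- beh$correct
    tab$rt <- beh$rt
    tab$participant <- participant
    preset <- presets[[if (task == "dms") "dms" else task]]
    taskEp <- list()
    manifestFreq <- rep(NA_real_, n)
    manifestPhase <- rep(NA_real_, n)
    for (et in epoch_types) {
      info <- tab
      info$epoch <- et
      ep <- generateNoise(n, layout, dur[[et]], config$sampling_rate,
                          config$noise_exponent,
                          deriveSeed(ms, participant, ti, 10 + match(et,
                            c("stimulus", "response", "delay"))),
                          sd = config$noise_sd, pre_onset = dur$pre_onset,
                          info = info)
      if (et %in% c("stimulus", "delay")) {
        cp <- embedCategoryPattern(ep, posterior, config$category_strength,
                                   patternSeed)
        ep <- cp$epochs
      }
      if (et == "delay" && !is.null(preset) && preset$amplitude > 0) {
        em <- embedOscillation(ep, frontal, preset$mean_freq, preset$freq_sd,
                               preset$amplitude,
                               deriveSeed(ms, participant, ti, 20))
        ep <- em$epochs
        manifestFreq <- em$manifest$freq_hz
        manifestPhase <- em$manifest$phase
      }
      if (et == "delay") {
        cs <- config$coupling_strength[task]
        if (!is.na(cs) && cs > 0)
          ep <- embedCoupling(ep, "Fz", posterior, c(4, 8), cs,
                              deriveSeed(ms, participant, ti, 30),
                              amplitude = config$coupling_amplitude)
      }
      taskEp[[et]] <- ep
    }
    tab$theta_freq_hz <- manifestFreq
    tab$theta_phase <- manifestPhase
    epochs[[task]] <- taskEp
    trials[[task]] <- tab
  }
  baseline <- NULL
  nbackTasks <- intersect(tasks, c("1-back", "2-back"))
  if (include_baseline && length(nbackTasks)) {
    nb <- 2L * sum(plan$nback_blocks[nbackTasks])
    baseline <- generateNoise(
      nb, layout, dur$baseline, config$sampling_rate, config$noise_exponent,
      deriveSeed(ms, participant, 40), sd = config$noise_sd,
      info = data.frame(task = "baseline", block = rep(seq_len(nb %/% 2L),
                                                       each = 2L),
                        epoch = "baseline"))
  }
  trials <- do.call(rbind, c(trials, list(make.row.names = FALSE)))
  manifest <- list(
    trials = trials,
    effects = list(frontal_channels = frontal,
                   posterior_channels = posterior,
                   theta_presets = presets, scenario = scenario,
                   category_strength = config$category_strength,
                   category_pattern_seed = patternSeed,
                   coupling = list(seed_channel = "Fz",
                                   target_channels = posterior,
                                   band = c(4, 8),
                                   strength = config$coupling_strength,
                                   amplitude = config$coupling_amplitude),
                   master_seed = ms, participant = participant))
  list(epochs = epochs, baseline = baseline, layout = layout,
       manifest = manifest)
}

#' Simulate delay-period trials for one oscillator condition
#'
#' Compact generator used by the peak-frequency recovery analyses: delay
#' epochs of 1/f noise with the condition's theta oscillator on the frontal
#' channel set, no other effects. The montage and frontal set come from the
#' config.
#'
#' @param n_trials trials to generate.
#' @param preset list(mean_freq, freq_sd, amplitude).
#' @param config a [simConfig()].
#' @param seed integer seed for this batch.
#' @return list(epochs, manifest, frontal) as in [embedOscillation()].
#' @export
simulateDelayTrials <- function(n_trials, preset, config, seed) {
  layout <- makeMontage(config$n_channels, config$head_radius,
                        deriveSeed(config$master_seed, 0))
  frontal <- frontalChannels(layout, 0.5)
  ep <- generateNoise(n_trials, layout, config$durations$delay,
                      config$sampling_rate, config$noise_exponent,
                      deriveSeed(seed, 1), sd = config$noise_sd,
                      pre_onset = config$durations$pre_onset)
  em <- embedOscillation(ep, frontal, preset$mean_freq, preset$freq_sd,
                         preset$amplitude, deriveSeed(seed, 2))
  list(epochs = em$epochs, manifest = em$manifest, frontal = frontal)
}

#' Write / read a ground-truth manifest as JSON lines
#'
#' One JSON record per trial; numbers keep full precision.
#'
#' @param trials the manifest trial data.frame.
#' @param path file path.
#' @return \code{readManifest} returns the data.frame.
#' @export
writeManifest <- function(trials, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(trials)))
    writeLines(jsonlite::toJSON(as.list(trials[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  lines <- readLines(path)
  recs <- lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
  do.call(rbind, recs)
}
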