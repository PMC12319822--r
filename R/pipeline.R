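#' Experiment templates
#'
#' Encodes the three study designs as configuration presets: the
#' movement-activation Go/NoGo design with MEG-style prep (500 Hz, 1-245 Hz
#' band-pass, notches at 49-55, 99-101, 149-151 and 199-201 Hz, source-space
#' beamforming, four band features), the paced-press variant, and the
#' EEG-style Go-only design (250 Hz, 1-95 Hz band-pass, 49-51 Hz notch,
#' slow-gamma only, channel-space peaks).
#'
#' @param id `"experiment1"`, `"experiment2"` or `"experiment3"`.
#' @return A template list used by [run_experiment()].
#' @export
experiment_template <- function(id = c("experiment1", "experiment2", "experiment3")) {
  id <- match.arg(id)
  base_bands <- list(
    beta_erd   = list(band = c(13, 30), mode = "min", lock = "onset",
                      baseline = c(-1, -0.5), filt = c(13, 30)),
    beta_ers   = list(band = c(13, 30), mode = "max", lock = "offset",
                      baseline = c(-1.5, -1), filt = c(13, 30)),
    slow_gamma = list(band = c(30, 60), mode = "max", lock = "onset",
                      baseline = c(-1, -0.5), filt = c(30, 60)),
    mid_gamma  = list(band = c(60, 90), mode = "max", lock = "onset",
                      baseline = c(-1, -0.5), filt = c(60, 90)))
  switch(id,
    experiment1 = list(
      id = id, task_id = "MA1", target_rate = 500,
      bandpass = c(1, 245),
      notches = list(c(49, 55), c(99, 101), c(149, 151), c(199, 201)),
      beamform = TRUE, bands = base_bands,
      mep = list(protocols = c("spMEP_early", "spMEP_late",
                               "SICI_early", "SICI_late"),
                 n_trials = 15L,
                 pairs = list(early = c("SICI_early", "spMEP_early"),
                              late = c("SICI_late", "spMEP_late")))),
    experiment2 = list(
      id = id, task_id = "MA2", target_rate = 500,
      bandpass = c(1, 245),
      notches = list(c(49, 55), c(99, 101), c(149, 151), c(199, 201)),
      beamform = TRUE, bands = base_bands["mid_gamma"],
      mep = NULL),
    experiment3 = list(
      id = id, task_id = "MA1-exp3", target_rate = 250,
      bandpass = c(1, 95), notches = list(c(49, 51)),
      beamform = FALSE, bands = base_bands["slow_gamma"],
      mep = list(protocols = c("spMEP", "SICI1ms", "SICI2.5ms"),
                 n_trials = 13L,
                 pairs = list(sici_1ms = c("SICI1ms", "spMEP"),
                              sici_2p5ms = c("SICI2.5ms", "spMEP")))))
}

#' Band-peak features for one simulated subject
#'
#' Runs the full sensor-to-feature chain on one subject: simulate (or accept)
#' a recording, downsample, band-pass/notch filter the sensor channels,
#' flag bad segments, detect movement onsets/offsets from EMG and exclude
#' outlier trials, then per band: band-filter, eigenvalue-normalise,
#' beamform (or stay in channel space), epoch around the lock event,
#' multitaper-decompose, baseline-correct and extract the band peak.
#'
#' @param config A [sim_config()].
#' @param template A template from [experiment_template()].
#' @param seed RNG seed for this subject.
#' @param bands Character vector naming which of the template's band
#'   features to compute (default: all).
#' @param rank LCMV PCA rank (default 50, clipped to the channel count).
#' @param roi Optional integer source/channel indices restricting the peak
#'   search.
#' @param rec Optional pre-simulated [recording()] (attributes `truth` and
#'   `leadfield` as produced by [simulate_recording()]).
#' @param max_trials Optionally truncate the simulated schedule to its first
#'   `max_trials` trials (shortens simulation studies; the full task designs
#'   are kept when `NULL`).
#' @return List with `features` (data frame: one row per band), `marks`,
#'   `mask`, `truth`.
#' @export
run_subject_features <- function(config, template = experiment_template(),
                                 seed = 1L, bands = names(template$bands),
                                 rank = 50, roi = NULL, rec = NULL,
                                 max_trials = NULL) {
  if (is.null(rec)) {
    schedule <- make_trial_schedule(template$task_id, child_seed(seed, 10))
    if (!is.null(max_trials))
      schedule <- schedule[schedule$trial <= max_trials, , drop = FALSE]
    truth <- make_ground_truth(config, schedule, child_seed(seed, 11))
    rec <- simulate_recording(config, schedule, truth, seed)
  } else {
    truth <- attr(rec, "truth")
  }
  lf <- attr(rec, "leadfield")
  rec <- resample_recording(rec, min(template$target_rate, rec$sampling_rate))
  fs <- rec$sampling_rate
  nyq <- fs / 2
  bp_hi <- min(template$bandpass[2], 0.95 * nyq)
  notches <- Filter(function(nt) nt[2] < 0.95 * nyq, template$notches)
  sens <- channels_in(rec)
  rec <- filter_band(rec, template$bandpass[1], bp_hi, notches, channels = sens)
  mask <- detect_bad_segments(rec)
  marks <- exclude_trials(detect_movements(rec))
  ok <- marks[!marks$excluded, , drop = FALSE]
  assert_that(nrow(ok) >= 5, "only %d trials survive EMG screening", nrow(ok))

  feats <- list()
  for (bn in bands) {
    bd <- template$bands[[bn]]
    rb <- filter_band(rec, bd$filt[1], bd$filt[2], channels = sens)
    rb <- eigen_normalize(rb)
    if (template$beamform) {
      C <- sensor_covariance(rb, mask)
      W <- lcmv_weights(C, lf, rank = rank)
      src <- project_sources(rb, W)
    } else {
      src <- rb$data[sens, , drop = FALSE]
    }
    lock_s <- if (bd$lock == "onset") ok$onset_s else ok$offset_s
    lock_samples <- round((ok$go_sample / fs + lock_s) * fs) + 1L
    epochs <- epoch_data(src, fs, lock_samples,
                         bad_samples = mask_samples(mask, fs))
    kept <- attr(epochs, "kept")
    tf <- multitaper_tf(epochs, fs, freq_range = bd$band)
    tf <- baseline_correct(tf, bd$baseline)
    win <- mark_windows(ok[kept, , drop = FALSE], bd$lock)
    pk <- extract_band_peak(tf, win, bd$band, mode = bd$mode, roi = roi)
    feats[[bn]] <- data.frame(band = bn, power = pk$power,
                              peak_freq_hz = pk$peak_frequency,
                              peak_loc = pk$peak_location,
                              n_epochs = dim(epochs)[1])
  }
  list(features = do.call(rbind, feats), marks = marks, mask = mask,
       truth = truth)
}

#' SICI measures for one simulated subject
#'
#' Simulates the template's MEP protocols, applies the rejection rules and
#' computes one SICI ratio per conditioned/unconditioned protocol pair.
#'
#' @param config A [sim_config()].
#' @param template A template from [experiment_template()] with a `mep`
#'   block.
#' @param seed RNG seed.
#' @return Data frame with one row per pair: `pair`, `ratio`,
#'   `conditioned_mean`, `unconditioned_mean`, `n_conditioned`,
#'   `n_unconditioned`, `n_rejected`.
#' @export
run_subject_sici <- function(config, template = experiment_template(), seed = 1L) {
  assert_that(!is.null(template$mep), "template '%s' has no TMS block",
              template$id)
  trials <- do.call(rbind, lapply(seq_along(template$mep$protocols), function(i)
    simulate_mep_trials(config, template$mep$protocols[i],
                        template$mep$n_trials, child_seed(seed, 20 + i))))
  trials <- reject_mep_trials(trials)
  rows <- lapply(names(template$mep$pairs), function(pn) {
    pr <- template$mep$pairs[[pn]]
    s <- sici(trials, pr[1], pr[2])
    data.frame(pair = pn, ratio = s$ratio,
               conditioned_mean = s$conditioned_mean,
               unconditioned_mean = s$unconditioned_mean,
               n_conditioned = s$n_used["conditioned"],
               n_unconditioned = s$n_used["unconditioned"],
               n_rejected = sum(trials$rejected))
  })
  do.call(rbind, rows)
}

#' Run a full simulated experiment
#'
#' Simulates a correlated population of subjects, runs the sensor-to-feature
#' chain, the TMS chain and the behavioural tasks per subject, and
#' correlates the requested subject-level features with bootstrap outlier
#' removal and a default-prior Bayes factor. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param template A template from [experiment_template()] (or its id).
#' @param bands Band features to compute per subject (default: the
#'   template's full set).
#' @param rank,roi Passed to [run_subject_features()].
#' @param behaviour Also simulate and score the two learning tasks
#'   (default `TRUE`).
#' @param corr_pairs List of `c(feature_x, feature_y)` column pairs from the
#'   feature table to correlate; defaults to slow-gamma peak frequency vs
#'   SICI ratio when both are available.
#' @param max_trials Passed to [run_subject_features()].
#' @return List: `features` (one row per subject x band), `sici`,
#'   `learning`, `correlations` (one `correlation_result` per pair),
#'   `population`, `dropped` (named reasons for subjects excluded because
#'   their data could not support the chain), `template_id`, `seed`.
#' @export
run_experiment <- function(config, template = experiment_template(),
                           bands = names(template$bands), rank = 50,
                           roi = NULL, behaviour = TRUE, corr_pairs = NULL,
                           max_trials = NULL) {
  if (is.character(template)) template <- experiment_template(template)
  pop <- simulate_population(config)
  n <- config$n_subjects
  feat_rows <- list(); sici_rows <- list(); learn_rows <- list()
  dropped <- character(0)
  for (i in seq_len(n)) {
    cfg_i <- pop$configs[[i]]
    sseed <- pop$table$subject_seed[i]
    # a subject whose data do not support the chain (e.g. too few usable
    # trials) is excluded from the study rather than aborting it
    sf <- tryCatch(
      run_subject_features(cfg_i, template, seed = sseed, bands = bands,
                           rank = rank, roi = roi, max_trials = max_trials),
      error = function(e) {
        dropped[as.character(i)] <<- conditionMessage(e)
        NULL
      })
    if (is.null(sf)) next
    sf$features$subject <- i
    feat_rows[[i]] <- sf$features
    if (!is.null(template$mep)) {
      si <- run_subject_sici(cfg_i, template, seed = sseed)
      si$subject <- i
      sici_rows[[i]] <- si
    }
    if (behaviour) {
      m1 <- ml1_score(simulate_ml1(cfg_i, child_seed(sseed, 30)))
      m2 <- ml2_score(simulate_ml2(cfg_i, child_seed(sseed, 31)))
      learn_rows[[i]] <- data.frame(
        subject = i, ml1_score_pct = m1$value,
        ml2_delta_mt_s = m2$value["delta_mt_s"],
        ml2_delta_error_deg = m2$value["delta_error_deg"])
    }
  }
  if (length(dropped) > 0) {
    warning(sprintf("excluded %d of %d subjects: %s", length(dropped), n,
                    paste(names(dropped), collapse = ", ")))
  }
  features <- do.call(rbind, feat_rows)
  sici_tab <- if (length(sici_rows)) do.call(rbind, sici_rows) else NULL
  learning <- if (length(learn_rows)) do.call(rbind, learn_rows) else NULL

  correlations <- list()
  if (is.null(corr_pairs) && "slow_gamma" %in% bands && !is.null(sici_tab)) {
    corr_pairs <- list(slow_gamma_freq_vs_sici = NULL)
  }
  # subject-level inference needs a population worth of subjects
  if (!is.null(corr_pairs) && "slow_gamma" %in% bands && !is.null(sici_tab)) {
    sg <- features[features$band == "slow_gamma", ]
    first_pair <- split(sici_tab, sici_tab$pair)[[1]]
    common <- intersect(sg$subject, first_pair$subject)
    if (length(common) >= 10) {
      correlations$slow_gamma_freq_vs_sici <- correlate_features(
        sg$peak_freq_hz[match(common, sg$subject)],
        first_pair$ratio[match(common, first_pair$subject)],
        seed = child_seed(config$seed, 40))
    }
  }
  list(features = features, sici = sici_tab, learning = learning,
       correlations = correlations, population = pop, dropped = dropped,
       template_id = template$id, seed = config$seed)
}
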