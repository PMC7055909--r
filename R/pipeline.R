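#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline with its default:
#' VAD framing and thresholds, feature bands, screening thresholds
#' (4-of-5 agreement, 0.8 confidence), the classifier grid and the master
#' seed.
#'
#' @param out_dir Output directory for artifacts (`NULL` = no files
#'   written).
#' @param simulate Number of records per class to synthesize (`0` = expect
#'   `wav_paths`).
#' @param wav_paths Optional character vector of input WAV files (named by
#'   sample id).
#' @param labels Optional named character vector of labels for
#'   `wav_paths`.
#' @param duration_s,rate_hz,silence_s Synthesis parameters.
#' @param vad_params List of [detect_utterance()] arguments.
#' @param f0_range_hz,harmonic_band_hz,entropy_band_hz,entropy_base
#'   Feature-extraction parameters.
#' @param screen Logical: simulate a rater panel and keep only pure
#'   samples.
#' @param panel A [panel_spec()] used when `screen = TRUE`.
#' @param min_agree,min_conf Pure-sample thresholds.
#' @param classifiers Classifier kinds for the evaluation grid.
#' @param subsets Subset families: any of `"lofo"`, `"spectral"`,
#'   `"stability"` (the full set is always included).
#' @param folds,nn_repeats Evaluation-design sizes.
#' @param seed Master seed; all pipeline randomness derives from it.
#' @param write_wav Logical: write synthesized records as WAV + JSON truth
#'   sidecars under `out_dir`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = NULL,
                            simulate = 0,
                            wav_paths = NULL,
                            labels = NULL,
                            duration_s = 2, rate_hz = 44100, silence_s = 0.5,
                            vad_params = list(),
                            f0_range_hz = c(100, 400),
                            harmonic_band_hz = c(50, 1500),
                            entropy_band_hz = c(0, 3000),
                            entropy_base = exp(1),
                            screen = FALSE,
                            panel = panel_spec(),
                            min_agree = 4, min_conf = 0.8,
                            classifiers = c("dt", "ld", "svm", "knn", "nn"),
                            subsets = c("lofo", "spectral", "stability"),
                            folds = 5, nn_repeats = 6,
                            seed = 1,
                            write_wav = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full voice-type discrimination pipeline
#'
#' Composition of all stages: (optional) synthesis of a labelled cohort,
#' voice activity detection, feature extraction, (optional) simulated
#' panel screening down to pure samples, and the classifier-by-subset
#' evaluation grid with per-type metrics and chi-square classifier
#' comparison.  Deterministic for a fixed configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return List with `features` (the extracted feature table), `screening`
#'   (kappa and pure-sample summary, when enabled), `report` (a
#'   `vt_report`), `per_type` (per-type TPR/FPR/AUC on the full set),
#'   `single_feature` (single-feature LD baseline) and `chi_square`
#'   (classifier comparison on the full set).
#' @examples
#' \donttest{
#' cfg <- pipeline_config(simulate = 25, rate_hz = 8000, duration_s = 1,
#'                        classifiers = c("ld", "knn"), subsets = NULL,
#'                        seed = 7)
#' res <- run_pipeline(cfg)
#' res$report
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ## ---- acquire records -------------------------------------------------
  if (config$simulate > 0) {
    classes <- c("modal", "breathy", "pressed")
    recs <- list(); labels <- character(); ids <- character()
    k <- 0L
    for (cl in classes) {
      for (i in seq_len(config$simulate)) {
        k <- k + 1L
        id <- sprintf("%s_%03d", cl, i)
        recs[[k]] <- synthesize_waveform(
          voice_profile(cl), config$duration_s, config$rate_hz,
          config$silence_s, seed = config$seed + 7919L * k)
        ids[k] <- id; labels[k] <- cl
      }
    }
    names(labels) <- ids
    if (isTRUE(config$write_wav) && !is.null(config$out_dir)) {
      wav_dir <- file.path(config$out_dir, "wav")
      dir.create(wav_dir, showWarnings = FALSE)
      for (k in seq_along(recs)) {
        write_wav(recs[[k]], file.path(wav_dir, paste0(ids[k], ".wav")))
        tr <- recs[[k]]$truth
        jsonlite::write_json(
          list(label = tr$profile$name, f0_hz = tr$f0_hz,
               jitter_pct = tr$profile$jitter_pct,
               shimmer_pct = tr$profile$shimmer_pct,
               silence_s = tr$silence_s,
               cycle_start_s = tr$cycle_start_s + tr$silence_s),
          file.path(wav_dir, paste0(ids[k], ".json")),
          auto_unbox = TRUE, digits = NA)
      }
    }
  } else {
    if (is.null(config$wav_paths))
      stop("configuration error: no input WAVs and simulate = 0",
           call. = FALSE)
    recs <- lapply(config$wav_paths, read_wav)
    ids <- names(config$wav_paths)
    if (is.null(ids)) ids <- sprintf("sample_%03d", seq_along(recs))
    labels <- config$labels
    if (is.null(labels) && !isTRUE(config$screen))
      stop("configuration error: labels (or screening) required",
           call. = FALSE)
  }

  ## ---- features --------------------------------------------------------
  feats <- extract_features_batch(
    recs, ids = ids,
    vad_params = config$vad_params,
    f0_range_hz = config$f0_range_hz,
    harmonic_band_hz = config$harmonic_band_hz,
    entropy_band_hz = config$entropy_band_hz,
    entropy_base = config$entropy_base)
  if (!is.null(labels)) feats$label <- unname(labels[feats$sample_id])

  ## ---- screening (optional) -------------------------------------------
  screening <- NULL
  if (isTRUE(config$screen)) {
    if (is.null(labels))
      stop("configuration error: screening needs truth labels to simulate ",
           "the panel", call. = FALSE)
    ratings <- simulate_panel(labels, config$panel,
                              seed = config$seed + 104729L)
    screened <- filter_pure(ratings, config$min_agree, config$min_conf)
    screening <- list(
      fleiss_kappa = fleiss_kappa(
        ratings[!grepl("_dup$", ratings$sample_id), ]),
      screened = screened,
      intra_rater = if (nrow(attr(ratings, "duplicate_map")) > 0)
        intra_rater_reliability(ratings) else NULL)
    keep <- feats$sample_id %in% names(screened$pure_labels)
    feats <- feats[keep, , drop = FALSE]
    feats$label <- unname(screened$pure_labels[feats$sample_id])
    if (!is.null(config$out_dir))
      jsonlite::write_json(
        list(fleiss_kappa = screening$fleiss_kappa,
             n_pure = length(screened$pure_labels),
             counts_by_type = as.list(screened$counts_by_type)),
        file.path(config$out_dir, "screening.json"),
        auto_unbox = TRUE, digits = NA)
  }

  ## ---- evaluation grid -------------------------------------------------
  plan <- feature_subset_plan(lofo = "lofo" %in% config$subsets,
                              spectral = "spectral" %in% config$subsets,
                              stability = "stability" %in% config$subsets)
  report <- run_lofo(feats, classifiers = config$classifiers, plan = plan,
                     folds = config$folds, nn_repeats = config$nn_repeats,
                     seed = config$seed)
  full_entries <- report$entries[grep("^full\\.", names(report$entries))]
  per_type <- lapply(full_entries, `[[`, "metrics")
  names(per_type) <- sub("^full\\.", "", names(full_entries))
  chi <- if (length(full_entries) >= 2)
    chi_square_compare(full_entries) else NULL
  sfl <- single_feature_ld(feats, folds = config$folds,
                           seed = config$seed + 31L)

  if (!is.null(config$out_dir)) {
    utils::write.csv(feats, file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed,
           accuracy = as.data.frame(report$accuracy),
           per_set = report$per_set,
           per_classifier = report$per_classifier,
           per_type = lapply(per_type, as.data.frame),
           single_feature_accuracy =
             lapply(sfl, function(e) e$accuracy),
           chi_square_p = if (!is.null(chi)) chi$p_value else NULL),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
  }

  list(features = feats, screening = screening, report = report,
       per_type = per_type, single_feature = sfl, chi_square = chi,
       config = config)
}
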