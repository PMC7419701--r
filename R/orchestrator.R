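# End-to-end phantom experiments: simulate -> preprocess -> features ->
# train -> predict (100-frame and all-frame) -> task GLM -> meta-ROI ->
# ROC evaluation, under a single validated configuration.

#' Default pipeline configuration
#'
#' The desk-scale phantom study: a 24-cubed 3 mm grid with 6 networks of 4
#' parcels, an 8-subject training cohort and a 12-subject test cohort, two
#' 160-frame rest runs (TR 2.2 s) and one 100-frame five-block task run per
#' subject, the standard denoising chain, a 2-block/8-layer dense classifier
#' on 2x-downsampled correlation volumes, and 101-point/10,000-replicate
#' bootstrap ROC evaluation.
#'
#' @return Nested named list of pipeline parameters.
#' @export
default_config <- function() {
  list(
    seed = 1,
    frames_mode = "both",
    out_dir = NULL,
    simulate = list(
      grid_shape = c(24, 24, 24), voxel_size_mm = 3,
      n_networks = 6, rois_per_network = 4,
      n_train_subjects = 8, n_test_subjects = 12,
      tr = 2.2, n_rest_runs = 2, rest_frames = 160, task_frames = 100,
      snr = 5, drift_amplitude = 1, spikes_per_run = 4, baseline = 1000),
    preprocess = list(
      detrend = TRUE, lowpass_hz = 0.1, smooth_fwhm_mm = 6,
      nuisance = TRUE, global_signal = TRUE, censor_threshold_percent = 0.5),
    features = list(
      downsample = 2, split_fractions = c(0.7, 0.3), min_frames = 30,
      chunk_size = 512, subset_frames = 100),
    classifier = list(
      n_dense_blocks = 2, total_layers = 8, kernel_edges = c(3, 5),
      growth_rate = 6, n_stem_channels = 8, use_batch_norm = TRUE,
      pooling = "average", patience_validations = 3, lr = 0.05,
      momentum = 0.9, batch_size = 32, max_epochs = 30, validate_every = 1,
      stem_pool = TRUE, compression = 0.5, mode_window = 3, box_length = 3),
    task = list(
      block_onsets = c(11, 31, 51, 71, 91), block_duration_frames = 10,
      hrf_shape = 6, hrf_scale = 1, amplitude_broca = 1,
      amplitude_wernicke = 0.4, amplitude_task_general = 1,
      smooth_fwhm_mm = 10),
    metaroi = list(
      peak_z = 8, blob_fwhm_mm = 12, z_threshold = 3.7,
      smooth1_fwhm = 1, smooth2_fwhm = 3, connectivity = 26,
      distractor = TRUE),
    evaluate = list(
      n_grid = 101, n_boot = 10000, alpha = 0.05, negatives = "hemisphere"))
}

#' Validate and complete a pipeline configuration
#'
#' Fills missing entries with defaults, rejects unknown keys, and checks
#' value constraints. All problems are reported together, each with its
#' path into the configuration document.
#'
#' @param config Nested list (e.g. parsed from a YAML file with
#'   [read_config()]); may be partial.
#' @return The completed configuration, invisibly-compatible for
#'   [run_experiment()].
#' @export
validate_config <- function(config = list()) {
  def <- default_config()
  errs <- character(0)
  merge_level <- function(d, u, path) {
    if (!is.list(u)) {
      errs <<- c(errs, sprintf("%s: expected a block, got a value", path))
      return(d)
    }
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      errs <<- c(errs, sprintf("unknown key(s): %s",
                               paste(paste0(path, ".", unknown), collapse = ", ")))
    for (nm in intersect(names(u), names(d))) {
      if (is.list(d[[nm]]) && !is.null(names(d[[nm]]))) {
        d[[nm]] <- merge_level(d[[nm]], u[[nm]], paste0(path, ".", nm))
      } else {
        d[[nm]] <- u[[nm]]
      }
    }
    d
  }
  cfg <- merge_level(def, config, "config")
  check <- function(cond, fmt, ...) if (!isTRUE(cond)) errs <<- c(errs, sprintf(fmt, ...))
  check(is.numeric(cfg$seed) && length(cfg$seed) == 1, "config.seed: one number required")
  check(cfg$frames_mode %in% c("100", "all", "both"),
        "config.frames_mode: must be one of \"100\", \"all\", \"both\" (got \"%s\")",
        as.character(cfg$frames_mode))
  check(cfg$preprocess$smooth_fwhm_mm >= 0,
        "config.preprocess.smooth_fwhm_mm: must be >= 0 (got %g)",
        cfg$preprocess$smooth_fwhm_mm)
  check(is.null(cfg$preprocess$lowpass_hz) || cfg$preprocess$lowpass_hz > 0,
        "config.preprocess.lowpass_hz: must be > 0 or null")
  check(cfg$preprocess$censor_threshold_percent >= 0,
        "config.preprocess.censor_threshold_percent: must be >= 0")
  check(cfg$simulate$snr >= 0, "config.simulate.snr: must be >= 0")
  check(cfg$simulate$n_test_subjects >= 1,
        "config.simulate.n_test_subjects: must be >= 1")
  check(cfg$features$downsample >= 1,
        "config.features.downsample: must be >= 1")
  check(abs(sum(cfg$features$split_fractions) - 1) < 1e-8,
        "config.features.split_fractions: must sum to 1")
  check(cfg$classifier$total_layers >= cfg$classifier$n_dense_blocks + 2,
        "config.classifier.total_layers: too small for %d dense blocks",
        cfg$classifier$n_dense_blocks)
  check(all(cfg$classifier$kernel_edges %% 2 == 1),
        "config.classifier.kernel_edges: must be odd")
  check(cfg$metaroi$z_threshold > 0, "config.metaroi.z_threshold: must be > 0")
  check(cfg$evaluate$n_boot >= 10, "config.evaluate.n_boot: must be >= 10")
  check(cfg$evaluate$alpha > 0 && cfg$evaluate$alpha <= 1,
        "config.evaluate.alpha: must be in (0, 1]")
  check(cfg$evaluate$negatives %in% c("hemisphere", "whole"),
        "config.evaluate.negatives: must be \"hemisphere\" or \"whole\"")
  if (length(errs))
    stopf("invalid configuration:\n  - %s", paste(errs, collapse = "\n  - "))
  cfg
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# deterministic per-run seeds derived from the global seed (kept < 2^31)
derive_seed <- function(seed, ...) {
  parts <- c(...)
  as.integer((seed * 97 + sum(parts * seq_along(parts) * 1009)) %% 2147483629L)
}

# simulate + preprocess the rest runs of one subject, return pooled series
subject_pooled <- function(atlas, protocol, sim, ppcfg, seed, subject, cohort_tag) {
  pps <- lapply(seq_len(sim$n_rest_runs), function(r) {
    rs <- derive_seed(seed, subject, r, if (cohort_tag == "train") 1 else 2)
    spikes <- if (sim$spikes_per_run > 0)
      with_seed(rs + 1L, sort(sample(2:protocol$n_frames_per_run,
                                     sim$spikes_per_run)))
    else integer(0)
    run <- simulate_rest_run(atlas, protocol, snr = sim$snr,
                             drift_amplitude = sim$drift_amplitude,
                             spike_frames = spikes, seed = rs,
                             baseline = sim$baseline)
    preprocess_run(run, ppcfg)
  })
  pool_runs(pps)
}

#' Run the full phantom experiment
#'
#' Executes simulate -> preprocess -> features -> train -> predict (at 100
#' kept frames and at all kept frames) -> task GLM -> meta-analytic ROI
#' construction -> group averaging -> ROC evaluation, and returns the
#' results bundle. Subject maps are averaged arithmetically before a single
#' group-level ROC per (ROI, method) pair is computed.
#'
#' @param config Configuration from [validate_config()] / [default_config()];
#'   partial lists are completed and validated.
#' @param out_dir Optional output directory; when given, group maps are
#'   written as NIfTI-1, ROC results as JSON, and a Markdown report is
#'   produced.
#' @return A list bundle: `atlas`, `model`, `language_rois`, `group_maps`,
#'   `roc` (per ROI and method), `comparisons`, `config`, `provenance`.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL) {
  cfg <- validate_config(config)
  sim <- cfg$simulate
  seed <- cfg$seed
  out_dir <- out_dir %||% cfg$out_dir

  log_stage("simulate", "atlas: %s grid, %d networks x %d parcels",
            paste(sim$grid_shape, collapse = "x"), sim$n_networks,
            sim$rois_per_network)
  atlas <- make_phantom_atlas(sim$grid_shape, sim$n_networks,
                              sim$rois_per_network,
                              seed = derive_seed(seed, 1),
                              voxel_size_mm = sim$voxel_size_mm)
  rest_protocol <- acquisition_protocol(sim$tr, sim$rest_frames,
                                        sim$n_rest_runs, sim$voxel_size_mm,
                                        sim$grid_shape)
  task_protocol <- acquisition_protocol(sim$tr, sim$task_frames, 1,
                                        sim$voxel_size_mm, sim$grid_shape)
  ppcfg <- cfg$preprocess

  log_stage("preprocess", "training cohort: %d subjects x %d rest runs",
            sim$n_train_subjects, sim$n_rest_runs)
  train_cohort <- lapply(seq_len(sim$n_train_subjects), function(s)
    subject_pooled(atlas, rest_protocol, sim, ppcfg, seed, s, "train"))

  log_stage("features", "building training examples (downsample %d)",
            cfg$features$downsample)
  examples <- build_training_examples(train_cohort, atlas,
                                      split_fractions = cfg$features$split_fractions,
                                      seed = derive_seed(seed, 2),
                                      downsample = cfg$features$downsample,
                                      min_frames = cfg$features$min_frames)
  rm(train_cohort)

  log_stage("train", "%d examples (%s input)", nrow(examples$volumes),
            paste(examples$input_shape, collapse = "x"))
  ccfg <- cfg$classifier
  net_config <- densenet3d_config(
    n_dense_blocks = ccfg$n_dense_blocks, total_layers = ccfg$total_layers,
    kernel_edges = ccfg$kernel_edges, growth_rate = ccfg$growth_rate,
    n_stem_channels = ccfg$n_stem_channels,
    use_batch_norm = ccfg$use_batch_norm, pooling = ccfg$pooling,
    n_classes = sim$n_networks,
    patience_validations = ccfg$patience_validations,
    split_fractions = cfg$features$split_fractions,
    stem_pool = ccfg$stem_pool, compression = ccfg$compression,
    lr = ccfg$lr, momentum = ccfg$momentum, batch_size = ccfg$batch_size,
    max_epochs = ccfg$max_epochs, validate_every = ccfg$validate_every)
  model <- rsn_densenet(examples, net_config, seed = derive_seed(seed, 3))
  log_stage("train", "validation accuracy %.3f (%s)",
            model$history$best_accuracy, model$history$stop_reason)

  design <- glm_design(cfg$task$block_onsets, cfg$task$block_duration_frames,
                       sim$task_frames, cfg$task$hrf_shape, cfg$task$hrf_scale)
  Xtask <- build_design_matrix(design, task_protocol)
  lang <- atlas$language_parcels
  task_general <- which(atlas$network_of_roi != atlas$language_network)[1]

  modes <- switch(cfg$frames_mode, "100" = "100", "all" = "all",
                  both = c("all", "100"))
  lang_maps <- list(); task_maps <- list()
  for (s in seq_len(sim$n_test_subjects)) {
    log_stage("predict", "test subject %d/%d", s, sim$n_test_subjects)
    pooled <- subject_pooled(atlas, rest_protocol, sim, ppcfg, seed, s, "test")
    for (mode in modes) {
      pm <- if (mode == "100") subset_frames(pooled, cfg$features$subset_frames)
            else pooled
      stream <- build_inference_examples(pm, mask = atlas$brain_mask,
                                         chunk_size = cfg$features$chunk_size,
                                         downsample = cfg$features$downsample)
      pv <- predict_volume(model, stream, atlas$brain_mask)
      pv <- smooth_probability(pv, ccfg$mode_window, ccfg$box_length)
      lang_maps[[mode]][[s]] <- pv$probs[, , , atlas$language_network]
    }
    rm(pooled)
    # task comparator
    ts <- derive_seed(seed, s, 999)
    spikes <- if (sim$spikes_per_run > 0)
      with_seed(ts + 1L, sort(sample(2:sim$task_frames,
                                     max(1L, sim$spikes_per_run %/% 2L))))
    else integer(0)
    trun <- simulate_task_run(atlas, task_protocol, design,
                              responsive_parcels = c(lang, task_general),
                              amplitude = c(cfg$task$amplitude_broca,
                                            cfg$task$amplitude_wernicke,
                                            cfg$task$amplitude_task_general),
                              snr = sim$snr,
                              drift_amplitude = sim$drift_amplitude,
                              spike_frames = spikes, seed = ts,
                              baseline = sim$baseline)
    pp <- preprocess_run(trun, ppcfg)
    amap <- fit_glm(pp$run, Xtask, pp$censor)
    amap <- postprocess_activation(amap, cfg$task$smooth_fwhm_mm,
                                   atlas$brain_mask)
    task_maps[[s]] <- amap$tstat
  }

  group_maps <- list()
  for (mode in modes)
    group_maps[[paste0("cnn-", if (mode == "all") "320" else "100")]] <-
      group_average(lang_maps[[mode]],
                    paste0("cnn-", if (mode == "all") "320" else "100"))
  group_maps[["task"]] <- group_average(task_maps, "task")

  log_stage("metaroi", "building ground-truth ROIs (Z > %g)",
            cfg$metaroi$z_threshold)
  meta <- simulate_meta_map(atlas, peak_z = cfg$metaroi$peak_z,
                            blob_fwhm_mm = cfg$metaroi$blob_fwhm_mm,
                            seed = derive_seed(seed, 4),
                            distractor = cfg$metaroi$distractor)
  rois <- build_language_rois(meta, z_threshold = cfg$metaroi$z_threshold,
                              smooth1_fwhm = cfg$metaroi$smooth1_fwhm,
                              smooth2_fwhm = cfg$metaroi$smooth2_fwhm,
                              connectivity = cfg$metaroi$connectivity)
  group_maps[["meta-truth"]] <- group_average(
    list(array(as.numeric(rois$broca_mask | rois$wernicke_mask),
               dim(rois$broca_mask))), "meta-truth")

  log_stage("evaluate", "%d-point grid, %d bootstrap replicates",
            cfg$evaluate$n_grid, cfg$evaluate$n_boot)
  hemi <- if (cfg$evaluate$negatives == "hemisphere") "left" else "both"
  truths <- list(broca = rois$broca_mask, wernicke = rois$wernicke_mask)
  roc <- list()
  for (roi in names(truths)) {
    other <- truths[[setdiff(names(truths), roi)]]
    emask <- make_eval_mask(atlas$brain_mask, exclude = other, hemisphere = hemi)
    roc[[roi]] <- list()
    for (mm in setdiff(names(group_maps), "meta-truth")) {
      roc[[roi]][[mm]] <- roc_curve_vertical(
        group_maps[[mm]], truths[[roi]], emask,
        n_grid = cfg$evaluate$n_grid, n_boot = cfg$evaluate$n_boot,
        alpha = cfg$evaluate$alpha,
        seed = derive_seed(seed, 5, match(roi, names(truths)),
                           match(mm, names(group_maps))),
        source_tag = mm, truth_tag = roi)
    }
  }
  comparisons <- list()
  if (all(c("cnn-320", "cnn-100") %in% names(group_maps)))
    for (roi in names(truths))
      comparisons[[roi]] <- compare_methods(roc[[roi]][["cnn-320"]],
                                            roc[[roi]][["cnn-100"]])

  bundle <- list(atlas = atlas, model = model, language_rois = rois,
                 meta_map = meta, group_maps = group_maps, roc = roc,
                 comparisons = comparisons, config = cfg,
                 provenance = list(seed = seed,
                                   config_hash = config_hash(cfg),
                                   package_version =
                                     as.character(utils::packageVersion("langmap"))))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
  sum(utf8ToInt(as.character(s)) * (seq_len(nchar(as.character(s))) %% 97 + 1)) %% 1e9
}

# serialize a results bundle: NIfTI group maps, JSON ROC results, report
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vox <- bundle$config$simulate$voxel_size_mm
  for (nm in names(bundle$group_maps))
    write_volume_nifti(bundle$group_maps[[nm]]$mean,
                       file.path(out_dir, paste0("group_", nm, ".nii.gz")), vox)
  write_volume_nifti(array(as.numeric(bundle$language_rois$broca_mask),
                           dim(bundle$language_rois$broca_mask)),
                     file.path(out_dir, "roi_broca.nii.gz"), vox)
  write_volume_nifti(array(as.numeric(bundle$language_rois$wernicke_mask),
                           dim(bundle$language_rois$wernicke_mask)),
                     file.path(out_dir, "roi_wernicke.nii.gz"), vox)
  res <- list(provenance = bundle$provenance,
              roc = lapply(bundle$roc, function(per_roi)
                lapply(per_roi, function(r)
                  list(source = r$source, truth = r$truth_tag, auc = r$auc,
                       auc_ci = r$auc_ci, n_boot = r$n_boot, alpha = r$alpha,
                       fpr_grid = r$fpr_grid, tpr_mean = r$tpr_mean,
                       tpr_lo = r$tpr_lo, tpr_hi = r$tpr_hi))),
              comparisons = lapply(bundle$comparisons, function(cmp)
                list(auc_diff = cmp$auc_diff, ci_overlap = cmp$ci_overlap)))
  jsonlite::write_json(res, file.path(out_dir, "roc_results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  rep <- c("# Phantom language-mapping experiment", "",
           sprintf("- seed: %d", bundle$provenance$seed),
           sprintf("- validation accuracy: %.3f",
                   bundle$model$history$best_accuracy), "")
  for (roi in names(bundle$roc))
    for (mm in names(bundle$roc[[roi]])) {
      r <- bundle$roc[[roi]][[mm]]
      rep <- c(rep, sprintf("- %s / %s: AUC %.4f [%.4f, %.4f]",
                            roi, mm, r$auc, r$auc_ci[1], r$auc_ci[2]))
    }
  writeLines(rep, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
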