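## End-to-end desk-scale workflow: generate phantoms, train stage-specific
## parameter networks, enhance, compare enhancers, classify, and render a
## Grad-CAM overlay -- writing every artifact plus a manifest of seeds,
## configuration and file hashes so a rerun with the same configuration
## reproduces the hashes of all deterministic artifacts.

#' Workflow configuration
#'
#' Desk-scale defaults; the full-scale analog (250 epochs, k = 25,
#' 512 x 512 inputs) is a matter of raising these values.
#'
#' @param n_per_stage phantoms per stage.
#' @param stages stage labels to include.
#' @param image_size phantom side length in pixels.
#' @param epochs training epochs per stage-specific network.
#' @param k cross-validation folds.
#' @param seed master seed; all stage seeds derive from it.
#' @param net_cfg a [param_net_config].
#' @param train_stages stages that get their own trained network.
#' @param window a [window_config].
#' @param weights a [loss_weights].
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_per_stage = 10, stages = STAGES, image_size = 64,
                       epochs = 5, k = 5, seed = 1L,
                       net_cfg = param_net_config(
                         conv_channels = c(8, 12, 16, 24, 32),
                         fc_widths = c(128, 64, 16, 3),
                         dropout_rate = 0.2, pooled_size = 2,
                         input_size = image_size, seed = seed),
                       train_stages = c("chronic"),
                       window = window_config(), weights = loss_weights()) {
  structure(list(n_per_stage = n_per_stage, stages = stages,
                 image_size = image_size, epochs = epochs, k = k,
                 seed = as.integer(seed), net_cfg = net_cfg,
                 train_stages = train_stages, window = window,
                 weights = weights),
            class = "run_config")
}

wf_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full synthetic workflow
#'
#' Executes generate -> preprocess -> optimize -> enhance -> compare ->
#' classify -> interpret on synthetic phantoms, writing artifacts under
#' `out_dir` and a `manifest.json` recording the configuration, all seeds,
#' and an MD5 hash of every artifact.  With `resume = TRUE`, stages whose
#' artifacts already exist on disk are skipped and only missing
#' (downstream) artifacts are regenerated.
#'
#' @param cfg a [run_config].
#' @param out_dir output directory.
#' @param resume skip stages whose outputs already exist.
#' @param verbose log per-stage progress.
#' @return invisibly, the manifest list.
#' @export
run_workflow <- function(cfg = run_config(), out_dir, resume = FALSE,
                         verbose = FALSE) {
  if (!inherits(cfg, "run_config")) stop("`cfg` must be a run_config",
                                         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    phantoms = file.path(out_dir, "phantoms"),
    nets = file.path(out_dir, "nets"),
    params = file.path(out_dir, "stage_params.csv"),
    comparison = file.path(out_dir, "enhancer_comparison.csv"),
    classification = file.path(out_dir, "classification.csv"),
    gradcam = file.path(out_dir, "gradcam_chronic.png"),
    manifest = file.path(out_dir, "manifest.json"))

  ## generate (always rebuilt in memory -- cheap and needed downstream)
  wf_log(verbose, "phantom", "generating %d samples/stage",
         cfg$n_per_stage)
  samples <- make_dataset(cfg$n_per_stage, cfg$stages,
                          base_seed = derive_seed(cfg$seed, "data"),
                          image_size = cfg$image_size)
  if (!resume || !dir.exists(paths$phantoms)) {
    dir.create(paths$phantoms, showWarnings = FALSE)
    for (i in seq_along(samples))
      write_phantom(samples[[i]], paths$phantoms,
                    sprintf("%s_%03d", samples[[i]]$stage, i), cfg$window)
  }

  ## optimize: stage-specific networks
  nets <- list()
  dir.create(paths$nets, showWarnings = FALSE)
  for (st in cfg$train_stages) {
    ck <- file.path(paths$nets, paste0(st, ".rds"))
    if (resume && file.exists(ck)) {
      nets[[st]] <- load_param_net(ck)
      wf_log(verbose, "optimize", "resumed %s net", st)
      next
    }
    wf_log(verbose, "optimize", "training %s net (%d epochs)", st,
           cfg$epochs)
    ncfg <- cfg$net_cfg
    ncfg$seed <- derive_seed(cfg$seed, "net", st)
    tr <- train_param_net(
      samples, build_param_net(ncfg),
      train_config(epochs = cfg$epochs, batch_size = 8,
                   weights = cfg$weights, stage_filter = st,
                   seed = derive_seed(cfg$seed, "train", st)),
      window = cfg$window)
    nets[[st]] <- tr$net
    save_param_net(tr$net, ck)
    utils::write.csv(tr$history,
                     file.path(paths$nets, paste0(st, "_history.csv")),
                     row.names = FALSE)
  }

  ## stage parameter summary (trained stages only)
  if (!resume || !file.exists(paths$params)) {
    st_samples <- Filter(function(s) s$stage %in% names(nets), samples)
    summ <- summarize_stage_params(nets, st_samples, cfg$window)
    utils::write.csv(summ, paths$params, row.names = FALSE)
  }

  ## compare: six enhancers, before/after static LT
  if (!resume || !file.exists(paths$comparison)) {
    wf_log(verbose, "compare", "paired t-tests over six enhancers")
    cmp <- enhancement_comparison(samples, window = cfg$window)
    utils::write.csv(cmp, paths$comparison, row.names = FALSE)
  }

  ## classify: static vs network parameter sources
  if (!resume || !file.exists(paths$classification)) {
    wf_log(verbose, "classify", "stage-vs-normal ablation, k=%d", cfg$k)
    backbone <- build_param_net(
      within_cfg_seed(cfg$net_cfg, derive_seed(cfg$seed, "backbone")))
    abl_samples <- Filter(function(s)
      s$stage %in% c(names(nets), "normal"), samples)
    abl <- enhancement_ablation(
      abl_samples,
      param_sources = list(static = enhancement_params(1.25, 0, 1.0),
                           network = nets),
      backbone = backbone, classifiers = c("LR", "SVM", "RF"),
      k = cfg$k, seed = derive_seed(cfg$seed, "classify"),
      window = cfg$window)
    utils::write.csv(abl, paths$classification, row.names = FALSE)
  }

  ## interpret: Grad-CAM overlay for one chronic phantom
  if (!resume || !file.exists(paths$gradcam)) {
    wf_log(verbose, "interpret", "Grad-CAM overlay")
    cls_samples <- Filter(function(s)
      s$stage %in% c("chronic", "normal"), samples)
    imgs8 <- lapply(cls_samples, function(s)
      window_uint8(s$image, cfg$window))
    labels <- vapply(cls_samples, function(s) s$stage, "")
    clf <- train_image_classifier(
      imgs8, labels,
      within_cfg_seed(cfg$net_cfg, derive_seed(cfg$seed, "clf")),
      epochs = cfg$epochs, batch_size = 8,
      seed = derive_seed(cfg$seed, "clf-fit"))
    target <- which(labels == "chronic")[1]
    cam <- gradcam(clf, imgs8[[target]], "chronic")
    write_gradcam_png(cam, imgs8[[target]], paths$gradcam)
  }

  ## manifest
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("deepclahe")),
    seed = cfg$seed,
    config = list(n_per_stage = cfg$n_per_stage, stages = cfg$stages,
                  image_size = cfg$image_size, epochs = cfg$epochs,
                  k = cfg$k, train_stages = cfg$train_stages,
                  window = unclass(cfg$window),
                  weights = unclass(cfg$weights)),
    artifacts = hashes)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

within_cfg_seed <- function(ncfg, seed) {
  ncfg$seed <- as.integer(seed)
  ncfg
}
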