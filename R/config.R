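#' Read a pipeline configuration file
#'
#' A single structured YAML file with sections `data`, `preprocessing`,
#' `patches`, `augmentation`, `model`, `training` and `evaluation` is
#' mapped onto the package's configuration objects; missing keys take the
#' constructors' defaults.  The shipped reference configuration
#' (`system.file("extdata", "kits19_reference.yaml", package = "voxseg")`)
#' documents a full multi-class abdominal CT setup.
#'
#' @param path YAML file path.
#' @return list with elements `data` (interface name + root), `preproc`,
#'   `patch`, `augment`, `model` ([unetConfig()]), `architecture`,
#'   `batch`, `train`, `evaluation` (mode + parameters) and `raw` (the
#'   parsed YAML).
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path))
    voxsegError("ioError", "config file not found: '%s'", path)
  raw <- yaml::read_yaml(path)
  g <- function(section, key, default = NULL) {
    v <- raw[[section]][[key]]
    if (is.null(v)) default else v
  }
  pre <- preprocSpec(
    clipRange = if (!is.null(g("preprocessing", "clip_lo")))
      c(g("preprocessing", "clip_lo"), g("preprocessing", "clip_hi")),
    normalization = g("preprocessing", "normalization", "zscore"),
    targetSpacing = g("preprocessing", "target_spacing"),
    nClasses = g("preprocessing", "n_classes", 2L),
    interpolation = g("preprocessing", "interpolation", "cubic"))
  patch <- patchConfig(
    patchShape = unlist(g("patches", "patch_shape", c(16L, 16L, 16L))),
    overlap = unlist(g("patches", "overlap")),
    analysis = g("patches", "analysis", "patchwise-grid"),
    skipBlanks = g("patches", "skip_blanks", TRUE),
    cropsPerSample = g("patches", "crops_per_sample", 1L))
  augRaw <- raw[["augmentation"]]
  aug <- if (is.null(augRaw)) augmentSpecOff() else do.call(augmentSpec, {
    map <- c(p_mirror = "pMirror", p_rotate = "pRotate",
             p_scale = "pScale", p_elastic = "pElastic",
             p_brightness = "pBrightness", p_contrast = "pContrast",
             p_gamma = "pGamma", p_noise = "pNoise",
             rotation_range = "rotationRange", scale_range = "scaleRange",
             elastic_amplitude = "elasticAmplitude",
             elastic_sigma = "elasticSigma",
             brightness_range = "brightnessRange",
             contrast_range = "contrastRange", gamma_range = "gammaRange",
             noise_sd_range = "noiseSdRange")
    args <- augRaw[names(augRaw) %in% names(map)]
    names(args) <- map[names(args)]
    lapply(args, unlist)
  })
  model <- unetConfig(
    nDims = g("model", "n_dims", 3L),
    inChannels = g("model", "in_channels", 1L),
    nClasses = g("model", "n_classes", g("preprocessing", "n_classes", 2L)),
    baseFilters = g("model", "base_filters", 32L),
    depth = g("model", "depth", 4L),
    batchNorm = g("model", "batch_norm", FALSE),
    dropout = g("model", "dropout", 0))
  batch <- batchPlan(
    batchSize = g("training", "batch_size", 2L),
    mode = g("training", "batch_mode", "on-the-fly"),
    cacheDir = g("training", "cache_dir"))
  train <- trainSpec(
    epochs = g("training", "epochs", 10L),
    learningRate = g("training", "learning_rate", 1e-4),
    loss = g("training", "loss", "tversky"),
    monitorMetrics = unlist(g("training", "monitor_metrics",
                              c("dice_soft", "dice_classwise"))),
    seed = g("training", "seed", 1L),
    logFile = g("training", "log_file"))
  list(data = list(interface = g("data", "interface", "nifti"),
                   root = g("data", "root", ".")),
       preproc = pre, patch = patch, augment = aug, model = model,
       architecture = g("model", "architecture", "unet"),
       batch = batch, train = train,
       evaluation = list(mode = g("evaluation", "mode", "kfold"),
                         k = g("evaluation", "k", 3L),
                         fraction = g("evaluation", "fraction", 0.8),
                         seed = g("evaluation", "seed", 1L)),
       raw = raw)
}
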