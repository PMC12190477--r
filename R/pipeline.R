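#' Configuration for a full pipeline run
#'
#' Bundles everything a run needs: either a synthetic plate (layout + scene
#' spec + per-condition overrides) or a manifest of images on disk, the
#' segmentation configuration, the metric parameters, and the output
#' directory. The configuration is fully serializable; its hash is recorded
#' in every output so results can be traced to the exact parameters.
#'
#' @param output_dir directory for the result bundle.
#' @param layout plate layout data frame (simulation mode).
#' @param scene base [scene_spec()] (simulation mode).
#' @param overrides per-condition scene overrides (see [generate_plate()]).
#' @param input_manifest path to a plate manifest YAML to analyze images from
#'   disk instead of simulating; `structure_mode` must then be explicit.
#' @param segmentation a [segmentation_config()].
#' @param structure_mode `"auto"` (clustered conditions -> focus, otherwise
#'   punctum; simulation mode only), `"punctum"` or `"focus"`.
#' @param positivity_threshold positivity ratio threshold (strict), default
#'   1.25.
#' @param dilation_radius disc radius for the positivity region, pixels.
#' @param min_structure_pixels dispersion qualification gate, pixels.
#' @param pool_sites see [aggregate_pearson()].
#' @param seed overrides the scene spec's base seed when not NULL.
#' @return An object of class `run_config` with a `config_hash` attribute
#'   available via [config_hash()].
#' @export
run_config <- function(output_dir,
                       layout = plate_layout(c("dispersed", "clustered")),
                       scene = scene_spec(),
                       overrides = list(dispersed = list(pattern = "dispersed"),
                                        clustered = list(pattern = "clustered")),
                       input_manifest = NULL,
                       segmentation = segmentation_config(),
                       structure_mode = c("auto", "punctum", "focus"),
                       positivity_threshold = 1.25,
                       dilation_radius = 5,
                       min_structure_pixels = 5,
                       pool_sites = FALSE,
                       seed = NULL) {
  structure_mode <- match.arg(structure_mode)
  if (!is.null(seed)) scene$seed <- as.integer(seed)
  if (is.null(input_manifest)) {
    validate_layout(layout)
    validate_scene_spec(scene)
  } else {
    if (!file.exists(input_manifest))
      stop("input_manifest does not exist: ", input_manifest)
    mf <- yaml::read_yaml(input_manifest)
    if (is.null(mf$channels$primary))
      stop("input manifest lacks a primary channel mapping")
    if (structure_mode == "auto")
      stop("structure_mode must be 'punctum' or 'focus' when analyzing images from disk")
  }
  validate_segmentation_config(segmentation)
  if (positivity_threshold <= 0) stop("positivity_threshold must be > 0")
  if (dilation_radius < 1) stop("dilation_radius must be >= 1")
  if (min_structure_pixels < 1) stop("min_structure_pixels must be >= 1")
  cfg <- list(output_dir = output_dir, layout = layout, scene = scene,
              overrides = overrides, input_manifest = input_manifest,
              segmentation = segmentation, structure_mode = structure_mode,
              positivity_threshold = positivity_threshold,
              dilation_radius = dilation_radius,
              min_structure_pixels = min_structure_pixels,
              pool_sites = pool_sites)
  class(cfg) <- "run_config"
  cfg
}

#' Hash of a run configuration
#'
#' MD5 over the serialized configuration (excluding the output directory, so
#' the same analysis written elsewhere hashes identically).
#'
#' @param config a [run_config()].
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "run_config"))
  core <- unclass(config)
  core$output_dir <- NULL
  hash_of(core)
}

structure_mode_for <- function(config, condition) {
  if (config$structure_mode != "auto") return(config$structure_mode)
  ov <- config$overrides[[condition]]
  pat <- if (!is.null(ov$pattern)) ov$pattern else config$scene$pattern
  if (identical(pat, "clustered")) "focus" else "punctum"
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> background subtraction -> cell
#' segmentation -> structure segmentation -> metrics (Pearson, positivity,
#' dispersion) -> hierarchical aggregation, and writes all result tables plus
#' a machine-readable run manifest with per-file checksums. Outputs are a
#' pure function of the configuration: rerunning the same config reproduces
#' every file byte-identically.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-field progress messages.
#' @return Invisibly, a list with all result tables, the per-field label maps
#'   (`cells`, `structures`), the output `paths` and the run `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  if (is.null(config$input_manifest)) {
    scenes <- generate_plate(config$layout, config$scene, config$overrides)
    fovs <- lapply(scenes, `[[`, "fov")
  } else {
    fovs <- load_plate(config$input_manifest)
    scenes <- NULL
  }
  pearson <- list(); struct_tab <- list(); disp <- list(); qc <- list()
  seg_out <- list()
  for (nm in names(fovs)) {
    fv <- fovs[[nm]]
    res <- tryCatch({
      sub <- lapply(fv$channels, subtract_background, config = config$segmentation)
      fv2 <- field_of_view(sub, fv$condition, fv$well, fv$site)
      cells <- segment_cells(fv2, config$segmentation)
      eq <- equalize_intensity(fv2$channels$primary, config$segmentation)
      mode <- structure_mode_for(config, fv$condition)
      smap <- segment_structures(fv2$channels$primary, eq, cells, mode,
                                 config$segmentation)
      st <- if (!is.null(fv2$channels$secondary))
        score_structure_positivity(fv2, cells, smap,
                                   threshold = config$positivity_threshold,
                                   dilation_radius = config$dilation_radius)
        else NULL
      pr <- if (!is.null(fv2$channels$secondary))
        withCallingHandlers(pearson_per_cell(fv2, cells),
                            warning = function(w) invokeRestart("muffleWarning"))
        else NULL
      dp <- dispersion_profiles(fv2, cells, smap, config$min_structure_pixels)
      list(fv2 = fv2, cells = cells, smap = smap, st = st, pr = pr, dp = dp,
           mode = mode)
    }, error = function(e) {
      stop(sprintf("pipeline stage failed for (%s): %s", nm, conditionMessage(e)),
           call. = FALSE)
    })
    if (!quiet)
      message(sprintf("[%s] cells=%d structures=%d mode=%s", nm,
                      max(res$cells), max(res$smap$labels), res$mode))
    seg_out[[nm]] <- list(cells = res$cells, structures = res$smap)
    if (!is.null(res$pr)) pearson[[nm]] <- res$pr
    if (!is.null(res$st)) struct_tab[[nm]] <- res$st
    disp[[nm]] <- res$dp
    qc[[nm]] <- data.frame(
      condition = fv$condition, well = fv$well, site = fv$site,
      n_cells = max(res$cells), n_structures = max(res$smap$labels),
      n_cells_with_profile = if (nrow(res$dp)) length(unique(res$dp$cell)) else 0L,
      n_unscorable = if (!is.null(res$st)) sum(!res$st$scorable) else NA_integer_)
  }
  tables <- list(qc = do.call(rbind, qc))
  if (length(pearson)) {
    prs <- do.call(rbind, pearson); rownames(prs) <- NULL
    agg <- aggregate_pearson(prs, pool_sites = config$pool_sites)
    tables$pearson_cell <- prs
    tables$pearson_well <- agg$well
    tables$pearson_condition <- agg$condition
  }
  if (length(struct_tab)) {
    stt <- do.call(rbind, struct_tab); rownames(stt) <- NULL
    tables$structures <- stt
    pf <- withCallingHandlers(positivity_fractions(stt),
                              warning = function(w) invokeRestart("muffleWarning"))
    tables$positivity_site <- pf$site
    tables$positivity_well <- pf$well
    tables$positivity_condition <- pf$condition
  }
  dps <- do.call(rbind, disp); rownames(dps) <- NULL
  if (nrow(dps)) {
    ad <- aggregate_dispersion(dps)
    tables$dispersion_cell <- dps
    tables$dispersion_well <- ad$well
    tables$dispersion_condition <- ad$condition
  }
  rownames(tables$qc) <- NULL

  paths <- write_results(tables, config$output_dir,
                         meta = list(config_hash = hash))
  manifest <- list(config_hash = hash,
                   package_version = as.character(packageVersion("focusq")),
                   files = as.list(setNames(unname(tools::md5sum(paths)),
                                            basename(paths))))
  mpath <- file.path(config$output_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(tables = tables, segmentation = seg_out, scenes = scenes,
                 paths = c(paths, run_manifest = mpath), manifest = manifest))
}
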