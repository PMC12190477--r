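#' Segmentation configuration
#'
#' Parameters for background subtraction, single-cell segmentation and
#' structure (punctum/focus) segmentation. Thresholds are manual and must be
#' held constant across images and conditions within a run; the defaults are
#' tuned to the synthetic scene generator's default intensity model and are
#' expected to need adjustment for real microscope data.
#'
#' @param background_radius radius (pixels) of the disc used by the
#'   morphological-opening background estimate; should be much larger than a
#'   structure and no larger than a cell.
#' @param cell_intensity_threshold intensity above which a (background
#'   subtracted) primary-channel pixel counts as cell foreground.
#' @param cell_min_area minimum cell area in pixels ("filtered by size").
#' @param cell_max_area optional maximum cell area (Inf disables; large debris
#'   filter).
#' @param watershed_blur_sigma Gaussian sigma (pixels) of the blur applied
#'   before watershed single-cell splitting.
#' @param watershed_tolerance minimum intensity depth separating two watershed
#'   objects; larger values merge shallow maxima (EBImage convention).
#' @param use_nuclear_channel_in_watershed if TRUE, the watershed surface is
#'   the blurred primary + nuclear merge and nuclei seed the cells.
#' @param nuclear_seed_threshold intensity threshold defining nuclear seeds
#'   when the merge option is on.
#' @param nuclear_seed_min_area minimum nuclear seed area in pixels.
#' @param equalization_blur_sigma Gaussian sigma (pixels) of the blur used by
#'   blur-divide equalization; should be at least a cell radius so details
#'   smaller than a cell are removed.
#' @param raw_bright_threshold intensity threshold on the background-subtracted
#'   image for structure pixels.
#' @param equalized_bright_threshold ratio threshold on the equalized image
#'   for structure pixels (dimensionless).
#' @param min_area_focus minimum focus area, pixels (default 35).
#' @param min_area_punctum minimum punctum area, pixels (default 5).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(background_radius = 25,
                                cell_intensity_threshold = 27,
                                cell_min_area = 300,
                                cell_max_area = Inf,
                                watershed_blur_sigma = 10,
                                watershed_tolerance = 50,
                                use_nuclear_channel_in_watershed = FALSE,
                                nuclear_seed_threshold = 75,
                                nuclear_seed_min_area = 25,
                                equalization_blur_sigma = 25,
                                raw_bright_threshold = 100,
                                equalized_bright_threshold = 1.5,
                                min_area_focus = 35,
                                min_area_punctum = 5) {
  cfg <- list(background_radius = background_radius,
              cell_intensity_threshold = cell_intensity_threshold,
              cell_min_area = cell_min_area, cell_max_area = cell_max_area,
              watershed_blur_sigma = watershed_blur_sigma,
              watershed_tolerance = watershed_tolerance,
              use_nuclear_channel_in_watershed = use_nuclear_channel_in_watershed,
              nuclear_seed_threshold = nuclear_seed_threshold,
              nuclear_seed_min_area = nuclear_seed_min_area,
              equalization_blur_sigma = equalization_blur_sigma,
              raw_bright_threshold = raw_bright_threshold,
              equalized_bright_threshold = equalized_bright_threshold,
              min_area_focus = min_area_focus,
              min_area_punctum = min_area_punctum)
  class(cfg) <- "segmentation_config"
  validate_segmentation_config(cfg)
  cfg
}

validate_segmentation_config <- function(cfg) {
  stopifnot(inherits(cfg, "segmentation_config"))
  with(cfg, {
    if (!(min_area_focus > min_area_punctum && min_area_punctum > 0))
      stop("min_area_focus must exceed min_area_punctum, both > 0")
    if (background_radius <= 0 || watershed_blur_sigma <= 0 ||
        equalization_blur_sigma <= 0)
      stop("radii and blur sigmas must be > 0")
    if (cell_min_area <= 0) stop("cell_min_area must be > 0")
  })
  invisible(cfg)
}

#' Subtract background from a channel
#'
#' Estimates the slowly-varying background by grayscale morphological opening
#' with a disc much larger than any structure of interest and subtracts it,
#' clipping at 0. Flat regions map to ~0 while the amplitude of spots smaller
#' than the disc is preserved.
#'
#' @param channel nonnegative 2D intensity matrix.
#' @param config a [segmentation_config()].
#' @return Background-subtracted matrix (nonnegative).
#' @export
subtract_background <- function(channel, config = segmentation_config()) {
  if (!all(is.finite(channel))) stop("channel contains non-finite pixels")
  if (any(channel < 0)) stop("channel must be nonnegative")
  bg <- gray_opening(channel, config$background_radius)
  pmax(channel - bg, 0)
}

#' Blur-divide intensity equalization
#'
#' Divides the (background-subtracted) image by a heavily blurred copy of
#' itself. The blur removes details smaller than a cell, so the quotient has
#' comparable intensities between dim and bright cells: a spot of fixed
#' relative contrast produces the same equalized peak regardless of the cell's
#' absolute brightness. A small epsilon (1e-6 of the image maximum) guards the
#' division; pixels whose blurred value falls below it map to 0.
#'
#' @param channel background-subtracted 2D intensity matrix.
#' @param config a [segmentation_config()]; uses `equalization_blur_sigma`.
#' @return Dimensionless ratio matrix, same shape.
#' @export
equalize_intensity <- function(channel, config = segmentation_config()) {
  if (!all(is.finite(channel))) stop("channel contains non-finite pixels")
  mx <- max(channel)
  if (mx <= 0) return(channel * 0)
  b <- gauss_blur(channel, config$equalization_blur_sigma)
  eps <- 1e-6 * mx
  out <- channel / (b + eps)
  out[b < eps] <- 0
  out
}

#' Segment single cells
#'
#' Cell foreground is taken from the background-subtracted primary channel by
#' a manual intensity threshold, holes are filled, and components smaller than
#' `cell_min_area` (or larger than `cell_max_area`) are removed. The
#' foreground is then partitioned into single cells by a watershed on the
#' Gaussian-blurred primary image; with
#' `use_nuclear_channel_in_watershed = TRUE` the surface is the blurred
#' primary + nuclear merge and thresholded nuclei seed the cells (this is the
#' variant that separates touching cells with distinct nuclei). Labels are
#' consecutive positive integers in pixel scan order; 0 is background.
#'
#' @param fov a [field_of_view()] whose channels are background-subtracted.
#' @param config a [segmentation_config()].
#' @return Integer label matrix (a cell label map).
#' @export
segment_cells <- function(fov, config = segmentation_config()) {
  stopifnot(inherits(fov, "fov"))
  primary <- fov$channels$primary
  fg <- primary > config$cell_intensity_threshold
  if (!any(fg)) return(matrix(0L, nrow(primary), ncol(primary)))
  fg <- as.matrix(EBImage::fillHull(fg * 1)) > 0
  lab <- label_components(fg, 8L)
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < config$cell_min_area | areas > config$cell_max_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  fg <- lab > 0L
  if (!any(fg)) return(matrix(0L, nrow(primary), ncol(primary)))

  if (isTRUE(config$use_nuclear_channel_in_watershed)) {
    nuc <- fov$channels$nuclear
    if (is.null(nuc))
      stop("nuclear channel required when use_nuclear_channel_in_watershed = TRUE")
    surface <- gauss_blur(primary + nuc, config$watershed_blur_sigma)
    seeds <- label_components(nuc > config$nuclear_seed_threshold, 8L)
    sa <- tabulate(seeds[seeds > 0L])
    small <- which(sa < config$nuclear_seed_min_area)
    if (length(small)) seeds[seeds %in% small] <- 0L
    if (!any(seeds > 0L))
      stop("no nuclear seeds above nuclear_seed_threshold")
    lab2 <- as.matrix(EBImage::propagate(surface, seeds, mask = fg))
  } else {
    surface <- gauss_blur(primary, config$watershed_blur_sigma)
    lab2 <- as.matrix(EBImage::watershed(surface * fg,
                                         tolerance = config$watershed_tolerance,
                                         ext = 1))
  }
  lab2 <- matrix(as.integer(round(lab2)), nrow(primary), ncol(primary))
  # size filter again: watershed splitting can leave sub-minimum fragments
  areas <- tabulate(lab2[lab2 > 0L])
  drop <- which(areas < config$cell_min_area)
  if (length(drop)) lab2[lab2 %in% drop] <- 0L
  relabel_consecutive(lab2)
}

#' Segment puncta or foci within cells
#'
#' Structure pixels are those bright in both the background-subtracted image
#' (`raw_bright_threshold`) and the equalized image
#' (`equalized_bright_threshold`); the two binary masks are multiplied to keep
#' pixels common to both, then multiplied by the cell mask so structures
#' outside cells are discarded. Connected components (8-connectivity) smaller
#' than the mode's minimum area (35 px for foci, 5 px for puncta) are removed
#' as noise. Each surviving structure is assigned to the cell containing the
#' majority of its pixels (ties to the lower cell id).
#'
#' @param channel background-subtracted primary channel.
#' @param equalized output of [equalize_intensity()] for the same channel.
#' @param cells cell label map from [segment_cells()].
#' @param mode `"punctum"` or `"focus"`; selects the minimum area.
#' @param config a [segmentation_config()].
#' @return An object of class `structure_map`: `labels` (integer matrix),
#'   `mode`, and `owner` (integer vector mapping structure label -> cell id).
#' @export
segment_structures <- function(channel, equalized, cells,
                               mode = c("punctum", "focus"),
                               config = segmentation_config()) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(channel), dim(equalized)),
            identical(dim(channel), dim(cells)))
  min_area <- if (mode == "focus") config$min_area_focus else config$min_area_punctum
  mask <- (channel > config$raw_bright_threshold) &
          (equalized > config$equalized_bright_threshold) &
          (cells > 0)
  lab <- label_components(mask, 8L)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    drop <- which(areas < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- relabel_consecutive(lab)
  }
  n <- max(lab)
  owner <- integer(n)
  for (k in seq_len(n)) {
    cv <- cells[lab == k]
    tab <- table(cv)
    best <- as.integer(names(tab)[tab == max(tab)])
    owner[k] <- min(best)  # majority overlap, ties to the lower cell id
  }
  structure(list(labels = lab, mode = mode, owner = owner),
            class = "structure_map")
}
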