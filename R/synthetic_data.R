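#' Specification of a synthetic field of view
#'
#' Describes one simulated multi-channel field: how many cells, their size and
#' shape, the spatial pattern of bright structures in the primary channel
#' (dispersed perinuclear puncta, one large perinuclear focus, or none), the
#' fraction of structures carrying secondary-channel signal, and the intensity
#' model (cytoplasmic fill, structure amplitude, background level and gradient,
#' additive Gaussian noise). All lengths are in pixels, all intensities in
#' arbitrary units. The same spec (including `seed`) always renders
#' bit-identical images and ground truth.
#'
#' @param image_shape integer vector (height, width) in pixels.
#' @param n_cells number of cells to place (without overlap).
#' @param cell_radius_range range of the cell's major semi-axis, pixels.
#' @param nucleus_radius_fraction nucleus radius as a fraction of the cell's
#'   minor semi-axis.
#' @param pattern `"dispersed"` (n_puncta_per_cell small puncta in an annulus
#'   around the nucleus), `"clustered"` (one large focus adjacent to the
#'   nucleus), or `"none"`.
#' @param n_puncta_per_cell puncta per cell in dispersed mode.
#' @param punctum_radius,focus_radius structure radii in pixels; structures are
#'   rendered as isotropic Gaussian spots with sigma = radius / 2.
#' @param cluster_offset distance of the focus center from the nucleus edge,
#'   pixels (perinuclear placement).
#' @param coloc_fraction fraction of structures that also carry secondary
#'   signal, in \[0, 1\]; realized count is `round(fraction * n_structures)`.
#' @param structure_amplitude,cytoplasm_amplitude,background_level intensity
#'   units for structure peaks, cytoplasmic fill and flat background.
#' @param noise_sd additive Gaussian noise sd (images are clipped at 0).
#' @param background_gradient_amplitude peak of a left-to-right linear ramp
#'   added to the background.
#' @param seed integer RNG seed.
#' @return An object of class `scene_spec` (a validated list).
#' @seealso [generate_scene()], [generate_plate()]
#' @export
scene_spec <- function(image_shape = c(256L, 256L),
                       n_cells = 6L,
                       cell_radius_range = c(18, 26),
                       nucleus_radius_fraction = 0.35,
                       pattern = c("dispersed", "clustered", "none"),
                       n_puncta_per_cell = 8L,
                       punctum_radius = 2,
                       focus_radius = 5,
                       cluster_offset = 2,
                       coloc_fraction = 0.5,
                       structure_amplitude = 400,
                       cytoplasm_amplitude = 25,
                       background_level = 20,
                       noise_sd = 5,
                       background_gradient_amplitude = 10,
                       seed = 1L) {
  pattern <- match.arg(pattern)
  spec <- list(image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
               cell_radius_range = as.numeric(cell_radius_range),
               nucleus_radius_fraction = nucleus_radius_fraction, pattern = pattern,
               n_puncta_per_cell = as.integer(n_puncta_per_cell),
               punctum_radius = punctum_radius, focus_radius = focus_radius,
               cluster_offset = cluster_offset, coloc_fraction = coloc_fraction,
               structure_amplitude = structure_amplitude,
               cytoplasm_amplitude = cytoplasm_amplitude,
               background_level = background_level, noise_sd = noise_sd,
               background_gradient_amplitude = background_gradient_amplitude,
               seed = as.integer(seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with(spec, {
    if (length(image_shape) != 2L || any(image_shape < 16L))
      stop("image_shape must be (height, width), each >= 16 pixels")
    if (n_cells < 0L) stop("n_cells must be >= 0")
    if (any(cell_radius_range <= 0) || cell_radius_range[1] > cell_radius_range[2])
      stop("cell_radius_range must be positive and ordered")
    if (nucleus_radius_fraction <= 0 || nucleus_radius_fraction >= 1)
      stop("nucleus_radius_fraction must be in (0, 1)")
    if (punctum_radius <= 0 || focus_radius <= 0)
      stop("structure radii must be > 0")
    if (coloc_fraction < 0 || coloc_fraction > 1)
      stop("coloc_fraction must be in [0, 1]")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (n_puncta_per_cell < 0L) stop("n_puncta_per_cell must be >= 0")
  })
  invisible(spec)
}

# Update a scene_spec with named overrides, revalidating.
modify_scene_spec <- function(spec, overrides) {
  if (length(overrides) == 0L) return(spec)
  bad <- setdiff(names(overrides), names(unclass(spec)))
  if (length(bad)) stop("unknown scene_spec field(s): ", paste(bad, collapse = ", "))
  for (nm in names(overrides)) spec[[nm]] <- overrides[[nm]]
  if ("n_cells" %in% names(overrides)) spec$n_cells <- as.integer(spec$n_cells)
  if ("seed" %in% names(overrides)) spec$seed <- as.integer(spec$seed)
  if ("image_shape" %in% names(overrides)) spec$image_shape <- as.integer(spec$image_shape)
  validate_scene_spec(spec)
  spec
}

# Boundary radius of an ellipse (semi-axes a >= b) along local angle phi.
ellipse_radius <- function(a, b, phi) {
  a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
}

#' Generate one synthetic field of view with ground truth
#'
#' Renders a multi-channel 2D scene: elliptical cells with nuclei, bright
#' structures in the primary channel following the spec's spatial pattern, a
#' secondary channel in which only structures flagged as colocalized carry
#' signal above a diffuse cytoplasmic level, and a nuclear channel. Each
#' channel receives a flat background, a left-to-right linear gradient and
#' additive Gaussian noise, then is clipped at 0. Cells are placed by
#' rejection sampling so they never overlap.
#'
#' @param spec a [scene_spec()].
#' @param max_tries placement attempts before giving up.
#' @return A list with components `fov` (class `fov`: named channel matrices
#'   `primary`, `secondary`, `nuclear` plus plate coordinates) and `truth`
#'   (class `ground_truth`: `cell_masks` and `nucleus_masks` label maps,
#'   `structures` data frame with one row per planted structure
#'   (cell, center row/col in 0-based pixels, radius, mode, has_secondary),
#'   and `pattern` per cell).
#' @export
generate_scene <- function(spec, max_tries = 2000L) {
  validate_scene_spec(spec)
  with_seed(spec$seed, {
    H <- spec$image_shape[1]; W <- spec$image_shape[2]
    cell_masks <- matrix(0L, H, W)
    nucleus_masks <- matrix(0L, H, W)
    cells <- list()
    tries <- 0L
    while (length(cells) < spec$n_cells) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop(sprintf("could not place %d non-overlapping cells in a %dx%d image after %d attempts",
                     spec$n_cells, H, W, max_tries))
      a <- runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
      ecc <- runif(1, 1, 1.5)
      b <- a / ecc
      theta <- runif(1, 0, pi)
      if (2 * (a + 2) >= H - 1 || 2 * (a + 2) >= W - 1)
        stop("cells too large for image_shape")
      r0 <- runif(1, a + 2, H - 3 - a)
      c0 <- runif(1, a + 2, W - 3 - a)
      ok <- TRUE
      for (cl in cells) {
        if (sqrt((r0 - cl$r0)^2 + (c0 - cl$c0)^2) < a + cl$a + 3) { ok <- FALSE; break }
      }
      if (!ok) next
      cells[[length(cells) + 1L]] <- list(r0 = r0, c0 = c0, a = a, b = b, theta = theta)
    }

    # paint cell + nucleus masks (0-based pixel coordinates)
    for (k in seq_along(cells)) {
      cl <- cells[[k]]
      rr <- max(0, floor(cl$r0 - cl$a)):min(H - 1, ceiling(cl$r0 + cl$a))
      cc <- max(0, floor(cl$c0 - cl$a)):min(W - 1, ceiling(cl$c0 + cl$a))
      rg <- matrix(rr, length(rr), length(cc))
      cg <- matrix(cc, length(rr), length(cc), byrow = TRUE)
      u <- (rg - cl$r0) * cos(cl$theta) + (cg - cl$c0) * sin(cl$theta)
      v <- -(rg - cl$r0) * sin(cl$theta) + (cg - cl$c0) * cos(cl$theta)
      inside <- (u / cl$a)^2 + (v / cl$b)^2 <= 1
      sub <- cell_masks[rr + 1, cc + 1]
      sub[inside] <- k
      cell_masks[rr + 1, cc + 1] <- sub
      rn <- spec$nucleus_radius_fraction * cl$b
      nuc <- (rg - cl$r0)^2 + (cg - cl$c0)^2 <= rn^2
      subn <- nucleus_masks[rr + 1, cc + 1]
      subn[nuc] <- k
      nucleus_masks[rr + 1, cc + 1] <- subn
      cells[[k]]$rn <- rn
    }

    # plant structures
    recs <- list()
    for (k in seq_along(cells)) {
      cl <- cells[[k]]
      place <- function(s, phi) {
        u <- s * cos(phi); v <- s * sin(phi)
        c(cl$r0 + u * cos(cl$theta) - v * sin(cl$theta),
          cl$c0 + u * sin(cl$theta) + v * cos(cl$theta))
      }
      if (spec$pattern == "dispersed") {
        placed <- NULL  # centers already planted in this cell
        min_sep <- 2 * spec$punctum_radius + 3  # keep planted puncta distinct
        for (j in seq_len(spec$n_puncta_per_cell)) {
          ctr <- c(cl$r0, cl$c0)  # fallback if no annulus position fits
          for (try in 1:100) {
            phi <- runif(1, 0, 2 * pi)
            rb <- ellipse_radius(cl$a, cl$b, phi)
            lo <- cl$rn + spec$punctum_radius
            hi <- rb - spec$punctum_radius - 1
            if (hi <= lo) next
            s <- runif(1, lo, hi)
            cand <- place(s, phi)
            ri <- as.integer(round(cand[1])) + 1L; ci <- as.integer(round(cand[2])) + 1L
            if (!(ri >= 1 && ri <= H && ci >= 1 && ci <= W && cell_masks[ri, ci] == k)) next
            if (!is.null(placed) &&
                min(sqrt((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2)) < min_sep)
              next
            ctr <- cand
            break
          }
          placed <- rbind(placed, ctr)
          recs[[length(recs) + 1L]] <- data.frame(
            cell = k, row = ctr[1], col = ctr[2],
            radius = spec$punctum_radius, mode = "punctum")
        }
      } else if (spec$pattern == "clustered") {
        for (try in 1:50) {
          phi <- runif(1, 0, 2 * pi)
          rb <- ellipse_radius(cl$a, cl$b, phi)
          s <- cl$rn + spec$cluster_offset
          if (s + spec$focus_radius + 1 <= rb) break
        }
        ctr <- place(s, phi)
        recs[[length(recs) + 1L]] <- data.frame(
          cell = k, row = ctr[1], col = ctr[2],
          radius = spec$focus_radius, mode = "focus")
      }
    }
    structures <- if (length(recs)) do.call(rbind, recs) else
      data.frame(cell = integer(0), row = numeric(0), col = numeric(0),
                 radius = numeric(0), mode = character(0))
    n_str <- nrow(structures)
    structures$has_secondary <- rep(FALSE, n_str)
    if (n_str > 0) {
      n_pos <- as.integer(round(spec$coloc_fraction * n_str))
      if (n_pos > 0) structures$has_secondary[sample.int(n_str, n_pos)] <- TRUE
    }
    structures <- cbind(structure = seq_len(n_str), structures)
    rownames(structures) <- NULL

    # render channels
    colm <- matrix(0:(W - 1), H, W, byrow = TRUE)
    grad <- if (W > 1) spec$background_gradient_amplitude * colm / (W - 1) else 0
    base <- spec$background_level + grad
    in_cell <- cell_masks > 0
    primary <- base + spec$cytoplasm_amplitude * in_cell
    secondary <- base + 0.5 * spec$cytoplasm_amplitude * in_cell
    add_spot <- function(img, r0, c0, radius, amp) {
      sg <- radius / 2
      ext <- ceiling(4 * sg)
      rr <- max(0, floor(r0 - ext)):min(H - 1, ceiling(r0 + ext))
      cc <- max(0, floor(c0 - ext)):min(W - 1, ceiling(c0 + ext))
      rg <- matrix(rr, length(rr), length(cc))
      cg <- matrix(cc, length(rr), length(cc), byrow = TRUE)
      img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] +
        amp * exp(-((rg - r0)^2 + (cg - c0)^2) / (2 * sg^2))
      img
    }
    for (i in seq_len(n_str)) {
      st <- structures[i, ]
      primary <- add_spot(primary, st$row, st$col, st$radius, spec$structure_amplitude)
      if (st$has_secondary)
        secondary <- add_spot(secondary, st$row, st$col, st$radius, spec$structure_amplitude)
    }
    nuclear <- spec$background_level + spec$structure_amplitude * (nucleus_masks > 0)
    if (spec$noise_sd > 0) {
      primary <- primary + rnorm(H * W, 0, spec$noise_sd)
      secondary <- secondary + rnorm(H * W, 0, spec$noise_sd)
      nuclear <- nuclear + rnorm(H * W, 0, spec$noise_sd)
    }
    primary <- pmax(primary, 0)
    secondary <- pmax(secondary, 0)
    nuclear <- pmax(nuclear, 0)

    fov <- field_of_view(list(primary = primary, secondary = secondary,
                              nuclear = nuclear))
    truth <- structure(list(cell_masks = cell_masks, nucleus_masks = nucleus_masks,
                            structures = structures,
                            pattern = rep(spec$pattern, spec$n_cells),
                            spec = spec),
                       class = "ground_truth")
    list(fov = fov, truth = truth)
  })
}

#' Define a plate layout
#'
#' A plate layout names the experimental conditions, the wells belonging to
#' each condition and the imaging sites within each well. Wells are unique
#' across the plate (a well cannot belong to two conditions).
#'
#' @param conditions character vector of condition names.
#' @param wells_per_condition replicate wells per condition (default 3, the
#'   usual triplicate design).
#' @param sites_per_well imaging sites (fields) per well.
#' @return A data frame with columns `condition`, `well`, `site`.
#' @export
plate_layout <- function(conditions, wells_per_condition = 3L, sites_per_well = 2L) {
  stopifnot(length(conditions) >= 1L, wells_per_condition >= 1L, sites_per_well >= 1L)
  out <- do.call(rbind, lapply(conditions, function(cd) {
    expand.grid(site = sprintf("s%d", seq_len(sites_per_well)),
                well = sprintf("%s_w%d", cd, seq_len(wells_per_condition)),
                condition = cd, stringsAsFactors = FALSE)[, 3:1]
  }))
  rownames(out) <- NULL
  validate_layout(out)
  out
}

validate_layout <- function(layout) {
  need <- c("condition", "well", "site")
  if (!all(need %in% names(layout)))
    stop("layout must have columns condition, well, site")
  key <- paste(layout$well, layout$site, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate (well, site) in layout: ", key[duplicated(key)][1])
  wc <- unique(layout[, c("condition", "well")])
  if (anyDuplicated(wc$well))
    stop("well assigned to more than one condition: ",
         wc$well[duplicated(wc$well)][1])
  invisible(layout)
}

#' Generate a full synthetic plate
#'
#' Renders one scene per (condition, well, site) of the layout. Per-condition
#' overrides change any [scene_spec()] field (typically `pattern` or
#' `coloc_fraction`), so conditions with different phenotypes share all other
#' generation parameters. Each scene gets a seed derived deterministically
#' from the base spec's seed and its (well, site), so regenerating a subset of
#' the plate reproduces the same scenes.
#'
#' @param layout a plate layout data frame (see [plate_layout()]).
#' @param spec base [scene_spec()]; its `seed` is the plate's base seed.
#' @param overrides named list: `condition -> list(field = value, ...)`.
#' @return Named list (`condition/well/site`) of scenes as returned by
#'   [generate_scene()], with plate coordinates stamped on each `fov`.
#' @export
generate_plate <- function(layout, spec = scene_spec(), overrides = list()) {
  validate_layout(layout)
  validate_scene_spec(spec)
  bad <- setdiff(names(overrides), unique(layout$condition))
  if (length(bad)) stop("overrides for unknown condition(s): ", paste(bad, collapse = ", "))
  out <- vector("list", nrow(layout))
  nms <- character(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    cd <- layout$condition[i]; wl <- layout$well[i]; st <- layout$site[i]
    sp <- modify_scene_spec(spec, overrides[[cd]])
    sp$seed <- derive_seed(spec$seed, wl, st)
    scene <- generate_scene(sp)
    scene$fov$condition <- cd
    scene$fov$well <- wl
    scene$fov$site <- st
    scene$seed <- sp$seed
    out[[i]] <- scene
    nms[i] <- paste(cd, wl, st, sep = "/")
  }
  names(out) <- nms
  out
}
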