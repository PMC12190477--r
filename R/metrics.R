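fov_meta <- function(fov) {
  list(condition = as.character(fov$condition), well = as.character(fov$well),
       site = as.character(fov$site))
}

#' Per-cell Pearson colocalization
#'
#' Computes the Pearson correlation coefficient between the primary and
#' secondary channel over all pixels inside each cell's mask (both channels
#' background-subtracted, no pixel thresholding). Cells with fewer than two
#' pixels or a constant channel are skipped with a warning, since r is
#' undefined there.
#'
#' @param fov a [field_of_view()] with `primary` and `secondary` channels,
#'   background-subtracted.
#' @param cells cell label map from [segment_cells()].
#' @return Data frame with one row per scored cell: condition, well, site,
#'   cell, r, n_pixels.
#' @export
pearson_per_cell <- function(fov, cells) {
  stopifnot(inherits(fov, "fov"))
  if (is.null(fov$channels$secondary))
    stop("secondary channel required for Pearson colocalization")
  meta <- fov_meta(fov)
  ids <- setdiff(sort(unique(as.integer(cells))), 0L)
  rows <- list(); skipped <- 0L
  for (k in ids) {
    px <- cells == k
    x <- fov$channels$primary[px]
    y <- fov$channels$secondary[px]
    if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      condition = meta$condition, well = meta$well, site = meta$site,
      cell = k, r = cor(x, y), n_pixels = length(x))
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d cell(s) with constant or <2-pixel channels", skipped))
  if (length(rows) == 0L)
    return(data.frame(condition = character(0), well = character(0),
                      site = character(0), cell = integer(0), r = numeric(0),
                      n_pixels = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# site data frame -> well medians -> condition mean +- sample SD over wells.
# `group` optionally keeps a statistic column through the hierarchy.
agg_site_to_condition <- function(site_df, value = "value", group = NULL) {
  gw <- c("condition", "well", group)
  fw <- stats::as.formula(paste(value, "~", paste(gw, collapse = "+")))
  well <- aggregate(fw, site_df, median)
  gc <- c("condition", group)
  fc <- stats::as.formula(paste(value, "~", paste(gc, collapse = "+")))
  cond_mean <- aggregate(fc, well, mean)
  names(cond_mean)[names(cond_mean) == value] <- "mean"
  cond_sd <- aggregate(fc, well, function(v) if (length(v) >= 2) sd(v) else NA_real_)
  names(cond_sd)[names(cond_sd) == value] <- "sd"
  cond_n <- aggregate(fc, well, length)
  names(cond_n)[names(cond_n) == value] <- "n_wells"
  cond <- merge(merge(cond_mean, cond_sd, by = gc), cond_n, by = gc)
  if (any(cond$n_wells < 2))
    warning("condition(s) with < 2 wells: SD undefined, reported as NA")
  list(well = well, condition = cond)
}

#' Aggregate per-cell Pearson records hierarchically
#'
#' Follows the cell -> site -> well -> condition scheme: the median r over the
#' single cells of each imaging site, the median of site values per well (or,
#' with `pool_sites = TRUE`, the median over all of the well's cells pooled),
#' then the mean and sample standard deviation over the wells of each
#' condition (typically 3 replicate wells).
#'
#' @param records output of [pearson_per_cell()] (rows from many fields).
#' @param pool_sites pool a well's cells instead of median-of-site-medians.
#' @return List of data frames: `site`, `well`, `condition` (mean, sd,
#'   n_wells).
#' @export
aggregate_pearson <- function(records, pool_sites = FALSE) {
  if (nrow(records) == 0L) stop("no Pearson records to aggregate")
  site <- aggregate(r ~ condition + well + site, records, median)
  names(site)[names(site) == "r"] <- "value"
  if (pool_sites) {
    well <- aggregate(r ~ condition + well, records, median)
    names(well)[names(well) == "r"] <- "value"
    cond <- agg_site_to_condition(
      transform(well, site = "pooled"), value = "value")$condition
    # well medians already computed; recompute condition stats over them
    return(list(site = site, well = well, condition = cond))
  }
  out <- agg_site_to_condition(site, value = "value")
  list(site = site, well = out$well, condition = out$condition)
}

#' Score structure positivity for the secondary channel
#'
#' For each segmented structure, a nearby cellular region is obtained by
#' morphological dilation of the structure by a disc, excluding all structure
#' pixels (of every structure in the image), background pixels (outside the
#' cell segmentation) and pixels of other cells. The positivity ratio is the
#' mean secondary-channel intensity over the structure divided by the mean
#' over this region; structures with ratio strictly greater than the
#' threshold (default 1.25) are positive. Structures whose region is empty
#' after the exclusions (or has nonpositive mean) are flagged unscorable and
#' excluded from fractions.
#'
#' @param fov a [field_of_view()] with background-subtracted `secondary`.
#' @param cells cell label map.
#' @param structures a `structure_map` from [segment_structures()].
#' @param threshold positivity ratio threshold (strict; default 1.25).
#' @param dilation_radius disc radius in pixels for the surrounding region.
#' @return Data frame, one row per structure: ids, mode, area,
#'   structure_mean, region_mean, ratio, positive, scorable.
#' @export
score_structure_positivity <- function(fov, cells, structures,
                                       threshold = 1.25, dilation_radius = 5) {
  stopifnot(inherits(fov, "fov"), inherits(structures, "structure_map"))
  if (is.null(fov$channels$secondary))
    stop("secondary channel required for positivity scoring")
  sec <- fov$channels$secondary
  lab <- structures$labels
  meta <- fov_meta(fov)
  H <- nrow(lab); W <- ncol(lab)
  all_struct <- lab > 0L
  brush <- EBImage::makeBrush(2L * as.integer(dilation_radius) + 1L, "disc")
  n <- max(lab)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    px <- which(lab == k)
    pos <- arrayInd(px, dim(lab))
    own <- structures$owner[k]
    pad <- dilation_radius + 1L
    r1 <- max(1L, min(pos[, 1]) - pad); r2 <- min(H, max(pos[, 1]) + pad)
    c1 <- max(1L, min(pos[, 2]) - pad); c2 <- min(W, max(pos[, 2]) + pad)
    sub <- lab[r1:r2, c1:c2] == k
    dil <- as.matrix(EBImage::dilate(sub * 1, brush)) > 0
    region <- dil & !all_struct[r1:r2, c1:c2] & (cells[r1:r2, c1:c2] == own)
    smean <- mean(sec[px])
    if (any(region)) rmean <- mean(sec[r1:r2, c1:c2][region]) else rmean <- NA_real_
    scorable <- is.finite(rmean) && rmean > 0
    ratio <- if (scorable) smean / rmean else NA_real_
    rows[[k]] <- data.frame(
      condition = meta$condition, well = meta$well, site = meta$site,
      cell = own, structure = k, mode = structures$mode,
      area = length(px), structure_mean = smean, region_mean = rmean,
      ratio = ratio, positive = isTRUE(ratio > threshold), scorable = scorable)
  }
  if (n == 0L)
    return(data.frame(condition = character(0), well = character(0),
                      site = character(0), cell = integer(0),
                      structure = integer(0), mode = character(0),
                      area = integer(0), structure_mean = numeric(0),
                      region_mean = numeric(0), ratio = numeric(0),
                      positive = logical(0), scorable = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fractions of positive structures and of positive cells
#'
#' Per imaging site, two statistics: the fraction of scorable structures that
#' are positive, and the fraction of structure-bearing cells that contain at
#' least one positive structure. Sites with zero scorable structures are
#' excluded with a warning. Aggregation then follows site -> well (median) ->
#' condition (mean +- SD over wells).
#'
#' @param table scored structure table from [score_structure_positivity()]
#'   (rows from many fields).
#' @return List of data frames `site`, `well`, `condition`; each carries a
#'   `statistic` column (`fraction_structures_positive`,
#'   `fraction_cells_positive`).
#' @export
positivity_fractions <- function(table) {
  if (nrow(table) == 0L) stop("no structures to summarize")
  keys <- unique(table[, c("condition", "well", "site")])
  rows <- list(); excluded <- 0L
  for (i in seq_len(nrow(keys))) {
    sel <- table$condition == keys$condition[i] & table$well == keys$well[i] &
           table$site == keys$site[i]
    sc <- table[sel & table$scorable, ]
    if (nrow(sc) == 0L) { excluded <- excluded + 1L; next }
    frac_struct <- mean(sc$positive)
    per_cell <- tapply(sc$positive, sc$cell, any)
    frac_cell <- mean(per_cell)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = keys$condition[i], well = keys$well[i], site = keys$site[i],
      statistic = c("fraction_structures_positive", "fraction_cells_positive"),
      value = c(frac_struct, frac_cell))
  }
  if (excluded > 0L)
    warning(sprintf("excluded %d site(s) with zero scorable structures", excluded))
  if (length(rows) == 0L) stop("no site had scorable structures")
  site <- do.call(rbind, rows)
  rownames(site) <- NULL
  out <- agg_site_to_condition(site, value = "value", group = "statistic")
  list(site = site, well = out$well, condition = out$condition)
}

#' Radial dispersion profile of one cell
#'
#' Finds the intensity-weighted centroid of the (primary-channel) signal
#' within the cell mask, assigns every in-cell pixel a ring index equal to its
#' Euclidean distance to the centroid rounded to the nearest integer, averages
#' intensity within each ring, and normalizes the profile by the cell's mean
#' intensity. Pixels outside the cell mask are never counted; rings with no
#' pixels are absent from the output. Cells whose structure mask has fewer
#' than `min_structure_pixels` nonzero pixels, or zero total intensity, are
#' skipped (returned as NULL).
#'
#' @param channel background-subtracted primary channel matrix.
#' @param cell_mask logical matrix selecting the cell's pixels.
#' @param structure_mask logical matrix of structure pixels (used only for the
#'   qualification gate); NULL disables the gate.
#' @param min_structure_pixels minimum nonzero structure pixels for the cell
#'   to qualify (default 5, the punctum minimum size).
#' @return Data frame (distance, value, n_pixels) or NULL if skipped. The
#'   pixel-count-weighted mean of `value` equals 1 by construction.
#' @export
dispersion_profile_cell <- function(channel, cell_mask, structure_mask = NULL,
                                    min_structure_pixels = 5) {
  cell_mask <- cell_mask > 0
  if (!is.null(structure_mask) &&
      sum(structure_mask[cell_mask] > 0) < min_structure_pixels)
    return(NULL)
  px <- which(cell_mask)
  if (length(px) == 0L) return(NULL)
  w <- channel[px]
  tot <- sum(w)
  if (tot <= 0) {
    warning("cell with zero total intensity skipped")
    return(NULL)
  }
  pos <- arrayInd(px, dim(channel)) - 1L  # 0-based (row, col)
  cr <- sum(w * pos[, 1]) / tot
  cc <- sum(w * pos[, 2]) / tot
  d <- round(sqrt((pos[, 1] - cr)^2 + (pos[, 2] - cc)^2))
  mean_int <- tot / length(w)
  ring_sum <- tapply(w, d, sum)
  ring_n <- tapply(w, d, length)
  out <- data.frame(distance = as.integer(names(ring_sum)),
                    value = as.numeric(ring_sum / ring_n) / mean_int,
                    n_pixels = as.integer(ring_n))
  out[order(out$distance), , drop = FALSE]
}

#' Dispersion profiles for every qualifying cell of a field
#'
#' Applies [dispersion_profile_cell()] to each segmented cell, gating on the
#' number of structure pixels the cell carries, and returns a long-format
#' table.
#'
#' @param fov a [field_of_view()] (background-subtracted primary).
#' @param cells cell label map.
#' @param structures `structure_map` used for the qualification gate (NULL
#'   disables the gate and profiles every cell).
#' @param min_structure_pixels see [dispersion_profile_cell()].
#' @return Data frame: condition, well, site, cell, distance, value, n_pixels.
#' @export
dispersion_profiles <- function(fov, cells, structures = NULL,
                                min_structure_pixels = 5) {
  stopifnot(inherits(fov, "fov"))
  meta <- fov_meta(fov)
  smask <- if (!is.null(structures)) structures$labels > 0L else NULL
  ids <- setdiff(sort(unique(as.integer(cells))), 0L)
  rows <- list()
  for (k in ids) {
    cm <- cells == k
    prof <- dispersion_profile_cell(fov$channels$primary, cm, smask,
                                    min_structure_pixels)
    if (is.null(prof)) next
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(condition = meta$condition, well = meta$well,
                 site = meta$site, cell = k),
      prof)
  }
  if (length(rows) == 0L)
    return(data.frame(condition = character(0), well = character(0),
                      site = character(0), cell = integer(0),
                      distance = integer(0), value = numeric(0),
                      n_pixels = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate dispersion profiles to well and condition level
#'
#' Per distance ring: the median over all of a well's cells that possess that
#' ring (no zero-padding of short profiles), then the mean and sample SD over
#' wells per condition. Wells contribute to a condition ring only if they have
#' it.
#'
#' @param profiles long cell-level table from [dispersion_profiles()].
#' @return List of data frames: `well` (condition, well, distance, value,
#'   n_cells) and `condition` (condition, distance, mean, sd, n_wells).
#' @export
aggregate_dispersion <- function(profiles) {
  if (nrow(profiles) == 0L) stop("no dispersion profiles to aggregate")
  well <- aggregate(value ~ condition + well + distance, profiles, median)
  ncell <- aggregate(value ~ condition + well + distance, profiles, length)
  names(ncell)[names(ncell) == "value"] <- "n_cells"
  well <- merge(well, ncell, by = c("condition", "well", "distance"))
  cond_mean <- aggregate(value ~ condition + distance, well, mean)
  names(cond_mean)[names(cond_mean) == "value"] <- "mean"
  cond_sd <- aggregate(value ~ condition + distance, well,
                       function(v) if (length(v) >= 2) sd(v) else NA_real_)
  names(cond_sd)[names(cond_sd) == "value"] <- "sd"
  cond_n <- aggregate(value ~ condition + distance, well, length)
  names(cond_n)[names(cond_n) == "value"] <- "n_wells"
  cond <- merge(merge(cond_mean, cond_sd, by = c("condition", "distance")),
                cond_n, by = c("condition", "distance"))
  well <- well[order(well$condition, well$well, well$distance), ]
  cond <- cond[order(cond$condition, cond$distance), ]
  rownames(well) <- rownames(cond) <- NULL
  list(well = well, condition = cond)
}

#' Peak statistics of a dispersion profile
#'
#' The peak is the maximum ring value; ties go to the smallest distance. The
#' half-max width is the number of contiguous rings around the peak (in ring
#' order) whose value is at least half the peak. A sharp narrow peak indicates
#' clustered foci; a low broad profile indicates dispersed puncta.
#'
#' @param profile data frame with `distance` and a value column (`value` or
#'   `mean`), or a bare numeric vector ordered by distance.
#' @return List: `peak_value`, `peak_distance`, `halfmax_width`.
#' @export
profile_peak_stats <- function(profile) {
  if (is.data.frame(profile)) {
    vcol <- if ("value" %in% names(profile)) "value" else "mean"
    profile <- profile[order(profile$distance), ]
    v <- profile[[vcol]]
    d <- profile$distance
  } else {
    v <- as.numeric(profile)
    d <- seq_along(v) - 1L
  }
  if (length(v) == 0L) stop("empty profile")
  i <- which.max(v)  # first maximum = smallest distance on ties
  half <- v[i] / 2
  lo <- i
  while (lo > 1L && v[lo - 1L] >= half) lo <- lo - 1L
  hi <- i
  while (hi < length(v) && v[hi + 1L] >= half) hi <- hi + 1L
  list(peak_value = v[i], peak_distance = d[i], halfmax_width = hi - lo + 1L)
}
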