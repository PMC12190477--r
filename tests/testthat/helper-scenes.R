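# Shared fixtures: everything is generated in code at test time.

default_cfg <- segmentation_config()

# Run background subtraction, cell segmentation and equalization on a scene.
process_scene <- function(scene, cfg = default_cfg, channels = "primary") {
  sub <- lapply(scene$fov$channels[channels], subtract_background, config = cfg)
  fv <- field_of_view(sub, scene$fov$condition, scene$fov$well, scene$fov$site)
  cells <- segment_cells(fv, cfg)
  eq <- equalize_intensity(fv$channels$primary, cfg)
  list(fv = fv, cells = cells, eq = eq)
}

# Two touching disk-shaped cells with distinct nuclei, built directly
# (the generator never places overlapping cells).
touching_cells_fov <- function() {
  H <- 96L; W <- 140L
  rg <- matrix(0:(H - 1), H, W)
  cg <- matrix(0:(W - 1), H, W, byrow = TRUE)
  d1 <- sqrt((rg - 47)^2 + (cg - 48)^2)
  d2 <- sqrt((rg - 47)^2 + (cg - 88)^2)
  body <- d1 <= 21 | d2 <= 21
  primary <- 60 * body
  nuclear <- 200 * ((d1 <= 7) | (d2 <= 7))
  field_of_view(list(primary = primary, nuclear = nuclear))
}

# Brute-force radial dispersion oracle: explicit per-pixel loops, per-ring
# value vectors collected in scan order, independent of the package's
# vectorized ring assignment.
brute_dispersion <- function(channel, cell_mask) {
  px <- which(cell_mask > 0)
  pos <- arrayInd(px, dim(channel)) - 1L
  w_vec <- numeric(0); wr <- numeric(0); wc <- numeric(0)
  for (i in seq_along(px)) {
    w_vec[i] <- channel[px[i]]
    wr[i] <- w_vec[i] * pos[i, 1]
    wc[i] <- w_vec[i] * pos[i, 2]
  }
  tot <- sum(w_vec)
  cr <- sum(wr) / tot
  cc <- sum(wc) / tot
  rings <- list()
  for (i in seq_along(px)) {
    k <- as.character(round(sqrt((pos[i, 1] - cr)^2 + (pos[i, 2] - cc)^2)))
    rings[[k]] <- c(rings[[k]], w_vec[i])
  }
  mean_int <- tot / length(w_vec)
  d <- as.integer(names(rings))
  value <- vapply(rings, function(v) (sum(v) / length(v)) / mean_int, 0)
  out <- data.frame(distance = d, value = unname(value),
                    n_pixels = vapply(rings, length, 0L))
  out[order(out$distance), , drop = FALSE]
}

# Paint axis-aligned rectangles of the requested areas onto a blank image,
# well separated; returns the intensity image (bright rectangles on zero).
rectangles_image <- function(areas, H = 80L, W = 200L, value = 1000) {
  img <- matrix(0, H, W)
  col0 <- 10L
  for (a in areas) {
    h <- max(1L, floor(sqrt(a)))
    wdt <- ceiling(a / h)
    cells <- a
    for (r in seq_len(h)) {
      ncol_r <- min(wdt, cells)
      img[10L + r, col0 + seq_len(ncol_r)] <- value
      cells <- cells - ncol_r
      if (cells <= 0) break
    }
    col0 <- col0 + wdt + 10L
  }
  img
}
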