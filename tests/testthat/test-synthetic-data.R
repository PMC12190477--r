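test_that("an empty scene is background plus noise with empty ground truth", {
  sp <- scene_spec(n_cells = 0L, seed = 5)
  sc <- generate_scene(sp)
  expect_equal(nrow(sc$truth$structures), 0L)
  expect_true(all(sc$truth$cell_masks == 0L))
  # away from clipping, pixels should scatter around background + gradient
  expect_lt(abs(mean(sc$fov$channels$primary) -
                (sp$background_level + sp$background_gradient_amplitude / 2)), 1)
  expect_lt(sd(sc$fov$channels$primary), sp$noise_sd + 4)
})

test_that("identical specs render bit-identical scenes", {
  sp <- scene_spec(pattern = "clustered", n_cells = 5L, seed = 1)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$fov$channels, b$fov$channels)
  expect_identical(a$truth$structures, b$truth$structures)
  expect_identical(a$truth$cell_masks, b$truth$cell_masks)
})

test_that("dispersed scenes plant the requested structure and coloc counts", {
  sp <- scene_spec(image_shape = c(360L, 360L), n_cells = 10L,
                   pattern = "dispersed", n_puncta_per_cell = 8L,
                   coloc_fraction = 0.5, seed = 2)
  sc <- generate_scene(sp)
  expect_equal(nrow(sc$truth$structures), 80L)
  expect_equal(sum(sc$truth$structures$has_secondary), 40L)
})

test_that("ground truth is internally consistent across random specs", {
  set.seed(99)
  for (i in 1:20) {
    sp <- scene_spec(pattern = sample(c("dispersed", "clustered"), 1),
                     n_cells = sample(3:6, 1),
                     n_puncta_per_cell = sample(4:9, 1),
                     coloc_fraction = runif(1),
                     seed = sample.int(1e6, 1))
    sc <- generate_scene(sp)
    tr <- sc$truth$structures
    n_expect <- if (sp$pattern == "clustered") sp$n_cells
                else sp$n_cells * sp$n_puncta_per_cell
    expect_equal(nrow(tr), n_expect)
    # every structure center lies inside its cell mask
    own <- sc$truth$cell_masks[cbind(round(tr$row) + 1, round(tr$col) + 1)]
    expect_equal(own, tr$cell)
    # realized coloc fraction within rounding of one structure
    expect_lte(abs(sum(tr$has_secondary) - sp$coloc_fraction * nrow(tr)), 0.5 + 1e-9)
  }
})

test_that("raising noise_sd changes pixels but not the planted truth", {
  a <- generate_scene(scene_spec(seed = 7, noise_sd = 2))
  b <- generate_scene(scene_spec(seed = 7, noise_sd = 12))
  expect_identical(a$truth$structures, b$truth$structures)
  expect_identical(a$truth$cell_masks, b$truth$cell_masks)
  expect_false(identical(a$fov$channels$primary, b$fov$channels$primary))
})

test_that("secondary signal appears only at colocalized structures", {
  sp <- scene_spec(coloc_fraction = 0.5, seed = 13)
  sc <- generate_scene(sp)
  tr <- sc$truth$structures
  disk_mean <- function(st) {
    rr <- round(st$row) + 1; cc <- round(st$col) + 1
    win <- sc$fov$channels$secondary[
      max(1, rr - 1):min(nrow(sc$fov$channels$secondary), rr + 1),
      max(1, cc - 1):min(ncol(sc$fov$channels$secondary), cc + 1)]
    mean(win)
  }
  pos <- vapply(which(tr$has_secondary), function(i) disk_mean(tr[i, ]), 0)
  neg <- vapply(which(!tr$has_secondary), function(i) disk_mean(tr[i, ]), 0)
  # colocalized structures carry ~ the configured amplitude above the diffuse
  # level; separation must dwarf the noise of the 9-pixel mean estimator
  expect_gt(mean(pos) - mean(neg), 0.5 * sp$structure_amplitude)
  expect_gt(min(pos) - max(neg), 3 * sp$noise_sd / sqrt(9))
})

test_that("plates enumerate sites with distinct deterministic seeds", {
  lay <- plate_layout("ctrl", wells_per_condition = 3, sites_per_well = 2)
  sp <- scene_spec(n_cells = 2L, seed = 3)
  pl <- generate_plate(lay, sp)
  expect_length(pl, 6L)
  seeds <- vapply(pl, `[[`, 0L, "seed")
  expect_equal(length(unique(seeds)), 6L)
  pl2 <- generate_plate(lay, sp)
  expect_identical(lapply(pl, function(s) s$fov$channels),
                   lapply(pl2, function(s) s$fov$channels))
})

test_that("invalid layouts are rejected", {
  bad <- data.frame(condition = c("a", "b"), well = "w1", site = "s1")
  expect_error(validate_layout(bad), "duplicate|condition")
  bad2 <- data.frame(condition = c("a", "b"), well = "w1", site = c("s1", "s2"))
  expect_error(generate_plate(bad2, scene_spec(n_cells = 1L)),
               "more than one condition")
  expect_error(scene_spec(coloc_fraction = 1.5), "coloc_fraction")
  expect_error(scene_spec(punctum_radius = 0), "radii")
})

test_that("impossible cell placement raises a placement error", {
  sp <- scene_spec(image_shape = c(80L, 80L), n_cells = 12L,
                   cell_radius_range = c(18, 20), seed = 1)
  expect_error(generate_scene(sp), "could not place")
})
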