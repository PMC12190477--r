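make_cell_fov <- function(primary, secondary) {
  field_of_view(list(primary = primary, secondary = secondary),
                condition = "c", well = "w", site = "s")
}

test_that("per-cell Pearson handles perfect, inverted and degenerate channels", {
  cells <- matrix(0L, 4, 4); cells[2:3, 2:3] <- 1L
  p <- matrix(runif(16, 1, 9), 4, 4)
  dup <- pearson_per_cell(make_cell_fov(p, p), cells)
  expect_equal(dup$r, 1)
  inv <- pearson_per_cell(make_cell_fov(p, 10 - p), cells)
  expect_equal(inv$r, -1)
  const <- matrix(5, 4, 4)
  expect_warning(out <- pearson_per_cell(make_cell_fov(p, const), cells),
                 "constant")
  expect_equal(nrow(out), 0L)
  expect_error(pearson_per_cell(field_of_view(list(primary = p)), cells),
               "secondary")
})

test_that("the four-pixel worked example gives r = 0.8", {
  cells <- matrix(0L, 2, 2); cells[] <- 1L
  p <- matrix(c(1, 2, 3, 4), 2, 2)
  s <- matrix(c(1, 3, 2, 4), 2, 2)
  out <- pearson_per_cell(make_cell_fov(p, s), cells)
  expect_equal(out$r, 0.8)
  expect_equal(out$n_pixels, 4L)
})

test_that("Pearson is invariant under positive affine rescaling", {
  set.seed(42)
  for (i in 1:5) {
    cells <- matrix(0L, 20, 20); cells[4:17, 4:17] <- 1L
    p <- matrix(runif(400, 0, 50), 20, 20)
    s <- 0.4 * p + matrix(rnorm(400, 0, 5), 20, 20)
    a <- runif(1, 0.1, 8); b <- runif(1, -2, 20)
    r1 <- pearson_per_cell(make_cell_fov(p, s), cells)$r
    r2 <- pearson_per_cell(make_cell_fov(a * p + b, s), cells)$r
    expect_equal(r1, r2, tolerance = 1e-12)
  }
})

test_that("hierarchical Pearson aggregation reproduces hand-computed values", {
  rec <- function(cond, well, site, rs)
    data.frame(condition = cond, well = well, site = site,
               cell = seq_along(rs), r = rs, n_pixels = 100L)
  records <- rbind(
    rec("c1", "w1", "s1", c(0.1, 0.2, 0.9)),   # site median 0.2
    rec("c1", "w1", "s2", 0.4),                 # single cell -> site median 0.4
    rec("c1", "w1", "s3", c(0.85, 0.9, 0.95)),  # site median 0.9
    rec("c1", "w2", "s1", 0.5),
    rec("c1", "w3", "s1", 0.7))
  agg <- aggregate_pearson(records)
  # well w1: median of site medians (0.2, 0.4, 0.9) = 0.4
  expect_equal(agg$well$value[agg$well$well == "w1"], 0.4)
  cond <- agg$condition
  expect_equal(cond$mean, mean(c(0.4, 0.5, 0.7)))
  expect_equal(cond$sd, sd(c(0.4, 0.5, 0.7)))
  expect_equal(cond$n_wells, 3L)
})

test_that("condition mean and SD over wells match the textbook example", {
  records <- data.frame(condition = "c", well = c("w1", "w2", "w3"),
                        site = "s1", cell = 1L, r = c(0.3, 0.5, 0.7),
                        n_pixels = 10L)
  agg <- aggregate_pearson(records)
  expect_equal(agg$condition$mean, 0.5)
  expect_equal(agg$condition$sd, 0.2)
  one_well <- records[1, ]
  expect_warning(a1 <- aggregate_pearson(one_well), "< 2 wells")
  expect_true(is.na(a1$condition$sd))
})

test_that("positivity ratio is strict at the threshold", {
  # one 3x3 structure inside one cell; secondary chosen so ratio is exact
  H <- 30L; W <- 30L
  cells <- matrix(1L, H, W)
  lab <- matrix(0L, H, W); lab[14:16, 14:16] <- 1L
  smap <- structure(list(labels = lab, mode = "punctum", owner = 1L),
                    class = "structure_map")
  sec_for_ratio <- function(ratio) {
    s <- matrix(100, H, W); s[lab == 1L] <- 100 * ratio; s
  }
  fv <- function(s) field_of_view(list(primary = s, secondary = s),
                                  condition = "c", well = "w", site = "s")
  at <- score_structure_positivity(fv(sec_for_ratio(1.25)), cells, smap)
  expect_equal(at$ratio, 1.25)
  expect_false(at$positive)            # strictly greater than 1.25 required
  expect_false(score_structure_positivity(fv(sec_for_ratio(1.0)),
                                          cells, smap)$positive)
  expect_true(score_structure_positivity(fv(sec_for_ratio(1.2500001)),
                                         cells, smap)$positive)
})

test_that("structures with no surrounding region are flagged unscorable", {
  H <- 20L; W <- 20L
  cells <- matrix(0L, H, W); cells[8:12, 8:12] <- 1L
  lab <- matrix(0L, H, W); lab[8:12, 8:12] <- 1L  # structure fills the cell
  smap <- structure(list(labels = lab, mode = "focus", owner = 1L),
                    class = "structure_map")
  s <- matrix(50, H, W)
  fv <- field_of_view(list(primary = s, secondary = s),
                      condition = "c", well = "w", site = "s")
  out <- score_structure_positivity(fv, cells, smap, dilation_radius = 3)
  expect_false(out$scorable)
  expect_true(is.na(out$ratio))
})

test_that("positivity fractions distinguish structure- and cell-level rates", {
  tab <- data.frame(condition = "c", well = "w1", site = "s1",
                    cell = c(1L, 1L, 1L), structure = 1:3, mode = "punctum",
                    area = 9L, structure_mean = 1, region_mean = 1,
                    ratio = c(2, 1, 1), positive = c(TRUE, FALSE, FALSE),
                    scorable = TRUE)
  pf <- suppressWarnings(positivity_fractions(tab))
  s <- pf$site
  expect_equal(s$value[s$statistic == "fraction_structures_positive"], 1 / 3)
  expect_equal(s$value[s$statistic == "fraction_cells_positive"], 1)
  tab$positive <- TRUE
  pf2 <- suppressWarnings(positivity_fractions(tab))
  expect_true(all(pf2$site$value == 1))
  tab$scorable <- FALSE
  expect_error(suppressWarnings(positivity_fractions(tab)), "no site")
})

test_that("dispersion profile is exactly 1 for uniform cells", {
  mask <- matrix(FALSE, 40, 40); mask[8:32, 8:32] <- TRUE
  ch <- matrix(0, 40, 40); ch[mask] <- 7.5
  prof <- dispersion_profile_cell(ch, mask)
  expect_true(all(abs(prof$value - 1) < 1e-12))
  expect_equal(sum(prof$n_pixels), sum(mask))
})

test_that("a point mass yields ring 0 = cell area and empty elsewhere", {
  mask <- matrix(FALSE, 30, 30); mask[10:20, 10:20] <- TRUE
  ch <- matrix(0, 30, 30); ch[15, 15] <- 123
  prof <- dispersion_profile_cell(ch, mask)
  area <- sum(mask)
  expect_equal(prof$value[prof$distance == 0], area)
  expect_true(all(prof$value[prof$distance > 0] == 0))
})

test_that("cells below the structure-pixel gate or without signal are skipped", {
  mask <- matrix(FALSE, 20, 20); mask[5:15, 5:15] <- TRUE
  ch <- matrix(0, 20, 20); ch[mask] <- 3
  smask <- matrix(0L, 20, 20); smask[10, 10:12] <- 1L  # 3 px < gate of 5
  expect_null(dispersion_profile_cell(ch, mask, smask, min_structure_pixels = 5))
  expect_warning(
    expect_null(dispersion_profile_cell(matrix(0, 20, 20), mask)),
    "zero total intensity")
})

test_that("ring averaging equals the brute-force per-pixel loop", {
  sc <- generate_scene(scene_spec(n_cells = 3L, seed = 21))
  cfg <- default_cfg
  pr <- process_scene(sc, cfg)
  for (k in seq_len(max(pr$cells))) {
    mask <- pr$cells == k
    fast <- dispersion_profile_cell(pr$fv$channels$primary, mask)
    slow <- brute_dispersion(pr$fv$channels$primary, mask)
    expect_identical(fast$value, slow$value)
    expect_identical(fast$distance, slow$distance)
  }
})

test_that("well and condition dispersion aggregation uses ring-wise medians", {
  prof <- function(well, cell, values)
    data.frame(condition = "c", well = well, site = "s1", cell = cell,
               distance = seq_along(values) - 1L, value = values,
               n_pixels = 10L)
  cells <- rbind(prof("w1", 1, c(0.5, 0.5)), prof("w1", 2, c(1.0, 1.0)),
                 prof("w1", 3, c(4.0, 4.0)))
  agg <- aggregate_dispersion(cells)
  expect_true(all(agg$well$value == 1.0))  # median of (0.5, 1, 4)
  # identical profiles in every cell pass through unchanged
  same <- rbind(prof("w1", 1, c(2, 1)), prof("w1", 2, c(2, 1)))
  expect_equal(aggregate_dispersion(same)$well$value, c(2, 1))
  # rings are aggregated only over cells that possess them
  ragged <- rbind(prof("w1", 1, c(1, 2, 3)), prof("w1", 2, c(1, 2)))
  aw <- aggregate_dispersion(ragged)$well
  expect_equal(aw$value[aw$distance == 2], 3)
})

test_that("aggregation is invariant to row order", {
  set.seed(31)
  prof <- data.frame(condition = "c",
                     well = sample(c("w1", "w2"), 60, TRUE),
                     site = "s1", cell = sample(1:5, 60, TRUE),
                     distance = sample(0:5, 60, TRUE), value = runif(60),
                     n_pixels = 5L)
  prof <- prof[!duplicated(prof[, c("well", "cell", "distance")]), ]
  a <- aggregate_dispersion(prof)
  b <- aggregate_dispersion(prof[sample(nrow(prof)), ])
  expect_equal(a$well, b$well)
  expect_equal(a$condition, b$condition)
})

test_that("peak statistics follow the tie and half-max rules", {
  flat <- profile_peak_stats(c(1, 1, 1))
  expect_equal(flat$peak_value, 1)
  expect_equal(flat$peak_distance, 0L)
  expect_equal(flat$halfmax_width, 3L)
  sharp <- profile_peak_stats(c(0.2, 3.0, 0.4))
  expect_equal(sharp$peak_value, 3.0)
  expect_equal(sharp$peak_distance, 1L)
  expect_equal(sharp$halfmax_width, 1L)
  mono <- profile_peak_stats(c(5, 4, 3, 2, 1))
  expect_equal(mono$peak_distance, 0L)
  expect_equal(mono$halfmax_width, 3L)  # 5, 4, 3 >= 2.5
  df <- data.frame(distance = c(3L, 1L, 2L), value = c(0.4, 0.2, 3.0))
  expect_equal(profile_peak_stats(df)$peak_distance, 2L)
})
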