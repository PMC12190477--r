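#' Construct a field of view
#'
#' A field of view is a registered set of same-shape 2D channel matrices with
#' role labels and plate coordinates. The `primary` channel (the structure
#' channel, e.g. a fluorescent LC3B fusion) is mandatory; `secondary` (an
#' immunostained marker) and `nuclear` (a DNA dye) are optional. Pixel values
#' are nonnegative intensities; integer input is stored as double without
#' rescaling. Pixel coordinates throughout the package are 0-based
#' (row, column) and distances are in pixel units.
#'
#' @param channels named list of numeric matrices; names from
#'   `primary`, `secondary`, `nuclear`.
#' @param condition,well,site plate coordinates (character or NA).
#' @return An object of class `fov`.
#' @export
field_of_view <- function(channels, condition = NA_character_,
                          well = NA_character_, site = NA_character_) {
  if (!is.list(channels) || is.null(names(channels)))
    stop("channels must be a named list of matrices")
  bad <- setdiff(names(channels), c("primary", "secondary", "nuclear"))
  if (length(bad)) stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  if (!"primary" %in% names(channels)) stop("primary channel is required")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, TRUE)))
    stop("all channels must be 2D matrices")
  ref <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, ref), TRUE)))
    stop("all channel arrays must share one shape")
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  structure(list(channels = channels, condition = condition, well = well,
                 site = site),
            class = "fov")
}

#' @export
print.fov <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<fov %s/%s/%s: %dx%d px, channels: %s>\n",
              x$condition, x$well, x$site, d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# 16-bit TIFF round trip: intensities are rounded to integer counts on write
# and read back unscaled.
write_channel_tiff <- function(mat, path) {
  m <- pmin(pmax(round(mat), 0), 65535)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

read_channel_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]  # tolerate gray stored with extra plane
  storage.mode(m) <- "double"
  m
}

#' Write a synthetic plate to disk
#'
#' Writes one 16-bit TIFF per channel per scene under
#' `root/<condition>/<well>/<site>_<role>.tif`, the planted structure table
#' and label masks per scene, a YAML scene spec, and a plate `manifest.yaml`
#' that [load_plate()] understands.
#'
#' @param scenes output of [generate_plate()].
#' @param root output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_plate <- function(scenes, root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  fovs <- list()
  for (scene in scenes) {
    fv <- scene$fov
    d <- file.path(root, fv$condition, fv$well)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (role in names(fv$channels))
      write_channel_tiff(fv$channels[[role]],
                         file.path(d, sprintf("%s_%s.tif", fv$site, role)))
    if (!is.null(scene$truth)) {
      tr <- scene$truth
      write_result_csv(tr$structures,
                       file.path(d, sprintf("%s_groundtruth.csv", fv$site)))
      write_channel_tiff(tr$cell_masks, file.path(d, sprintf("%s_cellmask.tif", fv$site)))
      write_channel_tiff(tr$nucleus_masks, file.path(d, sprintf("%s_nucmask.tif", fv$site)))
      yaml::write_yaml(unclass(tr$spec), file.path(d, sprintf("%s_spec.yaml", fv$site)))
    }
    fovs[[length(fovs) + 1L]] <- list(condition = fv$condition, well = fv$well,
                                      site = fv$site)
  }
  manifest <- list(
    channels = list(primary = "{condition}/{well}/{site}_primary.tif",
                    secondary = "{condition}/{well}/{site}_secondary.tif",
                    nuclear = "{condition}/{well}/{site}_nuclear.tif"),
    optional_channels = c("secondary", "nuclear"),
    fovs = fovs)
  path <- file.path(root, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

fill_template <- function(template, condition, well, site) {
  out <- gsub("{condition}", condition, template, fixed = TRUE)
  out <- gsub("{well}", well, out, fixed = TRUE)
  gsub("{site}", site, out, fixed = TRUE)
}

#' Load a plate of fields of view from a manifest
#'
#' The YAML manifest maps channel roles to path templates containing
#' `{condition}`, `{well}` and `{site}` placeholders, lists which roles are
#' optional, and enumerates the fields of view. A field entry may also carry
#' an explicit `files:` mapping overriding the templates.
#'
#' @param manifest path to the manifest YAML.
#' @param root directory against which relative paths resolve; defaults to the
#'   manifest's directory.
#' @return Named list of [field_of_view()] objects.
#' @export
load_plate <- function(manifest, root = dirname(manifest)) {
  mf <- yaml::read_yaml(manifest)
  if (is.null(mf$channels) || is.null(mf$channels$primary))
    stop("manifest must map the primary channel role to a file pattern")
  if (is.null(mf$fovs) || length(mf$fovs) == 0L)
    stop("manifest lists no fields of view")
  optional <- unlist(mf$optional_channels)
  out <- list()
  for (fv in mf$fovs) {
    cd <- fv$condition; wl <- fv$well; st <- fv$site
    if (is.null(cd) || is.null(wl) || is.null(st))
      stop("each fov entry needs condition, well and site")
    channels <- list()
    for (role in names(mf$channels)) {
      rel <- if (!is.null(fv$files[[role]])) fv$files[[role]]
             else fill_template(mf$channels[[role]], cd, wl, st)
      path <- file.path(root, rel)
      if (!file.exists(path)) {
        if (role == "primary" || !(role %in% optional))
          stop(sprintf("missing %s channel file for (%s, %s, %s): %s",
                       role, cd, wl, st, path))
        next
      }
      channels[[role]] <- read_channel_tiff(path)
    }
    dims <- lapply(channels, dim)
    if (!all(vapply(dims, function(d) identical(d, dims[[1]]), TRUE)))
      stop(sprintf("channel shape mismatch for (%s, %s, %s)", cd, wl, st))
    out[[paste(cd, wl, st, sep = "/")]] <-
      field_of_view(channels, condition = cd, well = wl, site = st)
  }
  out
}

# CSV writer with a commented metadata header and full-precision numerics.
# Doubles are printed with "%.17g" so read -> write -> read is exact.
write_result_csv <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# focusq %s", as.character(packageVersion("focusq"))), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  fmt <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) fmt <- df
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0L)
    write.table(fmt, con, sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  invisible(path)
}

#' Read a result CSV written by this package
#'
#' Skips the commented metadata header and re-parses numerics at full
#' precision, so `read_result_csv(write_results(...))` reproduces every
#' numeric field exactly.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_result_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a set of result tables
#'
#' Writes each table as `<name>.csv` under `out`, each with a commented
#' run-metadata header (package version plus any supplied metadata such as
#' the run's config hash). Column order is the data frame's column order and
#' is stable across runs.
#'
#' @param tables named list of data frames.
#' @param out output directory (created if needed).
#' @param meta named list of metadata strings for the header.
#' @return Named character vector of file paths, invisibly.
#' @export
write_results <- function(tables, out, meta = list()) {
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out, paste0(nm, ".csv"))
    write_result_csv(tables[[nm]], p, meta = meta)
    paths[nm] <- p
  }
  invisible(paths)
}
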