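#' Read and write ESRI ASCII grids
#'
#' Human-diffable raster I/O for landscape grids.  The on-disk row order is
#' top-down as the format prescribes; in memory row 1 is the bottom of the
#' landscape (y = 0), so rows are flipped on the way in and out.
#' `NODATA_value` is -9999.
#'
#' @param grid Numeric, integer or logical matrix.
#' @param path File path (`.asc`).
#' @param cellsize Cell size written to the header (default 1).
#' @return `write_asc()` returns `path` invisibly; `read_asc()` returns a
#'   numeric matrix.
#' @export
write_asc <- function(grid, path, cellsize = 1) {
  stopifnot(is.matrix(grid))
  m <- grid
  if (is.logical(m)) m <- m * 1L
  m[is.na(m)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %s", format(cellsize)),
    "NODATA_value -9999"), con)
  for (i in rev(seq_len(nrow(m))))
    writeLines(paste(format(m[i, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  ncols <- as.integer(vals[["ncols"]]); nrows <- as.integer(vals[["nrows"]])
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != ncols * nrows)
    stop(sprintf("expected %d values, found %d in '%s'",
                 ncols * nrows, length(body), path), call. = FALSE)
  m <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrows)), , drop = FALSE]  # bottom row = y 0
  m[m == nodata] <- NA
  m
}

#' Write a landscape to a set of ESRI ASCII rasters
#'
#' Writes `<prefix>_habitat.asc`, `<prefix>_patch_id.asc`,
#' `<prefix>_quality.asc`, `<prefix>_forage.asc` and a patch table
#' `<prefix>_patches.csv` (`patch_id`, `size_cells`, `n_edge_cells`).
#'
#' @param landscape A `dispersim_landscape`.
#' @param prefix Output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_landscape <- function(landscape, prefix) {
  stopifnot(inherits(landscape, "dispersim_landscape"))
  files <- c(habitat = paste0(prefix, "_habitat.asc"),
             patch_id = paste0(prefix, "_patch_id.asc"),
             quality = paste0(prefix, "_quality.asc"),
             forage = paste0(prefix, "_forage.asc"),
             patches = paste0(prefix, "_patches.csv"))
  write_asc(landscape$habitat_mask, files[["habitat"]])
  write_asc(landscape$patch_id, files[["patch_id"]])
  write_asc(round(landscape$quality, 6), files[["quality"]])
  write_asc(landscape$forage_mask, files[["forage"]])
  n_edge <- vapply(seq_along(landscape$patch_sizes), function(l)
    nrow(edge_cells(landscape$patch_id, l)), integer(1))
  write_results(data.frame(patch_id = seq_along(landscape$patch_sizes),
                           size_cells = landscape$patch_sizes,
                           n_edge_cells = n_edge),
                files[["patches"]])
  invisible(files)
}

#' Read a landscape from a habitat raster
#'
#' Builds a `dispersim_landscape` from a 0/1 habitat grid in ESRI ASCII
#' format (patches relabelled, no forage cells unless a quality raster is
#' supplied alongside).
#'
#' @param path Habitat raster path.
#' @param connectivity Patch connectivity (default 8).
#' @param forage_fraction Fraction of matrix cells classed as forage when a
#'   `_quality.asc` companion raster exists (default 0.15).
#' @return A `dispersim_landscape`.
#' @export
read_landscape <- function(path, connectivity = 8L, forage_fraction = 0.15) {
  m <- read_asc(path)
  mask <- !is.na(m) & m != 0
  lab <- label_patches(mask, connectivity)
  qpath <- sub("_habitat\\.asc$", "_quality.asc", path)
  quality <- matrix(0, nrow(mask), ncol(mask))
  fmask <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!identical(qpath, path) && file.exists(qpath)) {
    quality <- read_asc(qpath)
    quality[is.na(quality)] <- 0
    fmask <- forage_mask(quality, mask, forage_fraction)
  }
  structure(list(habitat_mask = mask, patch_id = lab$patch_id,
                 patch_sizes = lab$patch_sizes, quality = quality,
                 forage_mask = fmask, params = NULL),
            class = "dispersim_landscape")
}
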