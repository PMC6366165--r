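#' Landscape generation parameters
#'
#' Bundles the controls of the neutral landscape generator: grid size, the
#' fraction of cells that are suitable habitat (`hab_amount`, the habitat
#' amount HABAMT expressed as a fraction), the degree of spatial clustering
#' of habitat (`hab_agg`, HABAGG), the number of local-averaging passes
#' applied to the matrix forage-quality field, and the fraction of matrix
#' cells classed as forage patches.
#'
#' @param width,height Grid dimensions in cells (default 100 x 100).
#' @param hab_amount Fraction of the landscape that is habitat, in
#'   (0, 1); the study design uses 0.05--0.50.
#' @param hab_agg Habitat aggregation in `[0, 1]`; 0 scatters habitat cells
#'   at random, values near 1 grow large contiguous patches.
#' @param smoothing_passes Non-negative number of local-averaging passes
#'   applied to the uniform forage-quality seed field (default 3).
#' @param forage_fraction Fraction of matrix cells classed as forage
#'   patches (default 0.15, the top 15\% of matrix quality).
#' @param connectivity Patch connectivity, 8 (Moore, default) or 4.
#' @param method Habitat placement strategy.  `"blob"` (default) lays out
#'   a mosaic of compact patches whose sizes are exponentially distributed
#'   with a mean that grows geometrically with `hab_agg`, separated by a
#'   matrix buffer -- the discrete patch/matrix structure the dispersal
#'   model assumes.  `"cluster"` is a modified-random-cluster percolation
#'   generator; `"sequential"` places cells one at a time with probability
#'   `hab_agg` of attaching to the Moore frontier of existing habitat.
#' @return A `landscape_params` list.
#' @export
landscape_params <- function(width = 100L, height = 100L,
                             hab_amount = 0.2, hab_agg = 0.5,
                             smoothing_passes = 3L,
                             forage_fraction = 0.15,
                             connectivity = 8L,
                             method = c("blob", "cluster", "sequential")) {
  method <- match.arg(method)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 3L || height < 3L)
    stop("grid must be at least 3 x 3 cells", call. = FALSE)
  if (!is.finite(hab_amount) || hab_amount <= 0 || hab_amount >= 1)
    stop("`hab_amount` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.finite(hab_agg) || hab_agg < 0 || hab_agg > 1)
    stop("`hab_agg` must lie in [0, 1]", call. = FALSE)
  if (smoothing_passes < 0)
    stop("`smoothing_passes` must be non-negative", call. = FALSE)
  if (!is.finite(forage_fraction) || forage_fraction <= 0 || forage_fraction >= 1)
    stop("`forage_fraction` must lie strictly between 0 and 1", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  structure(list(width = width, height = height,
                 hab_amount = hab_amount, hab_agg = hab_agg,
                 smoothing_passes = as.integer(smoothing_passes),
                 forage_fraction = forage_fraction,
                 connectivity = as.integer(connectivity),
                 method = method),
            class = "landscape_params")
}

#' Generate a binary habitat mask
#'
#' Places exactly `round(hab_amount * width * height)` habitat cells.
#'
#' The default `"blob"` strategy emulates a fragmented mosaic of discrete
#' habitat patches embedded in a matrix: patch sizes are drawn from an
#' exponential distribution whose mean rises geometrically from one cell at
#' `hab_agg = 0` to `N/25` cells at `hab_agg = 0.75`
#' (`N` = grid cells), each capped at half the habitat budget so at least
#' two patches always exist; patches are grown as compact blobs (uniform
#' frontier accretion) around uniform random seeds, keeping a two-cell
#' buffer of matrix between patches until space runs out.  At
#' `hab_agg = 0` habitat is single-cell dust; as `hab_agg` rises the
#' mosaic coarsens into fewer, larger, more widely spaced patches, so both
#' mean patch size and mean inter-patch distance increase monotonically
#' with `hab_agg`.
#'
#' `"cluster"` is a modified-random-cluster generator (Bernoulli(`hab_agg`)
#' seed percolation, Moore-labelled clusters assigned in random order to
#' the exact count, the last truncated to a connected subset).
#' `"sequential"` places cells one at a time, drawing from the empty Moore
#' neighbours of existing habitat with probability `hab_agg` and uniformly
#' otherwise.  All strategies hit the exact habitat count for every
#' parameter combination.
#'
#' @param params A [landscape_params()] object.
#' @return A logical `height` x `width` matrix; row 1 is the bottom of the
#'   landscape (y = 0), columns index x.
#' @export
generate_habitat <- function(params) {
  stopifnot(inherits(params, "landscape_params"))
  n_hab <- round(params$hab_amount * params$width * params$height)
  switch(params$method %||% "blob",
    sequential = generate_habitat_cpp(params$width, params$height, n_hab,
                                      params$hab_agg),
    cluster = generate_habitat_cluster_cpp(params$width, params$height,
                                           n_hab, params$hab_agg),
    generate_habitat_blob_cpp(params$width, params$height, n_hab,
                              params$hab_agg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label habitat patches
#'
#' Connected-component labelling of a boolean habitat mask.  Labels are
#' contiguous from 1 in scan order; 0 marks matrix cells.
#'
#' @param mask Logical matrix (habitat = `TRUE`).
#' @param connectivity 8 (Moore, default) or 4 (von Neumann).
#' @return List with `patch_id` (integer matrix) and `patch_sizes`
#'   (integer vector indexed by label).
#' @export
label_patches <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  label_patches_cpp(mask, as.integer(connectivity))
}

#' Smoothed matrix forage-quality field
#'
#' Seeds every cell with an independent Uniform(0, 1) deviate and applies
#' `passes` rounds of local averaging over each cell's Moore neighbourhood
#' (self + 8 neighbours) with toroidal wrap, so the landscape-wide mean --
#' the total amount of food resources -- is conserved exactly while the
#' spatial grain coarsens.
#'
#' @param params A [landscape_params()] object (uses `width`, `height`,
#'   `smoothing_passes`).
#' @param passes Optional override of `params$smoothing_passes`.
#' @return Numeric `height` x `width` matrix in `[0, 1]`.
#' @export
smooth_quality <- function(params, passes = params$smoothing_passes) {
  stopifnot(inherits(params, "landscape_params"), passes >= 0)
  q <- matrix(stats::runif(params$width * params$height),
              nrow = params$height, ncol = params$width)
  for (i in seq_len(passes)) q <- moore_mean_torus(q)
  q
}

# Mean over the 3 x 3 Moore neighbourhood with toroidal wrap, vectorized
# via row/column rotations.  Exactly mean-preserving.
moore_mean_torus <- function(q) {
  up <- function(m) m[c(nrow(m), seq_len(nrow(m) - 1L)), , drop = FALSE]
  down <- function(m) m[c(seq_len(nrow(m) - 1L) + 1L, 1L), , drop = FALSE]
  left <- function(m) m[, c(seq_len(ncol(m) - 1L) + 1L, 1L), drop = FALSE]
  right <- function(m) m[, c(ncol(m), seq_len(ncol(m) - 1L)), drop = FALSE]
  (q + up(q) + down(q) + left(q) + right(q) +
     up(left(q)) + up(right(q)) + down(left(q)) + down(right(q))) / 9
}

#' Select forage patches from the matrix quality field
#'
#' Marks the top `fraction` of matrix cells (habitat cells excluded) by
#' forage quality; exactly `round(fraction * n_matrix)` cells are chosen.
#' Ties are broken deterministically by scan order (ascending row, then
#' column).
#'
#' @param quality Numeric quality matrix.
#' @param habitat_mask Logical habitat matrix of the same shape.
#' @param fraction Fraction of matrix cells to select, in (0, 1).
#' @return Logical matrix, `TRUE` on forage cells (all matrix cells).
#' @export
forage_mask <- function(quality, habitat_mask, fraction = 0.15) {
  stopifnot(is.matrix(quality), is.matrix(habitat_mask),
            all(dim(quality) == dim(habitat_mask)))
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  # scan order: row-major over (row, col); matrices are column-major so
  # order on (row, col) explicitly
  idx <- which(!habitat_mask)
  n_sel <- round(fraction * length(idx))
  out <- matrix(FALSE, nrow(quality), ncol(quality))
  if (n_sel == 0L) return(out)
  rows <- (idx - 1L) %% nrow(quality)
  cols <- (idx - 1L) %/% nrow(quality)
  ord <- order(-quality[idx], rows, cols)
  out[idx[ord[seq_len(n_sel)]]] <- TRUE
  out
}

#' Edge cells of a habitat patch
#'
#' Cells of the patch with at least one Moore neighbour outside the patch
#' (cells on the grid border count as edge).
#'
#' @param patch_id Integer patch-label matrix.
#' @param label Patch label (>= 1).
#' @return Two-column integer matrix of 0-based `(ix, iy)` cell indices.
#' @export
edge_cells <- function(patch_id, label) {
  stopifnot(is.matrix(patch_id))
  if (!any(patch_id == label))
    stop("no patch with label ", label, call. = FALSE)
  edge_cells_cpp(patch_id, as.integer(label))
}

#' Generate a complete landscape
#'
#' Runs the full landscape pipeline: habitat placement, patch labelling,
#' matrix-quality smoothing and forage-patch selection.
#'
#' @param params A [landscape_params()] object.
#' @param seed Optional integer seed; when supplied the landscape is a pure
#'   function of `(params, seed)`.
#' @return A `dispersim_landscape` object: list with `habitat_mask`,
#'   `patch_id`, `patch_sizes`, `quality`, `forage_mask`, `params`.
#' @examples
#' land <- generate_landscape(landscape_params(hab_amount = 0.2), seed = 1)
#' sum(land$habitat_mask)  # exactly 2000 cells
#' @export
generate_landscape <- function(params = landscape_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mask <- generate_habitat(params)
  lab <- label_patches(mask, params$connectivity)
  quality <- smooth_quality(params)
  quality[mask] <- 0  # forage quality is a matrix-cell property
  fmask <- forage_mask(quality, mask, params$forage_fraction)
  structure(list(habitat_mask = mask,
                 patch_id = lab$patch_id,
                 patch_sizes = lab$patch_sizes,
                 quality = quality,
                 forage_mask = fmask,
                 params = params),
            class = "dispersim_landscape")
}

#' @export
print.dispersim_landscape <- function(x, ...) {
  cat(sprintf("dispersim landscape: %d x %d cells, %d habitat cells (%.1f%%), %d patches\n",
              x$params$width, x$params$height, sum(x$habitat_mask),
              100 * mean(x$habitat_mask), length(x$patch_sizes)))
  cat(sprintf("  patch sizes: min %d, median %.0f, max %d; %d forage cells\n",
              min(x$patch_sizes), stats::median(x$patch_sizes),
              max(x$patch_sizes), sum(x$forage_mask)))
  invisible(x)
}

# Assemble a landscape object from explicit grids (used by fixtures and
# .asc import); patch sizes are recomputed from patch_id.
landscape_from_grids <- function(patch_id, forage = NULL, quality = NULL,
                                 params = NULL) {
  stopifnot(is.matrix(patch_id))
  mask <- patch_id > 0
  labs <- sort(unique(patch_id[mask]))
  if (length(labs) && !identical(as.integer(labs), seq_along(labs)))
    stop("patch labels must be contiguous from 1", call. = FALSE)
  sizes <- as.integer(tabulate(patch_id[mask], nbins = length(labs)))
  if (is.null(forage)) forage <- matrix(FALSE, nrow(patch_id), ncol(patch_id))
  if (is.null(quality)) quality <- matrix(0, nrow(patch_id), ncol(patch_id))
  structure(list(habitat_mask = mask,
                 patch_id = patch_id,
                 patch_sizes = sizes,
                 quality = quality,
                 forage_mask = forage,
                 params = params),
            class = "dispersim_landscape")
}
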