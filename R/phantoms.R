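#' Deterministic fractal phantoms of known dimension
#'
#' Validation objects for the box-counting estimator:
#' * `menger` — level-L Menger sponge on a `3^L` grid (dimension
#'   `log(20)/log(3)`; exactly `20^L` filled voxels),
#' * `cube` — solid cube filling a `size^3` grid (dimension 3),
#' * `shell` — one-voxel-thick hollow shell of a `size^3` cube
#'   (dimension 2),
#' * `line` — straight 1-voxel-wide line of length `size` in a `size^3`
#'   grid (dimension 1).
#'
#' @param kind phantom type.
#' @param level Menger recursion level (1..5; the grid is `3^level` per
#'   side).
#' @param size edge length for `cube`, `shell` and `line`.
#' @return a [voxel_mask()] with attribute `analytic_dim`, the phantom's
#'   exact dimension.
#' @export
gen_fractal_phantom <- function(kind = c("menger", "cube", "shell", "line"),
                                level = 3L, size = 64L) {
  kind <- match.arg(kind)
  if (kind == "menger") {
    level <- as.integer(level)
    if (level < 1L) stop("menger level must be >= 1", call. = FALSE)
    if (level > 5L)
      stop("menger level > 5 refused (grid would exceed 243^3)",
           call. = FALSE)
    n <- 3L^level
    coord <- 0:(n - 1L)
    keep_axis <- function(v) {
      # digit at each base-3 position, flagged when == 1
      out <- matrix(FALSE, length(v), level)
      for (l in seq_len(level)) out[, l] <- (v %/% 3L^(l - 1L)) %% 3L == 1L
      out
    }
    dx <- keep_axis(coord); dy <- keep_axis(coord); dz <- keep_axis(coord)
    g <- array(1L, dim = c(n, n, n))
    for (l in seq_len(level)) {
      # a subcube is removed when >= 2 of its 3 digits equal 1 at any level
      mid <- outer(outer(dx[, l], dy[, l], `+`), dz[, l], `+`)
      g[mid >= 2] <- 0L
    }
    m <- voxel_mask(g)
    attr(m, "analytic_dim") <- log(20) / log(3)
    return(m)
  }
  size <- as.integer(size)
  stopifnot(size >= 2L)
  if (kind == "cube") {
    m <- voxel_mask(array(1L, dim = c(size, size, size)))
    attr(m, "analytic_dim") <- 3
  } else if (kind == "shell") {
    g <- array(1L, dim = c(size, size, size))
    if (size > 2L)
      g[2:(size - 1L), 2:(size - 1L), 2:(size - 1L)] <- 0L
    m <- voxel_mask(g)
    attr(m, "analytic_dim") <- 2
  } else {
    g <- array(0L, dim = c(size, size, size))
    g[, 1L, 1L] <- 1L
    m <- voxel_mask(g)
    attr(m, "analytic_dim") <- 1
  }
  m
}

#' Pad a mask with background
#'
#' Shifts the object away from the array corner without changing it; used
#' to check translation robustness of the FD estimate.
#'
#' @param mask a [voxel_mask()] or array.
#' @param pad non-negative integer layers of background added on each side
#'   of each axis.
#' @return padded [voxel_mask()].
#' @export
pad_mask <- function(mask, pad = 1L) {
  m <- as_voxel_mask(mask)
  pad <- as.integer(pad)
  stopifnot(pad >= 0L)
  d <- dim(m$grid)
  g <- array(0L, d + 2L * pad)
  g[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    m$grid
  voxel_mask(g, spacing = m$spacing)
}

#' Synthetic multi-region blob label map
#'
#' A stand-in for a warped whole-brain parcellation: `n_regions` disjoint
#' blobs grown around jittered lattice seeds (each voxel belongs to its
#' nearest seed, within a radius). The `roughness` parameter perturbs each
#' region's boundary with seeded per-voxel noise; larger roughness yields
#' more irregular boundaries and hence larger measured boundary FD.
#'
#' @param n_regions number of regions (labels 1..n_regions).
#' @param grid_size cubic grid edge length.
#' @param seed RNG seed; the output is a pure function of the arguments.
#' @param roughness boundary perturbation amplitude in voxels (>= 0).
#' @param label_table optional region names; defaults to `region_001` ...
#'   (or [aal90_labels()] names when `n_regions == 90`).
#' @return an [roi_labelmap()].
#' @export
gen_blob_labelmap <- function(n_regions = 90L, grid_size = 96L, seed = 1L,
                              roughness = 0, label_table = NULL) {
  n_regions <- as.integer(n_regions)
  grid_size <- as.integer(grid_size)
  stopifnot(n_regions >= 1L, roughness >= 0)
  cells <- ceiling(n_regions^(1 / 3))
  cell <- grid_size / cells
  if (cell < 4)
    stop("overcrowded grid: fewer than 4 voxels per region cell",
         call. = FALSE)
  set.seed(seed)
  # seed centres on a jittered lattice, one cell per region
  slots <- utils::head(as.matrix(expand.grid(x = seq_len(cells),
                                             y = seq_len(cells),
                                             z = seq_len(cells))),
                       n_regions)
  centres <- (slots - 0.5) * cell +
    matrix(stats::runif(3 * n_regions, -cell / 8, cell / 8), ncol = 3)
  radius <- 0.38 * cell
  ax <- seq_len(grid_size) - 0.5
  gx <- array(ax, rep(grid_size, 3))
  gy <- aperm(gx, c(2, 1, 3))
  gz <- aperm(gx, c(3, 2, 1))
  dmin <- array(Inf, rep(grid_size, 3))
  lab <- array(0L, rep(grid_size, 3))
  for (i in seq_len(n_regions)) {
    d2 <- (gx - centres[i, 1])^2 + (gy - centres[i, 2])^2 +
      (gz - centres[i, 3])^2
    upd <- d2 < dmin
    dmin[upd] <- d2[upd]
    lab[upd] <- i
  }
  thr <- radius + if (roughness > 0)
    roughness * array(stats::rnorm(grid_size^3), rep(grid_size, 3))
  else 0
  lab[sqrt(dmin) > thr] <- 0L
  if (is.null(label_table)) {
    label_table <- if (n_regions == 90L) aal90_labels()
    else data.frame(label = seq_len(n_regions),
                    region = sprintf("region_%03d", seq_len(n_regions)))
  }
  roi_labelmap(lab, label_table = label_table)
}
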