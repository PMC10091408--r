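# 3D ion density maps on cubic grids over the box, after per-frame rigid
# superposition onto a reference, and 2D concentration maps projected onto the
# x-y plane through a chosen z-slab. Imaging is orthorhombic minimum-image:
# ions are wrapped to the cell centred on the RNA centroid after fitting.

#' 3D ion density grid
#'
#' Each frame is least-squares superposed (Kabsch) onto the reference using
#' the fit selection; ion positions are transformed along, re-imaged to the
#' primary cell centred on the fitted RNA centroid, and accumulated on a cubic
#' grid spanning the reference box.
#'
#' @param traj an `rna_traj`.
#' @param ions ion selection.
#' @param reference reference model (defaults to the trajectory topology);
#'   must carry a box.
#' @param fit selection of atoms used for superposition (>= 3 non-collinear).
#' @param spacing cubic voxel edge (Angstrom).
#' @return object of class `density_grid` with `origin`, `spacing`, `counts`
#'   (3D array of ion observations), `n_frames` and `n_in_grid`.
#' @export
density3d <- function(traj, ions = "ions", reference = NULL, fit = "nucleic",
                      spacing = 1) {
  reference <- reference %||% traj$topology
  if (is.null(reference$box)) stop("density grid needs a reference box")
  if (spacing <= 0) stop("grid spacing must be positive")
  top <- traj$topology
  ion_idx <- select_atoms(top, ions)
  fit_idx <- select_atoms(top, fit)
  if (length(fit_idx) < 3) stop("fit selection needs at least 3 atoms")
  ref_fit <- coords(reference)[select_atoms(reference, fit), , drop = FALSE]
  if (nrow(ref_fit) != length(fit_idx))
    stop("fit selection resolves differently on reference and topology")
  # Degenerate (collinear) fit sets give an ill-conditioned covariance.
  sv <- svd(sweep(ref_fit, 2, colMeans(ref_fit)))$d
  if (sv[2] < 1e-6) stop("degenerate fit selection: atoms are collinear")
  box <- reference$box
  dims <- pmax(1L, as.integer(ceiling(box / spacing)))
  counts <- array(0L, dim = dims)
  center <- colMeans(ref_fit)
  n_in <- 0L
  for (k in seq_along(traj$frames)) {
    xyz <- traj$frames[[k]]
    fitk <- kabsch(xyz[fit_idx, , drop = FALSE], ref_fit)
    ion_xyz <- sweep(xyz[ion_idx, , drop = FALSE] %*% t(fitk$R), 2, fitk$t, "+")
    # minimum-image wrap to the cell centred on the RNA centroid
    for (ax in 1:3) {
      ion_xyz[, ax] <- ion_xyz[, ax] -
        box[ax] * round((ion_xyz[, ax] - center[ax]) / box[ax])
    }
    v <- floor(sweep(ion_xyz, 2, c(0, 0, 0)) / spacing) + 1
    ok <- v[, 1] >= 1 & v[, 1] <= dims[1] &
          v[, 2] >= 1 & v[, 2] <= dims[2] &
          v[, 3] >= 1 & v[, 3] <= dims[3]
    v <- v[ok, , drop = FALSE]
    n_in <- n_in + nrow(v)
    if (nrow(v) > 0) {
      lin <- (v[, 3] - 1) * dims[1] * dims[2] + (v[, 2] - 1) * dims[1] + v[, 1]
      tab <- tabulate(lin, nbins = prod(dims))
      counts <- counts + array(tab, dim = dims)
    }
  }
  structure(list(origin = c(0, 0, 0), spacing = spacing, counts = counts,
                 box = box, n_frames = length(traj$frames), n_in_grid = n_in),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d x %d voxels at %.2f A, %d frames, %d observations\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              x$spacing, x$n_frames, x$n_in_grid))
  invisible(x)
}

#' Project a density grid onto the x-y plane
#'
#' Sums voxel counts over the z-slabs whose centres fall inside `z_window`
#' and converts to a 2D concentration map (mol/L per column cell, averaged
#' over frames).
#'
#' @param grid a `density_grid`.
#' @param z_window numeric length-2 window (Angstrom) in grid coordinates.
#' @return list with `x_centers`, `y_centers`, `counts` (matrix),
#'   `concentration` (mol/L matrix), `z_window` and `n_slabs`.
#' @export
project2d <- function(grid, z_window) {
  stopifnot(length(z_window) == 2)
  z_window <- sort(z_window)
  dims <- dim(grid$counts)
  zc <- grid$origin[3] + (seq_len(dims[3]) - 0.5) * grid$spacing
  sel <- which(zc >= z_window[1] & zc <= z_window[2])
  if (length(sel) == 0) stop("empty projection window: no z-slab inside it")
  sub <- grid$counts[, , sel, drop = FALSE]
  m <- apply(sub, c(1, 2), sum)
  cell_vol_l <- grid$spacing^2 * (length(sel) * grid$spacing) * 1e-27
  conc <- m / (grid$n_frames * AVOGADRO * cell_vol_l)
  list(x_centers = grid$origin[1] + (seq_len(dims[1]) - 0.5) * grid$spacing,
       y_centers = grid$origin[2] + (seq_len(dims[2]) - 0.5) * grid$spacing,
       counts = m, concentration = conc, z_window = z_window,
       n_slabs = length(sel))
}

#' z-window spanning a run of base pairs
#'
#' Convenience for slab selection: the z-range of the chosen pair origins,
#' padded by half a helical rise on each side.
#'
#' @param pair_origins matrix of pair origins (rows ordered along the helix).
#' @param pairs indices of the pairs defining the slab.
#' @param rise helical rise used for the padding (Angstrom).
#' @return numeric length-2 z-window.
#' @export
pair_z_window <- function(pair_origins, pairs, rise = 2.81) {
  z <- pair_origins[pairs, 3]
  c(min(z) - rise / 2, max(z) + rise / 2)
}

#' Write a density grid as OpenDX
#'
#' Values are mean counts per frame per voxel; grid order follows the OpenDX
#' convention (z fastest).
#'
#' @param grid a `density_grid`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_dx <- function(grid, file) {
  d <- dim(grid$counts)
  vals <- as.vector(aperm(grid$counts, c(3, 2, 1))) / grid$n_frames
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f",
            grid$origin[1] + grid$spacing / 2,
            grid$origin[2] + grid$spacing / 2,
            grid$origin[3] + grid$spacing / 2),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))), con)
  # three values per line
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0)
    writeLines(apply(matrix(vals[seq_len(n3)], ncol = 3, byrow = TRUE), 1,
                     function(r) paste(sprintf("%.6g", r), collapse = " ")), con)
  if (n3 < length(vals))
    writeLines(paste(sprintf("%.6g", vals[(n3 + 1):length(vals)]),
                     collapse = " "), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(file)
}
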