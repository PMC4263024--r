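## Voxel grids, masks and NIfTI I/O.
##
## Patient axes follow the radiotherapy convention used throughout the package:
## axis 1 = LR (mediolateral), axis 2 = AP (anteroposterior),
## axis 3 = SI (superoinferior). All lengths are millimetres; densities are
## relative water-equivalent density (water = 1, air ~ 0.001).

#' Construct a density grid
#'
#' A `density_grid` holds a 3-D array of relative water-equivalent density
#' together with its geometry: voxel spacing, origin (the centre of voxel
#' `[1,1,1]` in mm) and the mapping of array axes to patient axes.
#'
#' @param voxels 3-D numeric array of relative water-equivalent density
#'   (water = 1, air about 0.001). All values must be non-negative.
#' @param spacing Numeric length-3, voxel spacing in mm per axis (> 0).
#' @param origin Numeric length-3, mm coordinates of the first voxel centre.
#' @param axes Character length-3, permutation of `c("LR","AP","SI")` naming
#'   the patient axis along each array dimension.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(voxels, spacing, origin = c(0, 0, 0),
                         axes = c("LR", "AP", "SI")) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stopf("'voxels' must be a 3-D array")
  if (any(voxels < 0)) stopf("densities must be >= 0")
  check_numeric(spacing, "spacing", 3, positive = TRUE)
  check_numeric(origin, "origin", 3)
  if (!setequal(axes, c("LR", "AP", "SI")) || length(axes) != 3L)
    stopf("'axes' must be a permutation of LR, AP, SI")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), axes = axes),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<density_grid> %d x %d x %d voxels @ (%g, %g, %g) mm [%s]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              paste(x$axes, collapse = ", ")))
  cat(sprintf("  density range [%.3g, %.3g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.density_grid <- function(x) dim(x$voxels)

## mm coordinates of voxel centres along array axis i
axis_coords <- function(grid, i) {
  grid$origin[i] + (seq_len(dim(grid$voxels)[i]) - 1) * grid$spacing[i]
}

## n x 3 matrix of centres for voxels where mask is TRUE
mask_points <- function(grid, mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(grid$origin[1] + (idx[, 1] - 1) * grid$spacing[1],
        grid$origin[2] + (idx[, 2] - 1) * grid$spacing[2],
        grid$origin[3] + (idx[, 3] - 1) * grid$spacing[3])
}

#' Volume of a binary mask in cm^3
#'
#' @param mask Logical 3-D array.
#' @param grid The `density_grid` providing the voxel spacing.
#' @return Volume in cm^3.
#' @export
mask_volume_cm3 <- function(mask, grid) {
  sum(mask) * prod(grid$spacing) / 1000
}

## Build a 3-D logical/numeric array from separable per-axis contributions:
## out[i,j,k] = fx[i] + fy[j] + fz[k]
field3d <- function(fx, fy, fz) {
  nx <- length(fx); ny <- length(fy); nz <- length(fz)
  array(rep(fx, times = ny * nz), dim = c(nx, ny, nz)) +
    array(rep(rep(fy, each = nx), times = nz), dim = c(nx, ny, nz)) +
    array(rep(fz, each = nx * ny), dim = c(nx, ny, nz))
}

ellipsoid_mask <- function(grid, center, radii) {
  fx <- ((axis_coords(grid, 1) - center[1]) / radii[1])^2
  fy <- ((axis_coords(grid, 2) - center[2]) / radii[2])^2
  fz <- ((axis_coords(grid, 3) - center[3]) / radii[3])^2
  field3d(fx, fy, fz) <= 1
}

box_mask <- function(grid, lo, hi) {
  inside <- function(i) {
    x <- axis_coords(grid, i)
    as.numeric(x >= lo[i] & x <= hi[i])
  }
  field3d(inside(1), inside(2), inside(3)) == 3
}

## Cylinder with axis along array axis `axis`, circular cross-section in the
## two remaining axes.
cylinder_mask <- function(grid, center, radius, axis, span) {
  other <- setdiff(1:3, axis)
  f <- vector("list", 3)
  f[[other[1]]] <- ((axis_coords(grid, other[1]) - center[other[1]]) / radius)^2
  f[[other[2]]] <- ((axis_coords(grid, other[2]) - center[other[2]]) / radius)^2
  ax <- axis_coords(grid, axis)
  f[[axis]] <- ifelse(ax >= span[1] & ax <= span[2], 0, 2)
  field3d(f[[1]], f[[2]], f[[3]]) <= 1
}

## Trilinear interpolation of a 3-D array at arbitrary mm points.
## Points within half a voxel outside the grid are clamped to the boundary;
## points farther outside evaluate to `outside`.
trilinear_sample <- function(arr, spacing, origin, pts, outside = 0) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  d <- dim(arr)
  ci <- sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/") + 1
  valid <- ci[, 1] >= 0.5 & ci[, 1] <= d[1] + 0.5 &
           ci[, 2] >= 0.5 & ci[, 2] <= d[2] + 0.5 &
           ci[, 3] >= 0.5 & ci[, 3] <= d[3] + 0.5
  out <- rep(outside, nrow(pts))
  if (!any(valid)) return(out)
  cv <- ci[valid, , drop = FALSE]
  cv[, 1] <- pmin(pmax(cv[, 1], 1), d[1])
  cv[, 2] <- pmin(pmax(cv[, 2], 1), d[2])
  cv[, 3] <- pmin(pmax(cv[, 3], 1), d[3])
  i0 <- pmin(floor(cv[, 1]), d[1] - 1L); i0 <- pmax(i0, 1L)
  j0 <- pmin(floor(cv[, 2]), d[2] - 1L); j0 <- pmax(j0, 1L)
  k0 <- pmin(floor(cv[, 3]), d[3] - 1L); k0 <- pmax(k0, 1L)
  if (d[1] == 1L) i0 <- rep(1L, nrow(cv))
  if (d[2] == 1L) j0 <- rep(1L, nrow(cv))
  if (d[3] == 1L) k0 <- rep(1L, nrow(cv))
  fx <- cv[, 1] - i0; fy <- cv[, 2] - j0; fz <- cv[, 3] - k0
  i1 <- pmin(i0 + 1L, d[1]); j1 <- pmin(j0 + 1L, d[2]); k1 <- pmin(k0 + 1L, d[3])
  at <- function(i, j, k) arr[cbind(i, j, k)]
  v <- at(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
       at(i1, j0, k0) * fx * (1 - fy) * (1 - fz) +
       at(i0, j1, k0) * (1 - fx) * fy * (1 - fz) +
       at(i1, j1, k0) * fx * fy * (1 - fz) +
       at(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
       at(i1, j0, k1) * fx * (1 - fy) * fz +
       at(i0, j1, k1) * (1 - fx) * fy * fz +
       at(i1, j1, k1) * fx * fy * fz
  out[valid] <- v
  out
}

## NIfTI I/O -----------------------------------------------------------------

#' Write a density grid or mask to a NIfTI file
#'
#' @param grid A `density_grid`.
#' @param file Output path (`.nii` or `.nii.gz`).
#' @export
write_grid_nifti <- function(grid, file) {
  img <- RNifti::asNifti(grid$voxels)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a density grid from a NIfTI file
#'
#' @param file NIfTI path.
#' @param axes Patient-axis labels of the three array dimensions.
#' @return A `density_grid`.
#' @export
read_grid_nifti <- function(file, axes = c("LR", "AP", "SI")) {
  img <- RNifti::readNifti(file)
  sp <- RNifti::pixdim(img)[1:3]
  density_grid(array(as.numeric(img), dim = dim(img)[1:3]),
               spacing = sp, axes = axes)
}

#' Write every mask of a structure set as NIfTI (one file per mask)
#'
#' @param structures A `structure_set`.
#' @param grid The shared `density_grid`.
#' @param dir Output directory.
#' @return Named vector of file paths.
#' @export
write_structures_nifti <- function(structures, grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(structures$masks), function(nm) {
    f <- file.path(dir, paste0(nm, ".nii.gz"))
    img <- RNifti::asNifti(array(as.integer(structures$masks[[nm]]),
                                 dim = dim(grid$voxels)))
    RNifti::pixdim(img) <- grid$spacing
    RNifti::writeNifti(img, f)
    f
  }, character(1))
  invisible(paths)
}
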