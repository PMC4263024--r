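## Synthetic skull-base-like phantoms.
##
## The generator emulates the planning situation this package studies: a target
## volume seated in a region of severe density heterogeneity (lateral bone slab,
## retro-target air cavity, skull shell), an organ at risk abutting the PTV
## (brainstem) plus paired optic structures, anisotropic CTV-to-PTV margins and
## an external contour outside which densities are overridden with air.

#' Construct a structure set
#'
#' Named binary masks sharing the geometry of a density grid. Recognized roles
#' are `CTV`, `PTV`, `brainstem`, `chiasm`, `optic_ipsi`, `optic_contra` and
#' `external`; arbitrary extra masks are allowed.
#'
#' @param masks Named list of logical 3-D arrays, all with the grid's shape.
#' @param grid The shared `density_grid`.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, grid) {
  if (is.null(names(masks)) || any(names(masks) == ""))
    stopf("all masks must be named")
  d <- dim(grid$voxels)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), d))
      stopf("mask '%s' must be a logical array with the grid's shape", nm)
  }
  structure(list(masks = masks, dim = d, spacing = grid$spacing),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set>\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-13s %7d voxels (%.1f cm3)\n", nm, sum(x$masks[[nm]]),
                sum(x$masks[[nm]]) * prod(x$spacing) / 1000))
  invisible(x)
}

#' Parameters of a synthetic skull-base phantom
#'
#' Validates and collects all parameters of the seeded phantom generator.
#' The same spec and seed always produce bit-identical phantoms.
#'
#' @param shape Grid dimensions (voxels) along (LR, AP, SI).
#' @param spacing Voxel spacing in mm. The SI margin of the CTV-to-PTV
#'   expansion follows the slice spacing: 3 mm for 3 mm slices, otherwise
#'   2.5 mm.
#' @param ctv_volume_range Admissible CTV volume range in cm^3; the generated
#'   volume is drawn uniformly from the central part of this interval.
#' @param abut_brainstem If `TRUE` (default) the brainstem mask is constructed
#'   abutting the PTV (surface distance zero).
#' @param bone_slab If `TRUE`, a lateral bone slab partially covering the
#'   target cross-section is inserted in the ipsilateral entrance channel.
#' @param air_cavity If `TRUE`, an air cavity is carved near the target.
#' @param slab_density,bone_density Relative densities of the lateral slab and
#'   of the skull shell.
#' @param noise_sd Standard deviation of the soft-tissue density noise.
#' @param seed Integer seed; the generator is a pure function of (spec, seed).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(60, 60, 60), spacing = c(2, 2, 2.5),
                         ctv_volume_range = c(15.6, 90.7),
                         abut_brainstem = TRUE, bone_slab = TRUE,
                         air_cavity = TRUE, slab_density = 1.8,
                         bone_density = 1.5, noise_sd = 0.02, seed = 1L) {
  check_numeric(shape, "shape", 3, positive = TRUE)
  check_numeric(spacing, "spacing", 3, positive = TRUE)
  check_numeric(ctv_volume_range, "ctv_volume_range", 2, positive = TRUE)
  if (ctv_volume_range[1] >= ctv_volume_range[2])
    stopf("'ctv_volume_range' must be increasing")
  check_numeric(slab_density, "slab_density", 1, positive = TRUE)
  check_numeric(noise_sd, "noise_sd", 1, nonneg = TRUE)
  ## feasibility: the largest admissible CTV must fit well inside the grid
  extent <- shape * spacing
  rmax <- (3 * ctv_volume_range[2] * 1000 / (4 * pi))^(1 / 3)
  if (2.6 * rmax > min(extent))
    stopf("infeasible geometry: target (radius %.1f mm) too large for grid extent %.0f mm",
          rmax, min(extent))
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 ctv_volume_range = ctv_volume_range,
                 abut_brainstem = isTRUE(abut_brainstem),
                 bone_slab = isTRUE(bone_slab),
                 air_cavity = isTRUE(air_cavity),
                 slab_density = slab_density, bone_density = bone_density,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

## SI margin follows the slice-spacing rule; LR/AP margins are 2 mm.
default_margins <- function(spacing) {
  si <- if (isTRUE(all.equal(spacing[3], 3))) 3 else 2.5
  c(lr = 2, ap = 2, si = si)
}

#' Generate a heterogeneous skull-base-like phantom
#'
#' Builds a density grid with a skull shell, soft tissue, a lateral bone slab
#' whose edge cuts through the target's beam's-eye footprint, an air cavity in
#' the mediolateral entrance channel, and a structure set with CTV, PTV
#' (anisotropic margin expansion), brainstem (optionally abutting the PTV),
#' optic nerves, chiasm and the external contour (air override outside).
#'
#' @param spec A `phantom_spec`.
#' @return List with elements `grid` (`density_grid`) and `structures`
#'   (`structure_set`).
#' @export
make_skullbase_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("'spec' must be a phantom_spec")
  with_seed(spec$seed, .build_skullbase(spec))
}

.build_skullbase <- function(spec) {
  shape <- spec$shape; spacing <- spec$spacing
  extent <- shape * spacing
  grid0 <- density_grid(array(1, dim = shape), spacing)
  hc <- extent / 2                      # head centre, mm

  ## external contour: head ellipsoid
  semi <- c(0.43, 0.43, 0.47) * extent
  external <- ellipsoid_mask(grid0, hc, semi)

  ## densities: soft tissue + noise, skull shell near the external surface
  vox <- array(1, dim = shape)
  if (spec$noise_sd > 0)
    vox <- vox + array(rnorm(prod(shape), 0, spec$noise_sd), dim = shape)
  vox[vox < 0.85] <- 0.85
  shell <- external & !ellipsoid_mask(grid0, hc, semi - 4)
  vox[shell] <- spec$bone_density

  ## CTV: ellipsoid of seeded volume and mild anisotropy, central skull base
  vol <- runif(1, spec$ctv_volume_range[1] * 1.08,
               spec$ctv_volume_range[2] * 0.90)
  r0 <- (3 * vol * 1000 / (4 * pi))^(1 / 3)
  f <- exp(runif(3, log(0.85), log(1.18)))
  f <- f / prod(f)^(1 / 3)
  radii <- r0 * f
  ctv_c <- hc + c(runif(1, -4, 4), runif(1, -6, 0), runif(1, -8, 0))
  ctv <- ellipsoid_mask(grid0, ctv_c, radii) & external

  ## PTV: anisotropic margin expansion on this grid
  m <- default_margins(spacing)
  ptv <- expand_margin(ctv, spacing, m["lr"], m["ap"], m["si"]) & external

  ## lateral bone slab in the ipsilateral (low-LR) entrance channel; its
  ## posterior/superior edges cut through the target footprint so that
  ## mediolateral beams see a strong lateral density interface
  if (spec$bone_slab) {
    ey <- ctv_c[2] + runif(1, -3, 3)
    ez <- ctv_c[3] + runif(1, 0, 5)
    x1 <- ctv_c[1] - radii[1] - 8
    slab <- box_mask(grid0, lo = c(x1 - 14, ey, 0), hi = c(x1, extent[2], ez))
    slab <- slab & external & !ptv
    vox[slab] <- spec$slab_density
  }

  ## air cavity beside/behind the target, also crossing the LR channel
  if (spec$air_cavity) {
    cav_c <- c(ctv_c[1] - radii[1] - 6, ctv_c[2] + runif(1, 2, 8),
               ctv_c[3] + runif(1, -4, 2))
    cavity <- ellipsoid_mask(grid0, cav_c, c(6, 9, 8))
    cavity <- cavity & external & !ptv
    vox[cavity] <- AIR_DENSITY
  }

  ## tumours do not contain air: fix target density to soft tissue
  vox[ctv] <- 1.02

  ## brainstem: vertical cylinder posterior to the target; when abutting it is
  ## placed overlapping the PTV and the overlap carved away, which guarantees
  ## zero surface distance while staying disjoint from the PTV (hence the CTV)
  bs_r <- 7
  near <- abs(axis_coords(grid0, 1) - ctv_c[1]) < bs_r
  ptv_y <- apply(ptv[near, , , drop = FALSE], 2, any)
  y_back <- max(axis_coords(grid0, 2)[ptv_y])
  y_bs <- if (spec$abut_brainstem) y_back + bs_r - 3 else y_back + bs_r + 6
  brainstem <- cylinder_mask(grid0, c(ctv_c[1], y_bs, 0), bs_r, axis = 3,
                             span = c(ctv_c[3] - 30, ctv_c[3] + 25))
  brainstem <- brainstem & external & !ptv

  ## optic nerves (AP-running thin cylinders) and chiasm, anterior-superior
  ## of the target, anchored on the anterior CTV surface so that they never
  ## vanish inside it
  z_opt <- ctv_c[3] + radii[3] * 0.4
  ya <- ctv_c[2] - radii[2]
  nerve <- function(x) {
    cylinder_mask(grid0, c(x, 0, z_opt), 3, axis = 2,
                  span = c(ya - 30, ya - 4)) & external & !ctv
  }
  optic_ipsi <- nerve(ctv_c[1] - 16)
  optic_contra <- nerve(ctv_c[1] + 16)
  chiasm <- box_mask(grid0,
                     lo = c(ctv_c[1] - 8, ya - 13, z_opt - 4),
                     hi = c(ctv_c[1] + 8, ya - 4, z_opt + 4)) &
    external & !ctv
  for (nm in c("optic_ipsi", "optic_contra", "chiasm"))
    if (!any(get(nm))) stopf("degenerate phantom geometry: empty %s", nm)

  grid <- density_grid(vox, spacing)
  grid <- apply_external_override(grid, external)

  vol_ctv <- mask_volume_cm3(ctv, grid)
  if (vol_ctv < spec$ctv_volume_range[1] || vol_ctv > spec$ctv_volume_range[2])
    stopf("generated CTV volume %.1f cm3 outside configured range", vol_ctv)

  structures <- structure_set(list(
    CTV = ctv, PTV = ptv, brainstem = brainstem, chiasm = chiasm,
    optic_ipsi = optic_ipsi, optic_contra = optic_contra,
    external = external), grid)
  list(grid = grid, structures = structures, spec = spec)
}

#' Homogeneous water phantom with a cubic target
#'
#' Test and calibration fixture: every voxel has density exactly 1.0, a cubic
#' CTV sits at the grid centre and the PTV is its default margin expansion.
#'
#' @param shape Grid dimensions (voxels).
#' @param spacing Voxel spacing in mm.
#' @param ctv_side_mm Side of the cubic CTV (default one third of the
#'   smallest grid extent).
#' @param oar If `TRUE`, adds a box OAR (`"oar"`) lateral-posterior to the
#'   target at 4 mm distance, for constraint experiments.
#' @return List with `grid` and `structures`.
#' @export
make_water_phantom <- function(shape = c(60, 60, 60), spacing = c(1, 1, 1),
                               ctv_side_mm = NULL, oar = FALSE) {
  check_numeric(shape, "shape", 3, positive = TRUE)
  check_numeric(spacing, "spacing", 3, positive = TRUE)
  grid <- density_grid(array(1, dim = as.integer(shape)), spacing)
  extent <- shape * spacing
  side <- ctv_side_mm %||% (min(extent) / 3)
  if (side <= 0 || side >= min(extent)) stopf("invalid CTV side")
  hc <- extent / 2
  ctv <- box_mask(grid, hc - side / 2, hc + side / 2)
  m <- default_margins(spacing)
  ptv <- expand_margin(ctv, spacing, m["lr"], m["ap"], m["si"])
  masks <- list(CTV = ctv, PTV = ptv,
                external = array(TRUE, dim = dim(grid$voxels)))
  if (isTRUE(oar)) {
    gap <- 4
    masks$oar <- box_mask(grid,
                          lo = c(hc[1] - side / 2, hc[2] + side / 2 + gap,
                                 hc[3] - side / 2),
                          hi = c(hc[1] + side / 2, hc[2] + side / 2 + gap + 8,
                                 hc[3] + side / 2))
  }
  list(grid = grid, structures = structure_set(masks, grid))
}

#' Anisotropic margin expansion of a binary mask
#'
#' Expands a mask with an ellipsoidal (anisotropic-metric) margin: a voxel
#' belongs to the output iff its centre lies within the anisotropic distance
#' of some input voxel centre, i.e. there is an input voxel with offset
#' `(dx,dy,dz)` (mm) satisfying `(dx/lr)^2 + (dy/ap)^2 + (dz/si)^2 <= 1`.
#' A zero margin along an axis requires a zero offset along that axis, so
#' `expand_margin(m, sp, 0, 0, 0)` is the identity.
#'
#' @param mask Logical 3-D array.
#' @param spacing Voxel spacing in mm.
#' @param lr_mm,ap_mm,si_mm Margins in mm along LR, AP, SI (>= 0).
#' @return Logical array containing the input.
#' @export
expand_margin <- function(mask, spacing, lr_mm, ap_mm, si_mm) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stopf("'mask' must be a logical 3-D array")
  check_numeric(spacing, "spacing", 3, positive = TRUE)
  margins <- c(lr_mm, ap_mm, si_mm)
  check_numeric(margins, "margins", 3)
  if (any(margins < 0)) stopf("margins must be >= 0")
  d <- dim(mask)
  noff <- floor(margins / spacing)
  offs <- expand.grid(dx = -noff[1]:noff[1], dy = -noff[2]:noff[2],
                      dz = -noff[3]:noff[3])
  frac <- function(o, m, sp) if (m == 0) ifelse(o == 0, 0, 2) else (o * sp / m)^2
  keep <- frac(offs$dx, margins[1], spacing[1]) +
          frac(offs$dy, margins[2], spacing[2]) +
          frac(offs$dz, margins[3], spacing[3]) <= 1
  offs <- offs[keep, , drop = FALSE]
  out <- array(FALSE, dim = d)
  for (r in seq_len(nrow(offs))) {
    o <- as.integer(offs[r, ])
    src <- list(seq(max(1, 1 - o[1]), min(d[1], d[1] - o[1])),
                seq(max(1, 1 - o[2]), min(d[2], d[2] - o[2])),
                seq(max(1, 1 - o[3]), min(d[3], d[3] - o[3])))
    dst <- list(src[[1]] + o[1], src[[2]] + o[2], src[[3]] + o[3])
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] | mask[src[[1]], src[[2]], src[[3]]]
  }
  out
}

#' Override densities outside the external contour with air
#'
#' @param grid A `density_grid`.
#' @param external_mask Logical array on the same grid.
#' @return A new `density_grid` with voxels outside the mask set to the air
#'   density (0.001) and voxels inside unchanged.
#' @export
apply_external_override <- function(grid, external_mask) {
  if (!identical(dim(external_mask), dim(grid$voxels)))
    stopf("external mask shape does not match the grid")
  vox <- grid$voxels
  vox[!external_mask] <- AIR_DENSITY
  density_grid(vox, grid$spacing, grid$origin, grid$axes)
}
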