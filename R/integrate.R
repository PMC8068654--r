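sphere_voxels <- function(grid, center, radius, what = "sphere") {
  sp <- grid_spacing(grid)
  dims <- dim(grid$values)
  if (abs(grid$cell[4] - 90) > 1e-6 || abs(grid$cell[5] - 90) > 1e-6 ||
      abs(grid$cell[6] - 90) > 1e-6) {
    abort("sphere selection requires an orthorhombic grid")
  }
  lo <- floor((center - radius - grid$origin) / sp) + 1
  hi <- ceiling((center + radius - grid$origin) / sp) + 1
  if (any(lo < 1) || any(hi > dims)) {
    abort(paste0(what, " extends outside the map volume"))
  }
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  dx <- grid$origin[1] + (ix - 1) * sp[1] - center[1]
  dy <- grid$origin[2] + (iy - 1) * sp[2] - center[2]
  dz <- grid$origin[3] + (iz - 1) * sp[3] - center[3]
  r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  keep <- r2 <= radius^2
  if (!any(keep)) {
    abort(paste0("no voxel centers inside ", what,
      "; grid spacing too coarse for this radius"))
  }
  list(values = grid$values[ix, iy, iz][keep], n = sum(keep))
}

#' Integrate map density within a sphere
#'
#' Sums the map over all voxels whose centers lie within `radius` of
#' `center` and multiplies by the voxel volume (voxel-center inclusion, no
#' partial-voxel weighting).  The default radius 1.05 angstrom is the
#' covalent radius of sulfur, the probe used to compare candidate ligand
#' sites.
#'
#' @param grid a [density_grid()].
#' @param center cartesian 3-vector, angstrom.
#' @param radius sphere radius, angstrom.
#' @param atom_key optional label reported in errors and results.
#' @return one-row tibble: `atom`, `radius`, `rho` (integrated density, map
#'   units times angstrom^3), `n_voxels`.
#' @export
integrate_sphere <- function(grid, center, radius = 1.05, atom_key = "site") {
  stopifnot(radius > 0)
  sel <- sphere_voxels(grid, center, radius,
    what = paste0("integration sphere of atom ", atom_key))
  tibble(
    atom = atom_key, radius = radius,
    rho = sum(sel$values) * grid_voxel_volume(grid),
    n_voxels = sel$n
  )
}

#' Integrate spheres around a selection of model atoms
#'
#' One sphere per requested atom, in the requested order.  Alternate
#' centers may be supplied (e.g. sulfur positions taken from a re-refined
#' model while integrating the deposited map).
#'
#' @param model a [structure_model()].
#' @param grid a [density_grid()].
#' @param atoms character vector of atom names.
#' @param radius sphere radius, angstrom.
#' @param chain optional chain to disambiguate atom names.
#' @param centers optional numeric matrix (length(atoms) x 3) of cartesian
#'   centers overriding the model positions.
#' @return tibble with one row per atom: `atom`, `chain`, `radius`, `rho`,
#'   `n_voxels`, of class `integration_tbl`.
#' @export
integrate_selection <- function(model, grid, atoms, radius = 1.05,
                                chain = NULL, centers = NULL) {
  if (length(atoms) == 0) {
    out <- tibble(
      atom = character(), chain = character(), radius = numeric(),
      rho = numeric(), n_voxels = integer()
    )
    class(out) <- c("integration_tbl", class(out))
    return(out)
  }
  idx <- match_atoms(model, atoms, chain = chain)
  if (is.null(centers)) {
    centers <- atom_xyz(model)[idx, , drop = FALSE]
  } else {
    centers <- as.matrix(centers)
    stopifnot(nrow(centers) == length(atoms), ncol(centers) == 3)
  }
  out <- purrr::map_dfr(seq_along(atoms), function(i) {
    integrate_sphere(grid, centers[i, ], radius, atom_key = atoms[i]) |>
      mutate(chain = model$chain[idx[i]], .after = "atom")
  })
  class(out) <- c("integration_tbl", class(out))
  out
}

#' Highest contour level at which a site shows density
#'
#' The maximum sigma-unit map value over voxels within `radius` of
#' `center` — the highest contour at which any density appears at the site
#' (e.g. a strong Fe peak appears at a much higher level than a putative
#' N2 ligand).
#'
#' @inheritParams integrate_sphere
#' @return one-row tibble: `atom`, `radius`, `level_sigma`.
#' @export
peak_appearance_level <- function(grid, center, radius = 1.05,
                                  atom_key = "site") {
  stopifnot(radius > 0)
  sel <- sphere_voxels(grid, center, radius,
    what = paste0("peak sphere of atom ", atom_key))
  tibble(
    atom = atom_key, radius = radius,
    level_sigma = max(map_sigma(grid, sel$values))
  )
}
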