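#' Construct a density grid
#'
#' A density grid is a 3-D scalar field sampled on a unit cell.  Voxel
#' `(i, j, k)` (0-based) sits at `origin + M %*% c(i/nx, j/ny, k/nz)` where
#' `M` is the cell orthogonalization matrix; the voxel value is the density
#' at that point.  The map mean and rmsd (population standard deviation)
#' are always recomputed from the stored array, never trusted from a file
#' header, and define the sigma-unit scale `(value - mean) / rmsd`.
#'
#' @param values numeric 3-D array.
#' @param cell length-6 cell parameters; the grid spans the full cell.
#' @param origin cartesian position (angstrom) of voxel (0, 0, 0).
#' @param label free-text label.
#' @return a `density_grid` object.
#' @export
density_grid <- function(values, cell, origin = c(0, 0, 0), label = "map") {
  stopifnot(is.array(values), length(dim(values)) == 3)
  cell <- as.numeric(cell)
  if (any(cell[1:3] <= 0) || any(cell[4:6] <= 0)) {
    abort("cell edges and angles must be positive")
  }
  g <- structure(
    list(
      values = values, cell = cell, origin = as.numeric(origin),
      label = label
    ),
    class = "density_grid"
  )
  g$mean <- mean(values)
  g$rmsd <- sqrt(mean((values - g$mean)^2))
  g
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(
    "<density_grid> ", x$label, ": ", paste(d, collapse = "x"),
    " voxels, cell ", paste(signif(x$cell, 5), collapse = " "),
    ", mean ", signif(x$mean, 4), ", rmsd ", signif(x$rmsd, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Grid geometry helpers
#'
#' @param grid a [density_grid()].
#' @return `grid_spacing()` the per-axis voxel spacing in angstrom;
#'   `grid_voxel_volume()` the voxel volume in cubic angstrom.
#' @export
grid_spacing <- function(grid) grid$cell[1:3] / dim(grid$values)

#' @rdname grid_spacing
#' @export
grid_voxel_volume <- function(grid) {
  cell_volume(grid$cell) / prod(dim(grid$values))
}

#' Convert map values to sigma units
#'
#' @param grid a [density_grid()].
#' @param values raw map values; defaults to the whole grid array.
#' @return values standardized by the grid's mean and rmsd.
#' @export
map_sigma <- function(grid, values = grid$values) {
  if (grid$rmsd <= 0) abort("map rmsd is zero; sigma units undefined")
  (values - grid$mean) / grid$rmsd
}

#' Summarise a density grid
#'
#' @param grid a [density_grid()].
#' @return one-row tibble with dimensions, spacing, mean, rmsd and extrema.
#' @export
map_info <- function(grid) {
  d <- dim(grid$values)
  sp <- grid_spacing(grid)
  tibble(
    label = grid$label, nx = d[1], ny = d[2], nz = d[3],
    spacing_x = sp[1], spacing_y = sp[2], spacing_z = sp[3],
    mean = grid$mean, rmsd = grid$rmsd,
    min = min(grid$values), max = max(grid$values)
  )
}

#' Read a CCP4/MRC volumetric map
#'
#' Reads mode-2 (32-bit float) maps.  The axis order is normalized so the
#' returned array is indexed along the crystal x, y, z axes; map statistics
#' are recomputed from the data array.
#'
#' @param path file path.
#' @return a [density_grid()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hi <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nxyz <- hi[1:3]; mode <- hi[4]; mxyz <- hi[8:10]
  hf <- readBin(con, "double", n = 6, size = 4, endian = "little")
  cell <- hf
  maps <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  readBin(con, "double", n = 3, size = 4, endian = "little") # dmin/dmax/dmean
  hi2 <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  nsymbt <- hi2[2]
  readBin(con, "integer", n = 25, size = 4, endian = "little") # extra
  origin <- readBin(con, "double", n = 3, size = 4, endian = "little")
  readBin(con, "raw", n = 1024 - 52 * 4)
  if (mode != 2) abort(paste0("unsupported MRC mode: ", mode))
  if (any(nxyz <= 0)) abort("non-positive grid dimensions in header")
  if (any(cell[1:3] <= 0)) abort("non-positive cell in header")
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  nvox <- prod(nxyz)
  vals <- readBin(con, "double", n = nvox, size = 4, endian = "little")
  if (length(vals) != nvox) {
    abort(paste0(
      "map data truncated: expected ", nvox, " voxels, got ", length(vals)
    ))
  }
  arr <- array(vals, dim = nxyz)
  # Normalize axis order: header words MAPC/MAPR/MAPS say which crystal axis
  # runs fastest; canonical order is x fastest (1, 2, 3).
  if (!identical(maps, c(1L, 2L, 3L))) {
    arr <- aperm(arr, order(maps))
  }
  if (!all(dim(arr) == mxyz)) {
    warn("map sampling differs from full-cell sampling; using data extent")
    cell[1:3] <- cell[1:3] * dim(arr) / mxyz
  }
  density_grid(arr, cell, origin = origin,
    label = tools::file_path_sans_ext(basename(path)))
}

#' Write a density grid to a CCP4/MRC file
#'
#' Writes a mode-2 little-endian map with canonical x-fastest axis order and
#' the grid origin in the MRC-2014 origin header words.
#'
#' @param grid a [density_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(grid, path) {
  d <- dim(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2); wi(c(0, 0, 0)); wi(d)
  wf(grid$cell)
  wi(c(1, 2, 3))
  wf(c(min(grid$values), max(grid$values), grid$mean))
  wi(c(1, 0))          # ISPG (P1), NSYMBT
  wi(rep(0, 25))       # extra
  wf(grid$origin)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(grid$rmsd)
  wi(0)                # NLABL
  writeBin(raw(1024 - 56 * 4), con)
  wf(as.numeric(grid$values))
  invisible(path)
}
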