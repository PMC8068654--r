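#' Specify a synthetic map calculation
#'
#' Bundles the parameters of the Gaussian-atom map generator.  Each atom
#' contributes `occupancy * weight` electrons spread as a normalized 3-D
#' Gaussian whose covariance is the atom's displacement tensor
#' (`u_aniso` if present, else `b_iso / (8 pi^2) * I`) plus the global
#' `aniso_smear`; the weight is `n_electrons` for ordinary maps and the
#' per-element `anomalous_weights` entry for anomalous maps.  A band limit
#' applies a sharp reciprocal-space cutoff at `1/d_min`, reproducing the
#' Fourier truncation ripples seen around strong scatterers; a length-3
#' `band_limit` applies an ellipsoidal (per-axis) cutoff emulating
#' direction-dependent resolution.  Seeded Gaussian noise is added last.
#'
#' @param model a [structure_model()].
#' @param grid_spacing target voxel spacing, angstrom.
#' @param padding empty margin around the model when the grid is derived
#'   from the model extent rather than the model cell, angstrom.
#' @param band_limit optional resolution cutoff d_min (angstrom); scalar for
#'   a spherical cutoff or length-3 for per-axis cutoffs.
#' @param aniso_smear optional symmetric 3x3 tensor (angstrom^2) added to
#'   every atom's displacement covariance.
#' @param noise_sd additive Gaussian noise standard deviation, map units.
#' @param seed integer RNG seed for the noise.
#' @param anomalous_weights named numeric vector, element -> weight; the
#'   default gives signal only to the anomalous scatterers S, Fe and Mo.
#' @param box optional explicit grid geometry, `list(origin =, dims =)`,
#'   overriding the geometry derived from the model extent (used to place
#'   several models on one common grid).
#' @return a `map_spec` list.
#' @export
map_spec <- function(model, grid_spacing = 0.25, padding = 4,
                     band_limit = NULL, aniso_smear = NULL, noise_sd = 0,
                     seed = 1L,
                     anomalous_weights = c(S = 1, FE = 0.3, MO = 5),
                     box = NULL) {
  stopifnot(grid_spacing > 0, padding >= 0, noise_sd >= 0)
  if (!is.null(band_limit)) {
    stopifnot(length(band_limit) %in% c(1, 3), all(band_limit > 0))
  }
  if (!is.null(aniso_smear)) {
    stopifnot(is.matrix(aniso_smear), all(dim(aniso_smear) == 3))
    if (!isTRUE(all.equal(aniso_smear, t(aniso_smear)))) {
      abort("aniso_smear must be symmetric")
    }
  }
  if (any(anomalous_weights < 0)) abort("anomalous weights must be >= 0")
  structure(
    list(
      model = model, grid_spacing = grid_spacing, padding = padding,
      band_limit = band_limit, aniso_smear = aniso_smear,
      noise_sd = noise_sd, seed = as.integer(seed),
      anomalous_weights = anomalous_weights, box = box
    ),
    class = "map_spec"
  )
}

# Real-space Gaussian-atom density on an orthorhombic grid.
.gaussian_field <- function(model, dims, spacing, origin, weights,
                            aniso_smear) {
  vals <- array(0, dim = dims)
  xyz <- atom_xyz(model)
  for (j in seq_len(nrow(model))) {
    w <- weights[j] * model$occupancy[j]
    if (w == 0) next
    u <- model$u_aniso[[j]]
    sigma <- if (is.null(u)) diag(3) * model$b_iso[j] / (8 * pi^2) else u
    if (!is.null(aniso_smear)) sigma <- sigma + aniso_smear
    ev <- eigen(sigma, symmetric = TRUE)
    if (min(ev$values) <= 0) abort("atom displacement covariance not positive")
    smax <- sqrt(max(ev$values))
    cutoff <- 6 * smax
    ctr <- xyz[j, ]
    lo <- pmax(floor((ctr - cutoff - origin) / spacing) + 1, 1)
    hi <- pmin(ceiling((ctr + cutoff - origin) / spacing) + 1, dims)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx <- origin[1] + (ix - 1) * spacing[1] - ctr[1]
    dy <- origin[2] + (iy - 1) * spacing[2] - ctr[2]
    dz <- origin[3] + (iz - 1) * spacing[3] - ctr[3]
    g <- as.matrix(expand.grid(dx = dx, dy = dy, dz = dz))
    q <- g %*% ev$vectors
    expo <- sweep(q^2, 2, 2 * ev$values, "/")
    dens <- w * (2 * pi)^(-1.5) / sqrt(prod(ev$values)) *
      exp(-rowSums(expo))
    vals[ix, iy, iz] <- vals[ix, iy, iz] +
      array(dens, dim = c(length(ix), length(iy), length(iz)))
  }
  vals
}

.band_limit_filter <- function(vals, spacing, d_min) {
  dims <- dim(vals)
  freq_axis <- function(n, dx) {
    k <- 0:(n - 1)
    k[k > n / 2] <- k[k > n / 2] - n
    k / (n * dx)
  }
  sx <- freq_axis(dims[1], spacing[1])
  sy <- freq_axis(dims[2], spacing[2])
  sz <- freq_axis(dims[3], spacing[3])
  dm <- if (length(d_min) == 1) rep(d_min, 3) else d_min
  s2 <- outer(outer((sx * dm[1])^2, (sy * dm[2])^2, "+"), (sz * dm[3])^2, "+")
  ft <- fft(vals)
  ft[s2 > 1] <- 0
  Re(fft(ft, inverse = TRUE)) / prod(dims)
}

.synth_grid_geometry <- function(spec) {
  model <- spec$model
  if (!is.null(spec$box)) {
    dims <- spec$box$dims
    spacing <- rep(spec$grid_spacing, 3)
    return(list(dims = dims, spacing = spacing, origin = spec$box$origin,
      cell = c(dims * spacing, 90, 90, 90)))
  }
  lo <- c(min(model$x), min(model$y), min(model$z)) - spec$padding
  hi <- c(max(model$x), max(model$y), max(model$z)) + spec$padding
  dims <- pmax(ceiling((hi - lo) / spec$grid_spacing) + 1, 2)
  if (any(dims < 4)) abort("grid too small to hold model plus padding")
  spacing <- rep(spec$grid_spacing, 3)
  list(dims = dims, spacing = spacing, origin = lo,
    cell = c(dims * spacing, 90, 90, 90))
}

.synthesize <- function(spec, weights, label) {
  geo <- .synth_grid_geometry(spec)
  vals <- .gaussian_field(spec$model, geo$dims, geo$spacing, geo$origin,
    weights, spec$aniso_smear)
  if (!is.null(spec$band_limit)) {
    vals <- .band_limit_filter(vals, geo$spacing, spec$band_limit)
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vals <- vals + array(rnorm(prod(geo$dims), sd = spec$noise_sd), geo$dims)
  }
  density_grid(vals, geo$cell, origin = geo$origin, label = label)
}

#' Synthesize an electron-density map from a model
#'
#' @param spec a [map_spec()].
#' @return a [density_grid()] on an orthorhombic box enclosing the model
#'   plus padding; with no noise and no band limit each atom integrates to
#'   `occupancy * n_electrons` electrons.
#' @export
synthesize_map <- function(spec) {
  .synthesize(spec, spec$model$n_electrons,
    paste0(model_label(spec$model), "_2fofc"))
}

#' Synthesize an anomalous-difference style map
#'
#' As [synthesize_map()] but each atom is weighted by its element's entry in
#' `spec$anomalous_weights` (default: signal only for S, Fe and Mo, the
#' anomalous scatterers at a 7100 eV measurement) instead of its electron
#' count.
#'
#' @param spec a [map_spec()].
#' @return a [density_grid()].
#' @export
synthesize_anomalous_map <- function(spec) {
  w <- spec$anomalous_weights[toupper(spec$model$element)]
  w[is.na(w)] <- 0
  .synthesize(spec, unname(w), paste0(model_label(spec$model), "_anom"))
}

#' Closed-form sphere integral of an isotropic Gaussian atom
#'
#' Electrons inside radius `R` of an atom of `n` electrons with isotropic
#' B factor `b`: `n * (erf(sqrt(a) R) - 2 sqrt(a/pi) R exp(-a R^2))` with
#' `a = 4 pi^2 / b`.  Used as the analytic oracle for sphere integration.
#'
#' @param radius sphere radius, angstrom.
#' @param b_iso isotropic B factor, angstrom^2.
#' @param n_electrons total electrons of the atom.
#' @return electrons within the sphere.
#' @export
gaussian_sphere_integral <- function(radius, b_iso, n_electrons = 1) {
  a <- 4 * pi^2 / b_iso
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  n_electrons * (erf(sqrt(a) * radius) -
    2 * sqrt(a / pi) * radius * exp(-a * radius^2))
}

#' Stamp an anisotropic displacement tensor onto model atoms
#'
#' Sets each selected atom's `u_aniso` to `b_iso/(8 pi^2) I + smear`,
#' mimicking direction-dependent smearing of the apparent density.
#'
#' @param model a [structure_model()].
#' @param smear symmetric 3x3 tensor, angstrom^2.
#' @param atoms atom names to stamp; default all atoms.
#' @return the modified model.
#' @export
smear_model <- function(model, smear, atoms = model$name) {
  idx <- match_atoms(model, atoms)
  for (i in idx) {
    model$u_aniso[[i]] <- diag(3) * model$b_iso[i] / (8 * pi^2) + smear
  }
  model
}
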