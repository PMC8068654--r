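#' Distance between two model atoms
#'
#' @param model a [structure_model()].
#' @param a,b atom names (optionally disambiguated by `chain`).
#' @param chain optional chain identifier applied to both atoms.
#' @return one-row tibble: `atom_a`, `atom_b`, `distance` (angstrom).
#' @export
measure_distance <- function(model, a, b, chain = NULL) {
  ia <- match_atoms(model, a, chain = chain)
  ib <- match_atoms(model, b, chain = chain)
  d <- sqrt(sum((atom_xyz(model)[ia, ] - atom_xyz(model)[ib, ])^2))
  tibble(atom_a = a, atom_b = b, distance = d)
}

#' Mean isotropic B factor over a selection
#'
#' @param model a [structure_model()].
#' @param atoms atom names; defaults to every atom.
#' @param chain optional chain filter applied before matching.
#' @return mean `b_iso` in angstrom^2.
#' @export
average_b <- function(model, atoms = NULL, chain = NULL) {
  if (!is.null(chain)) model <- model[model$chain %in% chain, ]
  if (is.null(atoms)) {
    if (nrow(model) == 0) abort("empty selection for average_b")
    return(mean(model$b_iso))
  }
  if (length(atoms) == 0) abort("empty selection for average_b")
  mean(model$b_iso[match_atoms(model, atoms)])
}

#' Principal-axis decomposition of an anisotropic displacement tensor
#'
#' @param u symmetric positive-semidefinite 3x3 tensor, angstrom^2.
#' @param tol tolerance for negative eigenvalues.
#' @return list: `eigenvalues` (descending, angstrom^2), `axes` (3x3 matrix,
#'   column i the unit axis of eigenvalue i), `ratio` (smallest/largest,
#'   1 for an isotropic atom, near 0 for a strongly anisotropic one).
#' @export
anisotropy <- function(u, tol = 1e-8) {
  stopifnot(is.matrix(u), all(dim(u) == 3))
  if (!isTRUE(all.equal(u, t(u), tolerance = 1e-6))) {
    abort("displacement tensor must be symmetric")
  }
  e <- eigen((u + t(u)) / 2, symmetric = TRUE)
  if (min(e$values) < -tol) {
    abort("displacement tensor has a negative eigenvalue")
  }
  list(
    eigenvalues = e$values,
    axes = e$vectors,
    ratio = max(e$values[3], 0) / e$values[1]
  )
}

#' Angle between a bond and the axis of maximum anisotropy
#'
#' For a diatomic ligand modelled into anisotropically smeared density, the
#' bond tends to align with the direction the density is stretched.  This
#' measures the angle between the a-b bond vector and the major principal
#' axis of the two atoms' averaged displacement tensor (or of each atom
#' separately with `mode = "per_atom"`), folded to `[0, 90]` degrees since
#' eigenvectors carry no sign.
#'
#' @param model a [structure_model()]; both atoms must carry `u_aniso`.
#' @param a,b atom names.
#' @param chain optional chain identifier.
#' @param mode `"pair"` (average the two tensors) or `"per_atom"`.
#' @return angle(s) in degrees; named vector of length 2 for `"per_atom"`.
#' @export
bond_axis_alignment <- function(model, a, b, chain = NULL,
                                mode = c("pair", "per_atom")) {
  mode <- match.arg(mode)
  ia <- match_atoms(model, a, chain = chain)
  ib <- match_atoms(model, b, chain = chain)
  ua <- model$u_aniso[[ia]]
  ub <- model$u_aniso[[ib]]
  if (is.null(ua) || is.null(ub)) {
    abort("both atoms need anisotropic displacement tensors")
  }
  bond <- atom_xyz(model)[ib, ] - atom_xyz(model)[ia, ]
  bond <- bond / sqrt(sum(bond^2))
  angle_to_major <- function(u) {
    ax <- anisotropy(u)$axes[, 1]
    acos(pmin(abs(sum(ax * bond)), 1)) * 180 / pi
  }
  if (mode == "pair") {
    angle_to_major((ua + ub) / 2)
  } else {
    c(a = angle_to_major(ua), b = angle_to_major(ub))
  }
}
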