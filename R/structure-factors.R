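#' Reflection indices to a resolution limit
#'
#' Enumerates one Friedel hemisphere of integer reflections `(h, k, l)`
#' with `|s| <= 1/d_min` (including the forward reflection (0,0,0), whose
#' amplitude is the total electron count).
#'
#' @param cell length-6 cell parameters.
#' @param d_min resolution limit, angstrom.
#' @return tibble with integer columns `h`, `k`, `l`.
#' @export
reflection_indices <- function(cell, d_min) {
  stopifnot(d_min > 0)
  ainv <- solve(cell_matrix(cell))
  hmax <- ceiling(cell[1:3] / d_min)
  grid <- expand.grid(
    h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2], l = 0:hmax[3]
  )
  s2 <- rowSums((as.matrix(grid) %*% ainv)^2)
  keep <- s2 <= 1 / d_min^2 &
    (grid$l > 0 | (grid$l == 0 & grid$k > 0) |
      (grid$l == 0 & grid$k == 0 & grid$h >= 0))
  as_tibble(grid[keep, ])
}

#' Structure factors by direct summation over Gaussian atoms
#'
#' `F(h) = sum_j occ_j n_electrons_j exp(-B_j s^2 / 4) exp(2 pi i h . x_j)`
#' with `x_j` fractional coordinates and `s` the scattering vector length.
#' The single-Gaussian atom (a flat form factor damped by the B factor) is
#' the reciprocal-space twin of the real-space generator in
#' [synthesize_map()].
#'
#' @param model a [structure_model()].
#' @param hkl tibble with integer columns `h`, `k`, `l`.
#' @return tibble `h`, `k`, `l`, `s2`, `f_calc` (complex), `f_abs`; the
#'   model cell is attached as attribute `cell`.
#' @export
direct_structure_factors <- function(model, hkl) {
  if (nrow(model) == 0) abort("empty model")
  cell <- model_cell(model)
  if (anyDuplicated(hkl[c("h", "k", "l")])) {
    abort("duplicate reflection indices")
  }
  a_mat <- cell_matrix(cell)
  ainv <- solve(a_mat)
  hm <- as.matrix(hkl[c("h", "k", "l")])
  frac <- atom_xyz(model) %*% t(ainv)        # natom x 3
  s2 <- rowSums((hm %*% ainv)^2)
  phase <- 2 * pi * (hm %*% t(frac))         # nref x natom
  coeff <- exp(-outer(s2 / 4, model$b_iso)) *
    rep(model$occupancy * model$n_electrons, each = nrow(hm))
  dim(coeff) <- dim(phase)                   # occ * N * exp(-B s^2 / 4)
  fcalc <- rowSums(coeff * exp(1i * phase))
  out <- as_tibble(hkl)
  out$s2 <- s2
  out$f_calc <- fcalc
  out$f_abs <- Mod(fcalc)
  attr(out, "cell") <- cell
  out
}

#' Least-squares X-ray residual and its coordinate gradient
#'
#' `E_xray = sum_h (k |F_calc(h)| - F_obs(h))^2` with `k` the optimal
#' linear scale, a least-squares stand-in for the crystallographic
#' goodness-of-fit target.  The gradient with respect to the cartesian
#' atom positions is analytic (the scale is at its optimum, so its
#' dependence on coordinates drops out).
#'
#' @param model a [structure_model()].
#' @param refl tibble with `h`, `k`, `l`, `f_obs` (amplitudes >= 0).
#' @return list: `energy`, `gradient` (natom x 3), `scale`, `f_calc`.
#' @export
exray_energy <- function(model, refl) {
  if (nrow(refl) == 0) abort("no reflections to score")
  if (any(refl$f_obs < 0)) abort("f_obs amplitudes must be non-negative")
  cell <- model_cell(model)
  a_mat <- cell_matrix(cell)
  ainv <- solve(a_mat)
  hm <- as.matrix(refl[c("h", "k", "l")])
  frac <- atom_xyz(model) %*% t(ainv)
  s2 <- rowSums((hm %*% ainv)^2)
  phase <- 2 * pi * (hm %*% t(frac))
  coeff <- exp(-outer(s2 / 4, model$b_iso)) *
    rep(model$occupancy * model$n_electrons, each = nrow(hm))
  dim(coeff) <- dim(phase)
  fcalc <- rowSums(coeff * exp(1i * phase))
  fabs <- Mod(fcalc)
  fo <- refl$f_obs
  k <- sum(fabs * fo) / sum(fabs^2)
  resid <- k * fabs - fo
  energy <- sum(resid^2)
  # d|F|/dx_j = -c_jh Im(e^{i phase} conj(F)) / |F| * (2 pi A^-T h)
  safe <- pmax(fabs, 1e-12)
  t_h <- 2 * k * resid / safe
  m <- -(coeff * Im(exp(1i * phase) * Conj(fcalc))) * t_h
  g_vec <- 2 * pi * hm %*% ainv                 # nref x 3, d(h.x_frac)/dx
  gradient <- t(m) %*% g_vec                    # natom x 3
  list(energy = energy, gradient = gradient, scale = k, f_calc = fcalc)
}
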