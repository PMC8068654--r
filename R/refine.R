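#' Harmonic restraints from a model's current geometry
#'
#' Builds bond restraints for every atom pair closer than `cutoff`, with
#' ideal lengths taken from the current geometry (so the energy is zero at
#' the generating model) — the stand-in for a molecular-mechanics force
#' field in desk-scale refinements.
#'
#' @param model a [structure_model()].
#' @param cutoff neighbour cutoff, angstrom.
#' @param k force constant (energy unit / angstrom^2).
#' @return list with a `bonds` tibble (`a`, `b`, `k`, `d0`) and an empty
#'   `angles` tibble, class `restraint_set`.
#' @export
harmonic_restraints <- function(model, cutoff = 2.6, k = 100) {
  xyz <- atom_xyz(model)
  d <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(d) & d > 0 & d <= cutoff, arr.ind = TRUE)
  bonds <- tibble(
    a = model$name[pairs[, 1]], b = model$name[pairs[, 2]],
    k = k, d0 = d[pairs]
  )
  restraint_set(bonds)
}

#' Assemble a restraint set
#'
#' @param bonds tibble `a`, `b`, `k`, `d0` (names, force constant, ideal
#'   length in angstrom).
#' @param angles tibble `a`, `b`, `c`, `k`, `theta0` (vertex atom `b`,
#'   ideal angle in degrees).
#' @return a `restraint_set` list.
#' @export
restraint_set <- function(bonds = NULL, angles = NULL) {
  empty_b <- tibble(a = character(), b = character(), k = numeric(),
    d0 = numeric())
  empty_a <- tibble(a = character(), b = character(), c = character(),
    k = numeric(), theta0 = numeric())
  structure(
    list(bonds = bonds %||% empty_b, angles = angles %||% empty_a),
    class = "restraint_set"
  )
}

#' Harmonic restraint energy and gradient
#'
#' `E_mm = sum k_b (d - d0)^2 + sum k_a (theta - theta0)^2` with distances
#' in angstrom and angles in radians inside the quadratic.
#'
#' @param model a [structure_model()].
#' @param restraints a [restraint_set()]; atom references must resolve.
#' @return list: `energy`, `gradient` (natom x 3).
#' @export
restraint_energy <- function(model, restraints) {
  xyz <- atom_xyz(model)
  grad <- matrix(0, nrow(model), 3)
  energy <- 0
  b <- restraints$bonds
  if (nrow(b)) {
    ia <- match_atoms(model, b$a)
    ib <- match_atoms(model, b$b)
    dv <- xyz[ia, , drop = FALSE] - xyz[ib, , drop = FALSE]
    d <- sqrt(rowSums(dv^2))
    energy <- energy + sum(b$k * (d - b$d0)^2)
    gmag <- 2 * b$k * (d - b$d0) / pmax(d, 1e-12)
    gv <- dv * gmag
    for (r in seq_len(nrow(b))) {
      grad[ia[r], ] <- grad[ia[r], ] + gv[r, ]
      grad[ib[r], ] <- grad[ib[r], ] - gv[r, ]
    }
  }
  an <- restraints$angles
  if (nrow(an)) {
    ia <- match_atoms(model, an$a)
    ib <- match_atoms(model, an$b)
    ic <- match_atoms(model, an$c)
    for (r in seq_len(nrow(an))) {
      u <- xyz[ia[r], ] - xyz[ib[r], ]
      v <- xyz[ic[r], ] - xyz[ib[r], ]
      lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
      ct <- sum(u * v) / (lu * lv)
      ct <- max(min(ct, 1 - 1e-12), -1 + 1e-12)
      th <- acos(ct)
      st <- sqrt(1 - ct^2)
      th0 <- an$theta0[r] * pi / 180
      energy <- energy + an$k[r] * (th - th0)^2
      pref <- -2 * an$k[r] * (th - th0) / st
      da <- pref * (v / (lu * lv) - ct * u / lu^2)
      dc <- pref * (u / (lu * lv) - ct * v / lv^2)
      grad[ia[r], ] <- grad[ia[r], ] + da
      grad[ic[r], ] <- grad[ic[r], ] + dc
      grad[ib[r], ] <- grad[ib[r], ] - da - dc
    }
  }
  list(energy = energy, gradient = grad)
}

restrict_restraints <- function(restraints, region) {
  restraint_set(
    bonds = filter(restraints$bonds, .data$a %in% region & .data$b %in% region),
    angles = filter(restraints$angles,
      .data$a %in% region & .data$b %in% region & .data$c %in% region)
  )
}

#' Combined refinement energy (restrained and quantum-refinement forms)
#'
#' Evaluates the two standard energy combinations:
#' `E_cryst = w_a * E_xray + E_mm` (restrained refinement) and
#' `E_cqx = w_mm * (w_a * E_xray + E_mm - E_mm1) + E_qm1` (quantum
#' refinement), where system 1 is a chosen region whose restraint energy
#' `E_mm1` is subtracted to avoid double counting and replaced by the
#' energy `E_qm1` of a pluggable backend (a genuine QM engine in real
#' applications; harmonic surrogates in tests).  A restraint belongs to
#' system 1 only when all of its atoms are inside the region.  The default
#' weights are the package's reference values: `w_a = 1.5368` (the CNS
#' default X-ray weight) and `w_mm = 1/3`.
#'
#' @param model a [structure_model()].
#' @param refl reflection tibble with `f_obs` (see [exray_energy()]).
#' @param restraints a [restraint_set()].
#' @param region character vector of atom names forming system 1, or
#'   `NULL` for plain restrained refinement (then `e_mm1 = e_qm1 = 0`).
#' @param weights list with `w_a` and `w_mm`, both positive.
#' @param system1_backend function(region_model) returning
#'   `list(energy, gradient)` for the region atoms; defaults to the
#'   restricted restraint energy (which makes `E_cqx` and `E_cryst`
#'   agree up to the weight algebra).
#' @return an `energy_breakdown` list: `e_xray`, `e_mm`, `e_mm1`, `e_qm1`,
#'   `e_cryst`, `e_cqx`, `gradient_cryst`, `gradient_cqx`, `weights`.
#' @export
combined_energy <- function(model, refl, restraints, region = NULL,
                            weights = list(w_a = 1.5368, w_mm = 1 / 3),
                            system1_backend = NULL) {
  stopifnot(weights$w_a > 0, weights$w_mm > 0)
  ex <- exray_energy(model, refl)
  em <- restraint_energy(model, restraints)
  if (is.null(region)) {
    em1 <- list(energy = 0, gradient = matrix(0, nrow(model), 3))
    eq1 <- em1
    ridx <- integer()
  } else {
    if (length(region) == 0) abort("system-1 region must be non-empty")
    ridx <- match_atoms(model, region)
    r1 <- restrict_restraints(restraints, region)
    em1 <- restraint_energy(model, r1)
    sub <- structure_model(as_tibble(model)[ridx, ],
      cell = model_cell(model), label = "system1")
    backend <- system1_backend %||%
      function(m) restraint_energy(m, restrict_restraints(restraints, m$name))
    eq1_sub <- backend(sub)
    if (!is.finite(eq1_sub$energy)) {
      abort("system-1 backend returned a non-finite energy")
    }
    gq <- matrix(0, nrow(model), 3)
    gq[ridx, ] <- eq1_sub$gradient
    eq1 <- list(energy = eq1_sub$energy, gradient = gq)
  }
  e_cryst <- weights$w_a * ex$energy + em$energy
  e_cqx <- weights$w_mm * (weights$w_a * ex$energy + em$energy - em1$energy) +
    eq1$energy
  g_cryst <- weights$w_a * ex$gradient + em$gradient
  g_cqx <- weights$w_mm *
    (weights$w_a * ex$gradient + em$gradient - em1$gradient) + eq1$gradient
  structure(
    list(
      e_xray = ex$energy, e_mm = em$energy, e_mm1 = em1$energy,
      e_qm1 = eq1$energy, e_cryst = e_cryst, e_cqx = e_cqx,
      gradient_cryst = g_cryst, gradient_cqx = g_cqx,
      scale = ex$scale, weights = weights
    ),
    class = "energy_breakdown"
  )
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown>\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.energy_breakdown <- function(x, ...) {
  tibble(
    term = c("e_xray", "e_mm", "e_mm1", "e_qm1", "e_cryst", "e_cqx"),
    value = c(x$e_xray, x$e_mm, x$e_mm1, x$e_qm1, x$e_cryst, x$e_cqx)
  )
}

#' @export
glance.energy_breakdown <- function(x, ...) {
  tibble(
    e_cryst = x$e_cryst, e_cqx = x$e_cqx, w_a = x$weights$w_a,
    w_mm = x$weights$w_mm, scale = x$scale
  )
}

#' Gradient-based coordinate refinement
#'
#' Minimizes an energy function of the atomic coordinates by BFGS with an
#' Armijo backtracking line search, so the energy along accepted steps is
#' non-increasing.  B factors and occupancies stay fixed.  Deterministic
#' given identical inputs.
#'
#' @param model starting [structure_model()].
#' @param energy_fn function(model) returning `list(energy, gradient)`
#'   with gradient an natom x 3 matrix; see [refine_model()] for the
#'   standard targets.
#' @param max_iter iteration cap.
#' @param gtol convergence threshold on the gradient infinity norm.
#' @return a `refinement` object: refined `model`, `trace` tibble
#'   (`iter`, `energy`, `grad_norm`, `step`), `converged`, and the
#'   start/final energies.
#' @export
minimize <- function(model, energy_fn, max_iter = 300, gtol = 1e-4) {
  n <- nrow(model)
  x <- as.numeric(t(atom_xyz(model)))
  put <- function(x) {
    m <- model
    xyz <- matrix(x, ncol = 3, byrow = TRUE)
    m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
    m
  }
  ev <- function(x) {
    e <- energy_fn(put(x))
    if (!is.finite(e$energy)) abort("non-finite energy during minimization")
    list(f = e$energy, g = as.numeric(t(e$gradient)))
  }
  cur <- ev(x)
  h_inv <- diag(3 * n)
  trace <- list(tibble(iter = 0L, energy = cur$f,
    grad_norm = max(abs(cur$g)), step = NA_real_))
  converged <- max(abs(cur$g)) < gtol
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    p <- -as.numeric(h_inv %*% cur$g)
    if (sum(p * cur$g) >= 0) {
      h_inv <- diag(3 * n)
      p <- -cur$g
    }
    step <- 1
    slope <- sum(p * cur$g)
    nxt <- NULL
    for (ls in 1:50) {
      cand <- ev(x + step * p)
      if (cand$f <= cur$f + 1e-4 * step * slope) {
        nxt <- cand
        break
      }
      step <- step / 2
    }
    if (is.null(nxt)) break
    s <- step * p
    y <- nxt$g - cur$g
    ys <- sum(y * s)
    if (ys > 1e-12) {
      rho <- 1 / ys
      hy <- h_inv %*% y
      h_inv <- h_inv - rho * (s %*% t(hy) + hy %*% t(s)) +
        rho * (rho * sum(y * hy) + 1) * (s %*% t(s))
    }
    x <- x + s
    cur <- nxt
    trace[[length(trace) + 1]] <- tibble(iter = iter, energy = cur$f,
      grad_norm = max(abs(cur$g)), step = step)
    converged <- max(abs(cur$g)) < gtol
    if (max(abs(s)) < 1e-10) break
  }
  trace <- bind_rows(trace)
  structure(
    list(
      model = put(x), trace = trace, converged = converged,
      initial_energy = trace$energy[1],
      final_energy = trace$energy[nrow(trace)],
      n_iter = iter
    ),
    class = "refinement"
  )
}

#' Refine a model against reflections under the standard targets
#'
#' Convenience front end to [minimize()] using either the restrained
#' target `E_cryst` or the quantum-refinement combination `E_cqx` from
#' [combined_energy()].
#'
#' @inheritParams combined_energy
#' @param target `"cryst"` or `"cqx"`.
#' @param ... passed to [minimize()].
#' @return a `refinement` object whose `breakdown` holds the final
#'   [combined_energy()] terms.
#' @export
refine_model <- function(model, refl, restraints, target = c("cryst", "cqx"),
                         region = NULL,
                         weights = list(w_a = 1.5368, w_mm = 1 / 3),
                         system1_backend = NULL, ...) {
  target <- match.arg(target)
  fn <- function(m) {
    b <- combined_energy(m, refl, restraints, region = region,
      weights = weights, system1_backend = system1_backend)
    if (target == "cryst") {
      list(energy = b$e_cryst, gradient = b$gradient_cryst)
    } else {
      list(energy = b$e_cqx, gradient = b$gradient_cqx)
    }
  }
  out <- minimize(model, fn, ...)
  out$breakdown <- combined_energy(out$model, refl, restraints,
    region = region, weights = weights, system1_backend = system1_backend)
  out$target <- target
  out
}

#' @export
print.refinement <- function(x, ...) {
  cat(
    "<refinement> ", x$n_iter, " iterations, energy ",
    signif(x$initial_energy, 6), " -> ", signif(x$final_energy, 6),
    if (x$converged) " (converged)" else " (iteration cap)", "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.refinement <- function(x, ...) x$trace

#' @export
glance.refinement <- function(x, ...) {
  tibble(
    n_iter = x$n_iter, converged = x$converged,
    initial_energy = x$initial_energy, final_energy = x$final_energy
  )
}

#' Coordinate RMSD between two models
#'
#' @param a,b structure models with identical atom ordering.
#' @param align `"none"` for the raw RMSD, or `"translation"` to remove
#'   the net translation first.  Amplitude-only refinement in P1 cannot
#'   see the cell origin (translating every atom leaves all `|F|`
#'   unchanged), so recovery of a refined model is judged after
#'   translation alignment.
#' @return root-mean-square coordinate difference, angstrom.
#' @export
model_rmsd <- function(a, b, align = c("none", "translation")) {
  align <- match.arg(align)
  stopifnot(nrow(a) == nrow(b))
  d <- atom_xyz(a) - atom_xyz(b)
  if (align == "translation") d <- sweep(d, 2, colMeans(d))
  sqrt(mean(rowSums(d^2)))
}
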