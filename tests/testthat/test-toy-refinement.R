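refl_for <- function(model, d_min = 2.2) {
  hkl <- reflection_indices(model_cell(model), d_min)
  sf <- direct_structure_factors(model, hkl)
  dplyr::mutate(hkl, f_obs = sf$f_abs)
}

test_that("structure factors obey F(000) and Friedel symmetry", {
  hkl <- reflection_indices(model_cell(femo), 2.5)
  sf <- direct_structure_factors(femo, hkl)
  f000 <- sf$f_calc[sf$h == 0 & sf$k == 0 & sf$l == 0]
  expect_equal(Re(f000), sum(femo$occupancy * femo$n_electrons))
  expect_equal(Im(f000), 0)

  mates <- dplyr::mutate(hkl, h = -h, k = -k, l = -l)
  sfm <- direct_structure_factors(femo, mates)
  expect_equal(sfm$f_calc, Conj(sf$f_calc), tolerance = 1e-12)
  expect_error(
    direct_structure_factors(femo, dplyr::bind_rows(hkl[1, ], hkl[1, ])),
    "duplicate"
  )
})

test_that("translating one atom multiplies F by the expected phase factor", {
  one <- single_sulfide(cell = 10)
  hkl <- tibble::tibble(h = c(1L, 2L, 3L), k = 0L, l = 0L)
  f0 <- direct_structure_factors(one, hkl)$f_calc
  dx <- 0.8
  moved <- one
  moved$x <- moved$x + dx
  f1 <- direct_structure_factors(moved, hkl)$f_calc
  expect_equal(f1, f0 * exp(2i * pi * hkl$h * dx / 10), tolerance = 1e-12)
})

test_that("the X-ray residual is zero at truth and scale invariant", {
  refl <- refl_for(femo)
  ex <- exray_energy(femo, refl)
  expect_equal(ex$energy, 0, tolerance = 1e-15 * sum(refl$f_obs^2))

  # scaling the observations is absorbed by the optimal linear scale
  set.seed(3)
  pm <- femo
  pm$x <- pm$x + rnorm(nrow(pm), sd = 0.05)
  e1 <- exray_energy(pm, refl)
  refl2 <- dplyr::mutate(refl, f_obs = 2 * f_obs)
  e2 <- exray_energy(pm, refl2)
  expect_equal(e2$energy / e1$energy, 4, tolerance = 1e-8)
  expect_equal(e2$scale / e1$scale, 2, tolerance = 1e-8)
})

test_that("X-ray and restraint gradients match central differences", {
  set.seed(8)
  pm <- femo
  pm$x <- pm$x + rnorm(nrow(pm), sd = 0.08)
  refl <- refl_for(femo)
  rs <- harmonic_restraints(femo)
  rs$angles <- tibble::tibble(
    a = "FE2", b = "S2B", c = "FE6", k = 50, theta0 = 60
  )
  for (fn in list(
    function(m) exray_energy(m, refl),
    function(m) restraint_energy(m, rs)
  )) {
    ana <- fn(pm)
    for (probe in list(c(3, 1), c(10, 2), c(16, 3))) {
      i <- probe[1]; ax <- probe[2]
      h <- 1e-6
      plus <- pm; minus <- pm
      col <- c("x", "y", "z")[ax]
      plus[[col]][i] <- plus[[col]][i] + h
      minus[[col]][i] <- minus[[col]][i] - h
      num <- (fn(plus)$energy - fn(minus)$energy) / (2 * h)
      denom <- max(abs(num), 1e-6)
      expect_lt(abs(ana$gradient[i, ax] - num) / denom, 1e-4)
    }
  }
})

test_that("restraint energy is zero at ideal geometry and quadratic", {
  rs <- harmonic_restraints(femo, k = 100)
  expect_equal(restraint_energy(femo, rs)$energy, 0)
  stretched <- femo
  # stretch the SG-FE1 bond along z by delta
  delta <- 0.2
  stretched$z[stretched$name == "SG"] <-
    stretched$z[stretched$name == "SG"] - delta
  one_bond <- restraint_set(bonds = dplyr::filter(rs$bonds,
    a == "SG" | b == "SG"))
  expect_equal(restraint_energy(stretched, one_bond)$energy, 100 * delta^2,
    tolerance = 1e-10)
  dangling <- restraint_set(bonds = tibble::tibble(a = "SG", b = "ZZ9",
    k = 1, d0 = 1))
  expect_error(restraint_energy(femo, dangling), "ZZ9")
})

test_that("energy combination identities hold exactly", {
  refl <- refl_for(femo)
  rs <- harmonic_restraints(femo)
  set.seed(12)
  pm <- femo
  pm$x <- pm$x + rnorm(nrow(pm), sd = 0.1)
  pm$y <- pm$y + rnorm(nrow(pm), sd = 0.1)
  region <- c("MO", "FE1", "FE2", "S2B", "C")
  b <- combined_energy(pm, refl, rs, region = region)
  expect_identical(b$e_cryst, b$weights$w_a * b$e_xray + b$e_mm)
  expect_identical(
    b$e_cqx,
    b$weights$w_mm * (b$weights$w_a * b$e_xray + b$e_mm - b$e_mm1) +
      b$e_qm1
  )
  expect_equal(b$weights$w_a, 1.5368)
  expect_equal(b$weights$w_mm, 1 / 3)

  # default backend: e_qm1 equals e_mm1, so
  # e_cqx = w_mm (w_a e_xray + e_mm) + (1 - w_mm) e_mm1
  expect_equal(b$e_qm1, b$e_mm1)
  expect_equal(
    b$e_cqx,
    b$weights$w_mm * (b$weights$w_a * b$e_xray + b$e_mm) +
      (1 - b$weights$w_mm) * b$e_mm1,
    tolerance = 1e-12
  )

  # w_mm = 1 with e_qm1 = e_mm1 collapses the combination to e_cryst
  b1 <- combined_energy(pm, refl, rs, region = region,
    weights = list(w_a = 1.5368, w_mm = 1))
  expect_equal(b1$e_cqx, b1$e_cryst, tolerance = 1e-12)

  # a custom backend is used and propagated
  b2 <- combined_energy(pm, refl, rs, region = region,
    system1_backend = function(m) {
      list(energy = 7.5, gradient = matrix(0, nrow(m), 3))
    })
  expect_equal(b2$e_qm1, 7.5)
  bad <- function(m) list(energy = NaN, gradient = matrix(0, nrow(m), 3))
  expect_error(
    combined_energy(pm, refl, rs, region = region, system1_backend = bad),
    "non-finite"
  )
})

test_that("minimization is monotone and stationary at the generating model", {
  refl <- refl_for(femo)
  rs <- harmonic_restraints(femo)
  ref <- refine_model(femo, refl, rs, target = "cryst", max_iter = 50)
  expect_lt(model_rmsd(ref$model, femo), 1e-3)
  expect_true(all(diff(ref$trace$energy) <= 1e-9))
})

test_that("refinement recovers coordinates perturbed by 0.3 angstrom", {
  refl <- refl_for(femo, d_min = 2.0)
  rs <- harmonic_restraints(femo)
  set.seed(7)
  pm <- femo
  dirs <- matrix(rnorm(3 * nrow(femo)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2)) * 0.3
  pm$x <- pm$x + dirs[, 1]
  pm$y <- pm$y + dirs[, 2]
  pm$z <- pm$z + dirs[, 3]
  ref <- refine_model(pm, refl, rs, target = "cryst", max_iter = 300)
  expect_lt(model_rmsd(ref$model, femo, align = "translation"), 0.05)
  expect_true(all(diff(ref$trace$energy) <= 1e-9))
})

test_that("sulfide truth keeps a lower X-ray residual than an N2 model", {
  refl_truth <- refl_for(femo, d_min = 2.2)
  n2 <- substitute_ligand(femo, "2B", "N2", orientation = c(0, 0, 1))
  rs_s <- harmonic_restraints(femo)
  rs_n <- harmonic_restraints(n2)
  wins <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    noisy <- dplyr::mutate(refl_truth,
      f_obs = pmax(f_obs + rnorm(dplyr::n(), sd = 0.5), 0))
    start_s <- femo
    start_n <- n2
    ref_s <- refine_model(start_s, noisy, rs_s, target = "cryst",
      max_iter = 40)
    ref_n <- refine_model(start_n, noisy, rs_n, target = "cryst",
      max_iter = 40)
    wins <- wins + (ref_n$breakdown$e_xray > ref_s$breakdown$e_xray)
  }
  expect_equal(wins, 10L)
})
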