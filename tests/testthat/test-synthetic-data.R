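test_that("the cofactor fixture has the canonical composition and topology", {
  s_atoms <- femo$name[femo$element == "S"]
  expect_length(s_atoms, 10)           # 9 cluster sulfides + Cys thiolate
  expect_setequal(
    femo$name,
    c("MO", paste0("FE", 1:7), "C", "S1A", "S2A", "S3A", "S4A", "S5A",
      "S1B", "S3B", "S4B", "S2B", "SG")
  )
  xyz <- cbind(femo$x, femo$y, femo$z)
  rownames(xyz) <- femo$name
  d <- as.matrix(dist(xyz))
  metals <- c("MO", paste0("FE", 1:7))
  fe <- paste0("FE", 1:7)
  for (s in c("S2B", "S3A", "S5A")) {
    expect_equal(sum(d[s, fe] <= 2.6), 2)
  }
  expect_setequal(names(which(d["S2B", fe] <= 2.6)), c("FE2", "FE6"))
  for (s in c("S1A", "S2A", "S4A", "S1B", "S3B", "S4B")) {
    expect_gte(sum(d[s, metals] <= 2.6), 3)
  }
  # S2B sits on the perpendicular bisector of its Fe pair: its projection
  # onto the Fe2-Fe6 axis is the pair midpoint
  axis <- xyz["FE6", ] - xyz["FE2", ]
  axis <- axis / sqrt(sum(axis^2))
  proj <- xyz["FE2", ] + sum((xyz["S2B", ] - xyz["FE2", ]) * axis) * axis
  mid <- (xyz["FE2", ] + xyz["FE6", ]) / 2
  expect_lt(sqrt(sum((proj - mid)^2)), 0.2)
})

test_that("ligand substitution swaps electron budgets correctly", {
  n2 <- substitute_ligand(femo, "2B", "N2", orientation = c(1, 1, 0))
  expect_false("S2B" %in% n2$name)
  expect_true(all(c("N2B1", "N2B2") %in% n2$name))
  p1 <- atom_pos(n2, "N2B1")
  p2 <- atom_pos(n2, "N2B2")
  expect_equal(sqrt(sum((p1 - p2)^2)), 1.10, tolerance = 1e-10)
  expect_equal((p1 + p2) / 2, atom_pos(femo, "S2B"), tolerance = 1e-10)
  expect_equal(sum(femo$n_electrons) - sum(n2$n_electrons), 4)

  n2h2 <- substitute_ligand(femo, "3A", "N2H2")
  expect_equal(sum(femo$n_electrons) - sum(n2h2$n_electrons), 2)
  back <- substitute_ligand(n2h2, "3A", "S2-")
  expect_equal(sum(back$n_electrons), sum(femo$n_electrons))
  expect_error(substitute_ligand(femo, "9Z", "N2"), "unknown mu2 site")
})

test_that("a single Gaussian atom integrates to its electron count", {
  m16 <- single_sulfide(n_electrons = 16)
  g16 <- synthesize_map(map_spec(m16, grid_spacing = 0.25, padding = 4))
  tot16 <- sum(g16$values) * grid_voxel_volume(g16)
  expect_equal(tot16, 16, tolerance = 0.01)

  m18 <- single_sulfide(n_electrons = 18)
  g18 <- synthesize_map(map_spec(m18, grid_spacing = 0.25, padding = 4))
  tot18 <- sum(g18$values) * grid_voxel_volume(g18)
  expect_equal(tot18 / tot16, 18 / 16, tolerance = 1e-6)
})

test_that("maps are linear in the model and bit-reproducible by seed", {
  half_a <- structure_model(as.data.frame(femo)[1:9, ],
    cell = model_cell(femo))
  half_b <- structure_model(as.data.frame(femo)[10:19, ],
    cell = model_cell(femo))
  sp <- function(m) map_spec(m, grid_spacing = 0.4, box = femo_box)
  ga <- synthesize_map(sp(half_a))
  gb <- synthesize_map(sp(half_b))
  gall <- synthesize_map(sp(femo))
  expect_equal(gall$values, ga$values + gb$values, tolerance = 1e-12)

  n1 <- synthesize_map(map_spec(femo, grid_spacing = 0.4, noise_sd = 0.1,
    seed = 42))
  n2 <- synthesize_map(map_spec(femo, grid_spacing = 0.4, noise_sd = 0.1,
    seed = 42))
  expect_identical(n1$values, n2$values)
  n3 <- synthesize_map(map_spec(femo, grid_spacing = 0.4, noise_sd = 0.1,
    seed = 43))
  expect_false(identical(n1$values, n3$values))
})

test_that("resolution truncation produces negative Fourier ripples", {
  g0 <- synthesize_map(map_spec(femo, grid_spacing = 0.3))
  expect_gte(min(g0$values), 0)
  g <- synthesize_map(map_spec(femo, grid_spacing = 0.3, band_limit = 1.8))
  expect_lt(min(g$values), -1e-3)
  # ripples hug the cluster: the most negative voxel is near the metals
  idx <- which(g$values == min(g$values), arr.ind = TRUE)[1, ]
  pos <- g$origin + (idx - 1) * (g$cell[1:3] / dim(g$values))
  dmin_atom <- min(sqrt((femo$x - pos[1])^2 + (femo$y - pos[2])^2 +
    (femo$z - pos[3])^2))
  expect_lt(dmin_atom, 3)
})

test_that("anomalous maps weight elements, not electron counts", {
  spec <- map_spec(femo, grid_spacing = 0.3,
    anomalous_weights = c(S = 1, FE = 0.1, MO = 5))
  ga <- synthesize_anomalous_map(spec)
  idx <- which(ga$values == max(ga$values), arr.ind = TRUE)[1, ]
  pos <- ga$origin + (idx - 1) * (ga$cell[1:3] / dim(ga$values))
  expect_lt(sqrt(sum((pos - atom_pos(femo, "MO"))^2)), 0.3)

  zero <- synthesize_anomalous_map(map_spec(femo, grid_spacing = 0.5,
    anomalous_weights = c(S = 0, FE = 0, MO = 0)))
  expect_equal(max(abs(zero$values)), 0)

  one <- single_sulfide()
  g1 <- synthesize_anomalous_map(map_spec(one, grid_spacing = 0.25,
    anomalous_weights = c(S = 1)))
  r <- integrate_sphere(g1, atom_pos(one, "S1"), 1.05)
  expect_equal(r$rho, gaussian_sphere_integral(1.05, 15, 1),
    tolerance = 0.02)
})
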